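test_that("full-length probability is the base-composition product", {
  all1 <- synthesisModel(rep(1, 4), rep(1, 4))
  expect_equal(fullLengthProbability("ACGTACGT", all1), 1)
  m <- synthesisModel(c(A = 0.9, C = 1, G = 1, T = 0.9), rep(1, 4))
  expect_equal(fullLengthProbability("AT", m), 0.81)
  ## independent per-character loop
  set.seed(51)
  S <- setNames(runif(4, 0.6, 1), c("A", "C", "G", "T"))
  B <- setNames(runif(4, 0.6, 1), c("A", "C", "G", "T"))
  sm <- synthesisModel(S, B)
  sq <- "ACGTGGTTAC"
  want <- 1
  for (ch in strsplit(sq, "")[[1]]) want <- want * S[[ch]] * B[[ch]]
  expect_equal(fullLengthProbability(sq, sm), want, tolerance = 1e-14)
  expect_error(fullLengthProbability("ACGN", sm), "A,C,G,T")
})

test_that("variant probabilities match the exhaustive per-base state
           enumeration on 4-mers", {
  ## per-base states: ok (S*B), abasic (S*(1-B)), truncate (1-S);
  ## synthesis halts at the lowest truncating base (base 1 = 3' end);
  ## classify by error count
  oracle <- function(seq, S, B) {
    chars <- strsplit(seq, "")[[1]]; P <- length(chars)
    out <- list(full = 0, abasic = numeric(P), trunc = numeric(P),
                residual = 0)
    states <- expand.grid(rep(list(0:2), P))
    for (r in seq_len(nrow(states))) {
      st <- as.integer(states[r, ])
      pr <- 1
      for (m in 1:P) {
        b <- chars[P - m + 1]
        pr <- pr * switch(st[m] + 1, S[b] * B[b], S[b] * (1 - B[b]),
                          1 - S[b])
      }
      tpos <- which(st == 2)[1]
      if (is.na(tpos)) {
        ab <- which(st == 1)
        if (length(ab) == 0) out$full <- out$full + pr
        else if (length(ab) == 1) out$abasic[ab] <- out$abasic[ab] + pr
        else out$residual <- out$residual + pr
      } else {
        if (any(st[seq_len(tpos - 1)] == 1)) out$residual <- out$residual + pr
        else out$trunc[tpos] <- out$trunc[tpos] + pr
      }
    }
    out
  }
  set.seed(53)
  for (trial in 1:6) {
    sq <- or_randSeq(4)
    S <- setNames(runif(4, 0.5, 1), c("A", "C", "G", "T"))
    B <- setNames(runif(4, 0.5, 1), c("A", "C", "G", "T"))
    if (trial == 6) B["A"] <- 0  # ratio form of the abasic probability
                                 # is undefined; direct product required
    sm <- synthesisModel(S, B)
    vs <- variantSet(sq, sm)
    oc <- oracle(sq, S, B)
    expect_equal(vs$probability[vs$variant_class == "full"],
                 unname(oc$full), tolerance = 1e-12)
    expect_equal(vs$probability[vs$variant_class == "abasic"],
                 unname(oc$abasic), tolerance = 1e-12)
    expect_equal(vs$probability[vs$variant_class == "truncated"],
                 unname(oc$trunc), tolerance = 1e-12)
    expect_equal(attr(vs, "residual"), unname(oc$residual),
                 tolerance = 1e-12)
    expect_equal(sum(vs$probability) + attr(vs, "residual"), 1,
                 tolerance = 1e-12)
  }
})

test_that("variant structure: 3'-anchored prefixes, single abasic marks", {
  sm <- or_trueSynthesis()
  sq <- "ACGTTGCA"
  vs <- variantSet(sq, sm)
  expect_identical(nrow(vs), 2L * nchar(sq) + 1L)
  tr <- vs[vs$variant_class == "truncated", ]
  for (r in seq_len(nrow(tr))) {
    m <- tr$position[r]
    if (m == 1) expect_identical(tr$sequence[r], "")
    else  ## bases 1..m-1 from the 3' end = last m-1 characters
      expect_identical(tr$sequence[r],
                       substr(sq, nchar(sq) - m + 2, nchar(sq)))
  }
  ab <- vs[vs$variant_class == "abasic", ]
  for (r in seq_len(nrow(ab))) {
    d <- which(strsplit(ab$sequence[r], "")[[1]] !=
                 strsplit(sq, "")[[1]])
    expect_identical(length(d), 1L)
    expect_identical(substr(ab$sequence[r], d, d), "_")
    expect_identical(d, nchar(sq) - ab$position[r] + 1L)
  }
})

test_that("degenerate models collapse to the expected variant sets", {
  ## all probabilities 1 -> only the full-length probe, residual 0
  all1 <- synthesisModel(rep(1, 4), rep(1, 4))
  vs <- variantSet("ACGT", all1)
  expect_equal(vs$probability[vs$variant_class == "full"], 1)
  expect_equal(sum(vs$probability[vs$variant_class != "full"]), 0)
  expect_equal(attr(vs, "residual"), 0)
  ## single-base probe "A": abasic mass (1-B), full B, no truncation mass
  m <- synthesisModel(c(A = 1, C = 1, G = 1, T = 1),
                      c(A = 0.9, C = 1, G = 1, T = 1))
  vs1 <- variantSet("A", m)
  expect_equal(vs1$probability[vs1$variant_class == "full"], 0.9)
  expect_equal(vs1$probability[vs1$variant_class == "abasic"], 0.1)
  expect_equal(vs1$probability[vs1$variant_class == "truncated"], 0)
})

test_that("effective alpha is the probability-weighted mix with a
           zero-binding residual", {
  sm <- or_trueSynthesis()
  vs <- variantSet("ACGT", sm)
  ## single full-length variant dominates when alpha_F alone is set
  a <- numeric(nrow(vs)); a[vs$variant_class == "full"] <- 0.4
  expect_equal(effectiveAlpha(vs, a),
               0.4 * vs$probability[vs$variant_class == "full"])
  ## all alpha = 1 -> total emitted mass (< 1 because of the residual)
  expect_equal(effectiveAlpha(vs, rep(1, nrow(vs))),
               sum(vs$probability))
  expect_lt(effectiveAlpha(vs, rep(1, nrow(vs))), 1)
  ## hand-weighted two-variant example
  vs2 <- vs[1:2, ]
  vs2$probability <- c(0.6, 0.2)
  expect_equal(effectiveAlpha(vs2, c(0.5, 0.1)), 0.32)
  expect_error(effectiveAlpha(vs, rep(1.5, nrow(vs))), "\\[0, 1\\]")
})

test_that("vectorized variant machinery reproduces variantSet", {
  pf <- asNamespace("probeForest")
  set.seed(57)
  for (trial in 1:5) {
    sq <- or_randSeq(sample(3:12, 1))
    S <- setNames(runif(4, 0.5, 0.999), c("A", "C", "G", "T"))
    B <- setNames(runif(4, 0.5, 0.999), c("A", "C", "G", "T"))
    sm <- synthesisModel(S, B)
    vs <- variantSet(sq, sm)
    vd <- pf$.variantDesign(sq)
    pv <- pf$.variantProbs(vd$A, vd$fail, c(S, B))
    expect_equal(pv, vs$probability, tolerance = 1e-12)
    expect_identical(vd$sequences, vs$sequence)
  }
})

test_that("zero error rates reduce the pipeline to the error-free model", {
  p <- readNNParams()
  all1 <- synthesisModel(rep(1, 4), rep(1, 4))
  des <- makeDesign(4, probeLen = 8, segmentLengths = c(20L),
                    seed = 5)
  fm <- fragmentationModel(6)
  conc <- c(seg01 = 1e-8)
  pred <- predictIntensities(des, all1, conc, fm)
  ## spot alpha must equal the bare fractionBound of the full probe
  for (r in sample(nrow(des@probes), 3)) {
    kt <- buildKeqTable(des@probes$sequence[r], des@segments, p,
                        prune = 0)
    expect_equal(pred$alpha[r], fractionBound(kt, fm, conc),
                 tolerance = 1e-10)
  }
})
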