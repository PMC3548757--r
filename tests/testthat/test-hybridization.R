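test_that("table enumeration matches the exhaustive triple loop", {
  p <- readNNParams()
  set.seed(23)
  seg <- c(s1 = or_randSeq(12))
  probe <- or_revcomp(seg[[1]])  # 12-bp perfectly complementary probe
  kt <- buildKeqTable(probe, seg, p, prune = 0)
  ## brute-force count over (i, j, k): fragments j >= 2, offsets leaving
  ## >= 2 aligned bases on the 12-mer probe, both strands
  L <- 12L; P <- 12L; cnt <- 0L
  for (i in 1:(L - 1)) for (j in 2:(L - i + 1)) {
    for (k in 2:(P + j - 2)) {
      lo <- max(1L, k - j + 1L); hi <- min(P, k)
      if (hi - lo + 1L >= 2L) cnt <- cnt + 1L
    }
  }
  expect_identical(nrow(kt@entries), 2L * cnt)
  expect_true(all(kt@entries$keq > 0))
  ## prune = 0 vs default prune: pruned is a subset
  ktp <- buildKeqTable(probe, seg, p, prune = 1e-6)
  expect_lt(nrow(ktp@entries), nrow(kt@entries))
  expect_true(all(ktp@entries$keq >= 1e-6 * max(kt@entries$keq)))
})

test_that("a 2-bp probe against its 2-bp segment has the full-overlap
           entry and nothing below two pairs", {
  p <- readNNParams()
  kt <- buildKeqTable("AT", c(s = "AT"), p, prune = 0)
  e <- kt@entries
  expect_true(all(e$j == 2))  # only the whole segment can align
  expect_setequal(unique(e$strand), c("forward", "reverse"))
  expect_true(all(e$tail_class == "both_open"))  # whole-segment fragment
})

test_that("empty segment list and missing concentrations error", {
  p <- readNNParams()
  expect_error(buildKeqTable("ACGTACGT", character(0), p), "named|empty")
  kt <- buildKeqTable("ACGTACGT", c(s1 = "ACGTACGTAA"), p)
  fm <- fragmentationModel(5)
  expect_error(fractionBound(kt, fm, c(other = 1)), "missing concentration")
  expect_error(fractionBound(kt, fm, c(s1 = -1)), ">= 0")
})

test_that("fraction bound: fixed point, wash annihilation, monotonicity", {
  p <- readNNParams()
  set.seed(31)
  seg <- c(s1 = or_randSeq(16))
  probe <- or_revcomp(substr(seg[[1]], 3, 12))
  kt <- buildKeqTable(probe, seg, p, prune = 0)
  fm <- fragmentationModel(6)
  ## single entry with C*K = 1 -> alpha = 1/2 (Langmuir fixed point):
  ## synthesize a table with one entry directly
  one <- kt
  one@entries <- kt@entries[1L, , drop = FALSE]
  K1 <- one@entries$keq
  w1 <- fm@p^c(both_cut = 2, left_open = 1, right_open = 1,
               both_open = 0)[one@entries$tail_class] *
    fm@q^(one@entries$j - 1)
  alpha <- fractionBound(one, fm, c(s1 = unname(1 / (K1 * w1))))
  expect_equal(alpha, 0.5, tolerance = 1e-12)
  ## wash above every K -> empty numerator
  expect_equal(fractionBound(kt, fm, c(s1 = 1e-6),
                             washModel(2 * max(kt@entries$keq))), 0)
  ## alpha in [0, 1) and non-decreasing in C without wash
  cs <- 10^seq(-20, -2, by = 2)
  as <- vapply(cs, function(C) fractionBound(kt, fm, c(s1 = C)),
               numeric(1))
  expect_true(all(as >= 0 & as < 1))
  expect_true(all(diff(as) > 0))
  ## washed alpha never exceeds unwashed
  aw <- fractionBound(kt, fm, c(s1 = 1e-8),
                      washModel(stats::median(kt@entries$keq)))
  expect_lte(aw, fractionBound(kt, fm, c(s1 = 1e-8)))
})

test_that("dilution limit: alpha approaches the linear Langmuir sum", {
  p <- readNNParams()
  seg <- c(s1 = "ACGGATTTACGGA")
  kt <- buildKeqTable("TCCGTAAA", seg, p, prune = 0)
  fm <- fragmentationModel(4)
  e <- kt@entries
  w <- fm@p^c(both_cut = 2, left_open = 1, right_open = 1,
              both_open = 0)[e$tail_class] * fm@q^(e$j - 1)
  C <- 1e-25
  lin <- C * sum(w * e$keq)
  expect_equal(fractionBound(kt, fm, c(s1 = C)), lin,
               tolerance = 1e-8)
})

test_that("fraction bound equals the independent brute force on random
           small instances", {
  p <- readNNParams()
  set.seed(37)
  for (trial in 1:12) {
    L <- sample(8:20, 1)
    P <- sample(4:10, 1)
    seg <- c(s1 = or_randSeq(L))
    probe <- or_randSeq(P)
    if (trial %% 4 == 0) {
      pb <- strsplit(probe, "")[[1]]
      pb[sample(2:(P - 1), 1)] <- "_"
      probe <- paste(pb, collapse = "")
    }
    mu <- runif(1, 1.5, 12)
    C <- 10^runif(1, -14, -4)
    kt <- buildKeqTable(probe, seg, p, prune = 0)
    ## 0.99 factor keeps the threshold off exact entry values, where
    ## independently-rounded energies could flip an entry by one ulp
    washThr <- if (trial %% 2) 0 else
      0.99 * stats::median(kt@entries$keq)
    got <- fractionBound(kt, fragmentationModel(mu), c(s1 = C),
                         washModel(washThr))
    want <- or_alpha(probe, seg[[1]], p, mu, C, washThr)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("aggregated fast path agrees with the per-entry table", {
  p <- readNNParams()
  pf <- asNamespace("probeForest")
  set.seed(41)
  for (trial in 1:8) {
    L1 <- sample(10:25, 1); L2 <- sample(10:25, 1)
    segs <- c(a = or_randSeq(L1), b = or_randSeq(L2))
    probe <- or_randSeq(sample(5:10, 1))
    mu <- runif(1, 2, 15)
    fm <- fragmentationModel(mu)
    conc <- c(a = 10^runif(1, -12, -6), b = 10^runif(1, -12, -6))
    kt <- buildKeqTable(probe, segs, p, prune = 0)
    ## keep thresholds off the exact K values: the per-entry and grouped
    ## paths compute the same energies by different summation orders, so
    ## a threshold sitting exactly on an entry flips it by one ulp
    wash <- sort(sample(kt@entries$keq, 2)) * 0.9999
    for (wi in c(0, 1, 2)) {
      thr <- if (wi == 0) 0 else wash[wi]
      a1 <- fractionBound(kt, fm, conc, washModel(thr))
      cache <- pf$.keqCache(segs, p, 42, 1, wash, TRUE)
      cm <- pf$.coefMatrices(cache, probe, fm, thr)
      a2 <- as.numeric(cm$num %*% conc) /
        (as.numeric(cm$den %*% conc) + 1)
      expect_equal(a2, a1, tolerance = 1e-10)
    }
  }
})

test_that("temperature ordering: entries reorder consistently under
           pure-enthalpy tables", {
  ## with all dS = 0, K_eq ordering by dH is preserved at any temperature
  p <- readNNParams()
  tab <- p@steps
  tab$dS <- 0
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write.table(tab, tmp, sep = "\t", row.names = FALSE, quote = FALSE)
  ph <- readNNParams(tmp)
  seg <- c(s1 = "ACGTAGGCAT")
  k1 <- buildKeqTable("ATGCCT", seg, ph, prune = 0, tempC = 42)
  k2 <- buildKeqTable("ATGCCT", seg, ph, prune = 0, tempC = 84)
  ## sorted by the cold-table ordering, the hot table must be
  ## non-decreasing too (exact ties allowed: many alignments share a
  ## dH total under a pure-enthalpy table)
  o <- order(k1@entries$keq)
  hot <- k2@entries$keq[o]
  expect_true(all(diff(hot) >= -1e-12 * hot[-length(hot)]))
})

test_that("disallowing left-overhanging fragments removes exactly the
           alignments past the probe 5' end", {
  p <- readNNParams()
  seg <- c(s1 = "ACGTACGTACGT")
  ktAll <- buildKeqTable("TACGTA", seg, p, prune = 0)
  ktNo <- buildKeqTable("TACGTA", seg, p, prune = 0,
                        allowLeftOverhang = FALSE)
  expect_lt(nrow(ktNo@entries), nrow(ktAll@entries))
  ## remaining entries must have the fragment 5' end within the probe
  ## frame and no aligned base cut off on the left: k - j + 1 >= 1
  expect_true(all(ktNo@entries$k - ktNo@entries$j + 1 >= 1))
})
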