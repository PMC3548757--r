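test_that("bundled parameter set loads complete and in stated units", {
  p <- readNNParams()
  expect_s4_class(p, "NNParameterSet")
  expect_identical(sum(p@steps$class == "match"), 10L)
  expect_identical(sum(p@steps$class == "mismatch"), 51L)
  ## strand-symmetry of the lookup: all 16 WC contexts resolvable
  expect_length(probeForest:::.missingMatchSteps(p), 0L)
  ## units: AA/TT enthalpy is tens of kJ/mol, negative
  aa <- p@steps[p@steps$step == "AA/TT", ]
  expect_lt(aa$dH, -20000)
  expect_gt(aa$dH, -60000)
})

test_that("parameter file errors are specific", {
  p <- readNNParams()
  tab <- p@steps
  tmp <- withr::local_tempfile(fileext = ".tsv")
  ## drop one WC step -> error naming it
  write.table(tab[tab$step != "CG/GC", ], tmp, sep = "\t",
              row.names = FALSE, quote = FALSE)
  expect_error(readNNParams(tmp), "CG/GC")
  ## duplicate step -> parse error with row number
  write.table(rbind(tab, tab[tab$step == "AA/TT", ]), tmp, sep = "\t",
              row.names = FALSE, quote = FALSE)
  expect_error(readNNParams(tmp), "duplicate step 'AA/TT'.*row",
               perl = TRUE)
})

test_that("overrides replace single entries and leave the rest alone", {
  p0 <- readNNParams()
  ov <- data.frame(step = "AG/TT", dH = -1234, dS = -5,
                   class = "mismatch")
  p1 <- readNNParams(overrides = ov)
  ## duplex containing exactly the AG/TT step: probe 5'-AG-3' over
  ## target 3'-TT-5', i.e. fragment "TT" with its 5' base at position 2
  al <- function(par) deltaG(duplexAlignment("AG", "TT", 2), par, 310)
  expect_false(isTRUE(all.equal(al(p0), al(p1))))
  ## an alignment avoiding that step is untouched
  al2 <- function(par) deltaG(duplexAlignment("AAAA", "TTTT", 4), par, 310)
  expect_equal(al2(p0), al2(p1))
})

test_that("free energy matches a position-by-position oracle on random
           duplexes, including mismatches and abasic nicks", {
  p <- readNNParams()
  set.seed(101)
  for (trial in 1:40) {
    P <- sample(5:15, 1)
    probe <- or_randSeq(P)
    target <- or_revcomp(probe)  # perfect duplex on the target strand
    tb <- strsplit(target, "")[[1]]
    ## inject 0-2 mismatches into the target
    nmm <- sample(0:2, 1)
    for (m in sample(seq_len(P), nmm)) {
      tb[m] <- sample(setdiff(c("A", "C", "G", "T"), tb[m]), 1)
    }
    target <- paste(tb, collapse = "")
    pb <- strsplit(probe, "")[[1]]
    if (trial %% 3 == 0) pb[sample(2:(P - 1), 1)] <- "_"
    probe <- paste(pb, collapse = "")
    tempK <- runif(1, 290, 340)
    na <- sample(c(1, 0.5, 0.195), 1)
    got <- tryCatch(
      deltaG(duplexAlignment(probe, target, P), p, tempK, na),
      error = function(e) e)
    ## bottom bases 3'->5' beneath probe position i: the target base
    ## pairing it is target[P - i + 1]
    under <- paste(rev(strsplit(target, "")[[1]]), collapse = "")
    want <- or_deltaG(probe, under, p, tempK, na)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("additivity: n-mer perfect duplex equals sum of step terms plus
           two initiation terms", {
  p <- readNNParams()
  set.seed(7)
  for (trial in 1:10) {
    P <- sample(5:15, 1)
    probe <- or_randSeq(P)
    frag <- or_revcomp(probe)
    dg <- deltaG(duplexAlignment(probe, frag, P), p, 315.15)
    ## accumulate by brute force from the raw table
    pb <- strsplit(probe, "")[[1]]
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    env <- or_stepEnv(p)
    acc <- 0
    for (i in 1:(P - 1)) {
      hs <- or_stepLookup(env, paste0(pb[i], pb[i + 1]),
                          paste0(comp[pb[i]], comp[pb[i + 1]]))
      acc <- acc + hs[1] - 315.15 * hs[2]
    }
    init <- p@steps[p@steps$class == "initiation", ]
    for (b in pb[c(1, P)]) {
      row <- init[init$step == if (b %in% c("A", "T")) "init_A/T"
                  else "init_G/C", ]
      acc <- acc + row$dH - 315.15 * row$dS
    }
    expect_equal(dg, acc, tolerance = 1e-12)
  }
})

test_that("strand-swapped presentation of a duplex has identical energy", {
  p <- readNNParams()
  set.seed(11)
  for (trial in 1:10) {
    P <- sample(4:12, 1)
    probe <- or_randSeq(P)
    frag <- or_randSeq(P)  # generally mismatched duplex
    a <- tryCatch(deltaG(duplexAlignment(probe, frag, P), p, 310),
                  error = function(e) NULL)
    b <- tryCatch(deltaG(duplexAlignment(frag, probe, P), p, 310),
                  error = function(e) NULL)
    if (is.null(a) || is.null(b)) next
    expect_equal(a, b, tolerance = 1e-12)
  }
})

test_that("keq follows exp(-dG/RT), is monotone, and clamps overflow", {
  R <- 8.314462618
  expect_equal(keq(0, 315.15), 1)
  expect_equal(keq(-R * 315.15, 315.15), exp(1))
  expect_equal(keq(R * 300 * log(2), 300), 0.5)
  dg <- sort(runif(20, -5e4, 5e4))
  k <- keq(dg, 310)
  expect_true(all(diff(k) < 0))  # strictly decreasing in dG
  expect_true(all(k > 0))
  expect_warning(kk <- keq(-1e7, 310), "clamp")
  expect_true(is.finite(kk))
})

test_that("alignments with fewer than two paired bases are rejected", {
  expect_error(duplexAlignment("ACGT", "AC", 1), "aligned")
  expect_error(duplexAlignment("A_GT", "ACGT", 2), "paired")
  p <- readNNParams()
  expect_error(buildKeqTable("A", c(s = "ACGT"), p), "shorter than 2")
})

test_that("a 2-bp duplex with zeroed tables has zero free energy", {
  p <- readNNParams()
  tab <- p@steps
  tab$dH <- 0; tab$dS <- 0
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write.table(tab, tmp, sep = "\t", row.names = FALSE, quote = FALSE)
  p0 <- readNNParams(tmp)
  expect_equal(deltaG(duplexAlignment("AT", "AT", 2), p0, 315.15), 0)
})

test_that("single AT/TA step example evaluates by hand arithmetic", {
  ## one step, custom table: dH = -33400, dS = -93.7, zero initiation
  p <- readNNParams()
  tab <- p@steps
  tab$dH[tab$class == "initiation"] <- 0
  tab$dS[tab$class == "initiation"] <- 0
  tab$dH[tab$step == "AT/TA"] <- -33400
  tab$dS[tab$step == "AT/TA"] <- -93.7
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write.table(tab, tmp, sep = "\t", row.names = FALSE, quote = FALSE)
  pz <- readNNParams(tmp)
  dg <- deltaG(duplexAlignment("AT", "AT", 2), pz, 315.15, na = 1)
  expect_equal(dg, -33400 + 315.15 * 93.7, tolerance = 1e-12)
})

test_that("mutating one step changes only alignments containing it", {
  p0 <- readNNParams()
  p1 <- scaleStepEnthalpy(p0, "CG/GC", 1.25)
  with_cg <- duplexAlignment("ACGA", "TCGT", 4)
  without_cg <- duplexAlignment("ATTA", "TAAT", 4)
  expect_false(deltaG(with_cg, p1, 310) == deltaG(with_cg, p0, 310))
  expect_equal(deltaG(without_cg, p1, 310), deltaG(without_cg, p0, 310))
  expect_error(scaleStepEnthalpy(p0, "XX/YY", 1.1), "unknown step")
})
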