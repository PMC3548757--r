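## Independent oracles used across the suite. Everything here is written
## as plain, naive R (explicit enumeration, string-keyed lookups straight
## from the loaded parameter rows) so that it shares no code path with
## the implementation it checks.

or_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

or_randSeq <- function(L) paste(sample(c("A", "C", "G", "T"), L,
                                       replace = TRUE), collapse = "")

## environment keyed by "XY/WZ" (top 5'->3' / bottom 3'->5'), both strand
## presentations registered, values c(dH, dS); built from the raw rows
or_stepEnv <- function(params) {
  env <- new.env(parent = emptyenv())
  tab <- params@steps
  rev2 <- function(s) paste(rev(strsplit(s, "")[[1]]), collapse = "")
  for (r in which(tab$class %in% c("match", "mismatch"))) {
    top <- substr(tab$step[r], 1, 2); bot <- substr(tab$step[r], 4, 5)
    v <- c(tab$dH[r], tab$dS[r])
    assign(paste0(top, "/", bot), v, envir = env)
    sym <- paste0(rev2(bot), "/", rev2(top))
    if (!exists(sym, envir = env)) assign(sym, v, envir = env)
  }
  init <- tab[tab$class == "initiation", ]
  env$.init_AT <- c(init$dH[init$step == "init_A/T"],
                    init$dS[init$step == "init_A/T"])
  env$.init_GC <- c(init$dH[init$step == "init_G/C"],
                    init$dS[init$step == "init_G/C"])
  env
}

or_stepLookup <- function(env, top, bottom) {
  hit <- get0(paste0(top, "/", bottom), envir = env, ifnotfound = NULL)
  if (!is.null(hit)) return(hit)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  nmm <- sum(strsplit(top, "")[[1]] != comp[strsplit(bottom, "")[[1]]])
  if (nmm >= 2) return(c(0, 0))
  stop("oracle: no value for ", top, "/", bottom)
}

## free energy of a full gapless duplex: probe 5'->3' over target bases
## laid 3'->5' beneath it (both plain character strings, equal length;
## "_" in the probe marks an abasic position). Nick model: abasic breaks
## the helix; each sub-helix of >= 2 pairs gets steps + two initiation
## terms chosen by its terminal probe bases + the salt term.
or_deltaG <- function(probe, under, params, tempK, na = 1,
                      env = or_stepEnv(params)) {
  pb <- strsplit(probe, "")[[1]]
  ub <- strsplit(under, "")[[1]]
  stopifnot(length(pb) == length(ub))
  ## initiation by the terminal pair: G/C if either base is G or C
  initFor <- function(p) if (pb[p] %in% c("G", "C") ||
                             ub[p] %in% c("G", "C")) env$.init_GC
  else env$.init_AT
  total <- 0
  idx <- seq_along(pb)
  runs <- split(idx[pb != "_"], cumsum(pb == "_")[pb != "_"])
  for (r in runs) {
    if (length(r) < 2L) next
    dH <- 0; dS <- 0
    for (q in seq_len(length(r) - 1L)) {
      p1 <- r[q]; p2 <- r[q + 1L]
      hs <- or_stepLookup(env, paste0(pb[p1], pb[p2]),
                          paste0(ub[p1], ub[p2]))
      dH <- dH + hs[1L]; dS <- dS + hs[2L]
    }
    i1 <- initFor(r[1L]); i2 <- initFor(r[length(r)])
    dH <- dH + i1[1L] + i2[1L]; dS <- dS + i1[2L] + i2[2L]
    total <- total + (dH - tempK * dS) +
      params@saltCoef * (length(r) - 1L) * log(na)
  }
  total
}

## Brute-force washed competitive occupancy: materializes every fragment
## of every strand of the segment and every alignment offset on the
## probe, scoring each duplex with or_deltaG. Weights: q^(j-1) times p
## per fragment end strictly inside the segment.
or_alpha <- function(probe, segment, params, mu, C, washThr = 0,
                     tempK = celsiusToKelvin(42), na = 1) {
  P <- nchar(probe); L <- nchar(segment)
  pcut <- 1 / mu; q <- 1 - pcut
  RT <- 8.314462618 * tempK
  env <- or_stepEnv(params)
  num <- 0; den <- 0
  pb <- strsplit(probe, "")[[1]]
  for (strand in 1:2) {
    t <- if (strand == 1) segment else or_revcomp(segment)
    tb <- strsplit(t, "")[[1]]
    for (i in 1:(L - 1)) for (j in 2:(L - i + 1)) {
      w <- C * pcut^((i > 1) + (i + j - 1 < L)) * q^(j - 1)
      ## the fragment's 5'-most base pairs probe position k (probe-frame
      ## coordinate of the fragment 5' end); probe position p pairs
      ## fragment base k - p + 1, i.e. strand base i + k - p
      for (k in 2:(P + j - 2)) {
        lo <- max(1, k - j + 1); hi <- min(P, k)
        if (hi - lo + 1 < 2) next
        probeWin <- pb[lo:hi]
        underWin <- tb[i + k - (lo:hi)]
        if (sum(probeWin != "_") < 2) next
        dg <- or_deltaG(paste(probeWin, collapse = ""),
                        paste(underWin, collapse = ""),
                        params, tempK, na, env)
        K <- exp(max(min(-dg / RT, 700), -700))
        den <- den + w * K
        if (K >= washThr) num <- num + w * K
      }
    }
  }
  num / (den + 1)
}

## default true synthesis rates for simulations (resequencing-chip-like)
or_trueSynthesis <- function() {
  synthesisModel(c(A = 0.967, C = 0.944, G = 0.908, T = 0.950),
                 c(A = 0.959, C = 0.941, G = 0.953, T = 0.962))
}
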