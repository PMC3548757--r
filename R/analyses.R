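## Model-driven analyses: positional mismatch effects and
## forward/reverse strand intensity ratios.

#' All single-base substitution variants of a sequence
#'
#' @param seq DNA sequence over A, C, G, T of length L.
#' @return data.frame(position, base, sequence) with exactly \code{3*L}
#'   rows; position 1 is the 5' end.
#' @export
substitutionVariants <- function(seq) {
  .checkDNA(seq, "sequence")
  chars <- strsplit(seq, "")[[1]]
  rows <- list()
  for (p in seq_along(chars)) {
    for (b in setdiff(.BASES, chars[p])) {
      v <- chars; v[p] <- b
      rows[[length(rows) + 1L]] <-
        data.frame(position = p, base = b,
                   sequence = paste(v, collapse = ""))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Positional mismatch-effect scan
#'
#' For every distinct probe sequence in the design, predicts the
#' intensity of the perfect-match probe and of all \code{3*L}
#' single-substitution variants under the same model parameters, and
#' aggregates the mismatch/perfect intensity ratio by substitution
#' position. Position 1 is the probe's 5' end. Under target
#' fragmentation, more fragments can cover the center of a probe than an
#' edge, so central substitutions depress intensity the most.
#'
#' @inheritParams predictIntensities
#' @param maxProbes cap on the number of distinct probe sequences
#'   scanned (NULL = all), taken in design order.
#' @return list with \code{per_variant} (probe_id, position, base,
#'   intensity, ratio), \code{perfect} (probe_id, intensity) and
#'   \code{per_position} (position, mean_ratio).
#' @export
mismatchScan <- function(design, synthesis, concentrations, frag,
                         wash = washModel(0), scanner = scannerModel(),
                         params = readNNParams(), tempC = 42, na = 1,
                         cache = NULL, maxProbes = NULL) {
  if (is.null(cache))
    cache <- keqCache(design@segments, params, tempC, na,
                      washGrid = wash@keqThreshold)
  seqs <- unique(design@probes$sequence)
  if (!is.null(maxProbes)) seqs <- utils::head(seqs, maxProbes)
  conc <- .orderedConc(concentrations, cache)
  rates <- .ratesVector(synthesis)
  predictSeqs <- function(sq, ids) {
    fake <- new("ChipDesign",
                probes = data.frame(probe_id = ids, sequence = sq,
                                    strand = "+",
                                    segment_id = cache$segNames[1L],
                                    replicate_group = NA_character_,
                                    locus = ids),
                segments = Biostrings::DNAStringSet(
                  stats::setNames(vapply(cache$segs, .decodeSeq,
                                         character(1)),
                                  cache$segNames)))
    dm <- .designMatrices(fake)
    coef <- .designCoef(dm, cache, frag, wash@keqThreshold)
    a <- .alphaPerProbe(dm, coef, rates, conc)[dm$spotIdx]
    expectedIntensity(a, scanner)
  }
  perVar <- list(); perfect <- list()
  for (si in seq_along(seqs)) {
    sq <- seqs[si]
    vars <- substitutionVariants(sq)
    ints <- predictSeqs(c(sq, vars$sequence),
                        c("pm", sprintf("mm%03d", seq_len(nrow(vars)))))
    pm <- ints[1L]
    perfect[[si]] <- data.frame(probe_id = sq, intensity = pm)
    perVar[[si]] <- data.frame(probe_id = sq, position = vars$position,
                               base = vars$base, intensity = ints[-1L],
                               ratio = ints[-1L] / pm)
  }
  pv <- do.call(rbind, perVar)
  pp <- stats::aggregate(ratio ~ position, pv, mean)
  names(pp)[2L] <- "mean_ratio"
  list(per_variant = pv, perfect = do.call(rbind, perfect),
       per_position = pp)
}

#' Forward/reverse intensity ratios binned by base composition
#'
#' Pairs each forward-strand probe with the reverse-strand probe of the
#' same locus, computes the log(forward/reverse) intensity ratio for the
#' observed and the expected intensities (averaged across chips when a
#' list of chips is given), and bins pairs by the forward probe's
#' composition key \code{(A - T) + (G - C)}. With equal synthesis rates
#' across bases the expected ratio stays near zero (exactly zero up to
#' the small cross-hybridization asymmetry: strand reversal maps each
#' mismatch type onto a different one); unequal rates tilt the curve
#' along the composition key.
#'
#' @param design a \linkS4class{ChipDesign} with locus tags.
#' @param observed named intensities, data.frame(probe_id, intensity), or
#'   a list of such (one per chip).
#' @param expected same shapes as \code{observed}.
#' @param minBinCount bins with fewer pairs are flagged.
#' @return list with \code{per_pair} (locus, key, log_ratio_observed,
#'   log_ratio_expected) and \code{per_bin} (key, mean_observed,
#'   mean_expected, count, flagged).
#' @export
strandRatioBins <- function(design, observed, expected,
                            minBinCount = 50L) {
  toList <- function(x) if (is.list(x) && !is.data.frame(x)) x else list(x)
  obsL <- toList(observed); expL <- toList(expected)
  stopifnot(length(obsL) == length(expL))
  p <- design@probes
  fwd <- p[p$strand == "+", , drop = FALSE]
  rev <- p[p$strand == "-", , drop = FALSE]
  fwd <- fwd[!duplicated(fwd$locus), , drop = FALSE]
  rev <- rev[!duplicated(rev$locus), , drop = FALSE]
  loci <- intersect(fwd$locus, rev$locus)
  unpaired <- length(setdiff(union(fwd$locus, rev$locus), loci))
  if (unpaired) .diagBump("unpaired_probes_skipped", unpaired)
  fwd <- fwd[match(loci, fwd$locus), ]
  rev <- rev[match(loci, rev$locus), ]
  key <- vapply(fwd$sequence, function(s) {
    n <- table(factor(strsplit(s, "")[[1]], levels = .BASES))
    as.integer((n["A"] - n["T"]) + (n["G"] - n["C"]))
  }, 1L, USE.NAMES = FALSE)
  ratioOf <- function(lst, ids1, ids2) {
    m <- sapply(lst, function(x) {
      v <- .observedVector(x, design)
      names(v) <- design@probes$probe_id
      log(pmax(v[ids1], 1) / pmax(v[ids2], 1))
    })
    rowMeans(as.matrix(m))
  }
  lro <- ratioOf(obsL, fwd$probe_id, rev$probe_id)
  lre <- ratioOf(expL, fwd$probe_id, rev$probe_id)
  perPair <- data.frame(locus = loci, key = key,
                        log_ratio_observed = as.numeric(lro),
                        log_ratio_expected = as.numeric(lre))
  agg <- stats::aggregate(cbind(log_ratio_observed, log_ratio_expected)
                          ~ key, perPair, mean)
  cnt <- as.data.frame(table(key = perPair$key), stringsAsFactors = FALSE)
  cnt$key <- as.integer(cnt$key)
  perBin <- merge(agg, cnt, by = "key")
  names(perBin) <- c("key", "mean_observed", "mean_expected", "count")
  perBin$flagged <- perBin$count < minBinCount
  list(per_pair = perPair, per_bin = perBin[order(perBin$key), ])
}
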