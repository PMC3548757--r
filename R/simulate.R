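## Synthetic-chip factory: designs and observed intensities generated
## from the forward model at known parameters.

#' Noise model constructor
#'
#' @param kind "none" or "lognormal_multiplicative".
#' @param sigma log-scale standard deviation of the multiplicative noise.
#' @return a \linkS4class{NoiseModel}.
#' @export
noiseModel <- function(kind = c("lognormal_multiplicative", "none"),
                       sigma = 0) {
  new("NoiseModel", kind = match.arg(kind), sigma = sigma)
}

#' Generate a synthetic chip design
#'
#' Emulates a resequencing-style design: random target segments tiled by
#' forward/reverse probe pairs. Each locus is a probe-length window of a
#' segment queried by two spots — one probe reverse-complementary to the
#' forward strand and one to the reverse strand (i.e. the window sequence
#' itself) — sharing a locus tag. Optionally duplicates spots as
#' replicate groups (same sequence, distinct spot ids).
#'
#' @param nLoci number of loci; the design gets \code{2 * nLoci} probes
#'   plus replicates.
#' @param probeLen probe length (default 25).
#' @param segmentLengths integer vector, one length per target segment;
#'   each must be >= probeLen.
#' @param nReplicateSpots number of spots to duplicate once each.
#' @param seed RNG seed; designs are deterministic given the seed.
#' @return a \linkS4class{ChipDesign}.
#' @export
makeDesign <- function(nLoci, probeLen = 25L, segmentLengths = c(60L, 60L),
                       nReplicateSpots = 0L, seed = 1L) {
  if (any(segmentLengths < probeLen))
    stop("infeasible geometry: every segment length must be >= probeLen")
  stopifnot(nLoci >= 1L, nReplicateSpots >= 0L)
  .withSeed(seed, {
    segs <- vapply(segmentLengths, function(L)
      paste(sample(.BASES, L, replace = TRUE), collapse = ""),
      character(1))
    names(segs) <- sprintf("seg%02d", seq_along(segs))
    segIdx <- sample.int(length(segs), nLoci, replace = TRUE)
    starts <- vapply(segIdx, function(s)
      sample.int(segmentLengths[s] - probeLen + 1L, 1L), 1L)
    rows <- vector("list", nLoci)
    for (l in seq_len(nLoci)) {
      win <- substr(segs[segIdx[l]], starts[l], starts[l] + probeLen - 1L)
      locus <- sprintf("locus%04d", l)
      rows[[l]] <- data.frame(
        probe_id = c(sprintf("pf%04d", l), sprintf("pr%04d", l)),
        sequence = c(.revcomp(win), win),
        strand = c("+", "-"),
        segment_id = names(segs)[segIdx[l]],
        replicate_group = NA_character_,
        locus = locus)
    }
    probes <- do.call(rbind, rows)
    if (nReplicateSpots > 0L) {
      pick <- sample.int(nrow(probes), min(nReplicateSpots, nrow(probes)))
      dup <- probes[pick, , drop = FALSE]
      grp <- sprintf("rg%04d", seq_along(pick))
      probes$replicate_group[pick] <- grp
      dup$replicate_group <- grp
      dup$probe_id <- paste0(dup$probe_id, "_rep")
      probes <- rbind(probes, dup)
    }
    rownames(probes) <- NULL
    new("ChipDesign", probes = probes,
        segments = Biostrings::DNAStringSet(segs))
  })
}

setMethod("show", "ChipDesign", function(object) {
  cat("ChipDesign:", nrow(object@probes), "probe spots (",
      sum(!is.na(object@probes$replicate_group)), "in replicate groups ) over",
      length(object@segments), "segment(s) of length",
      paste(Biostrings::width(object@segments), collapse = ", "), "\n")
})

#' Simulate observed intensities for a design
#'
#' Computes expected intensities with the full forward model at the given
#' true parameters, then applies multiplicative lognormal noise per spot
#' (replicate spots draw independent noise) and clamps to the scanner
#' range [0, MAX].
#'
#' @inheritParams predictIntensities
#' @param noise a \linkS4class{NoiseModel}.
#' @param seed RNG seed for the noise draws.
#' @return data.frame with columns \code{probe_id}, \code{intensity}
#'   (observed) and \code{expected} (noiseless).
#' @export
simulateChip <- function(design, synthesis, concentrations, frag,
                         wash = washModel(0), scanner = scannerModel(),
                         noise = noiseModel("none"), seed = 1L,
                         params = readNNParams(), tempC = 42, na = 1,
                         cache = NULL) {
  stopifnot(is(noise, "NoiseModel"))
  pred <- predictIntensities(design, synthesis, concentrations, frag,
                             wash, scanner, params, tempC, na, cache)
  obs <- pred$expected
  if (noise@kind == "lognormal_multiplicative" && noise@sigma > 0) {
    obs <- .withSeed(seed, {
      pred$expected * exp(stats::rnorm(nrow(pred), 0, noise@sigma))
    })
    obs <- pmin(pmax(obs, 0), scanner@max)
  }
  data.frame(probe_id = pred$probe_id, intensity = obs,
             expected = pred$expected)
}

#' Calibrate the replicate-noise sigma for a target replicate correlation
#'
#' For multiplicative lognormal noise, two same-sequence spots have
#' population Pearson correlation
#' \code{rho = Var(I) / (E[I^2] exp(sigma^2) - E[I]^2)} across spots with
#' noiseless intensities I; solving for sigma gives
#' \code{sigma = sqrt(log((Var(I)/rho + E[I]^2) / E[I^2]))}.
#'
#' @param expected noiseless expected intensities of the spot population
#'   whose replicate correlation is targeted.
#' @param targetCorrelation desired replicate-spot Pearson correlation.
#' @return a \linkS4class{NoiseModel} with the calibrated sigma.
#' @export
calibrateNoiseSigma <- function(expected, targetCorrelation = 0.906) {
  stopifnot(targetCorrelation > 0, targetCorrelation < 1)
  m <- mean(expected); v <- stats::var(expected) * (length(expected) - 1) /
    length(expected)
  e2 <- v + m^2
  arg <- (v / targetCorrelation + m^2) / e2
  if (arg <= 1)
    stop("target correlation not reachable: intensity spread too small")
  noiseModel("lognormal_multiplicative", sigma = sqrt(log(arg)))
}

#' Replicate-spot correlation of one chip
#'
#' Pearson correlation between the first two spots of every replicate
#' group (same probe sequence, different spot).
#'
#' @param design a \linkS4class{ChipDesign} with replicate groups.
#' @param observed named intensities or data.frame(probe_id, intensity).
#' @return correlation across replicate groups.
#' @export
replicateCorrelation <- function(design, observed) {
  obs <- .observedVector(observed, design)
  names(obs) <- design@probes$probe_id
  grp <- split(design@probes$probe_id,
               design@probes$replicate_group)
  grp <- grp[lengths(grp) >= 2L]
  if (length(grp) < 3L) stop("need at least 3 replicate groups")
  a <- vapply(grp, function(g) obs[[g[1L]]], numeric(1))
  b <- vapply(grp, function(g) obs[[g[2L]]], numeric(1))
  stats::cor(a, b)
}

#' Choose segment concentrations spanning the scanner's dynamic range
#'
#' Finds the single shared concentration (all segments equal) for which
#' the design's median occupancy equals a target, via bisection on the
#' log scale. Used to place simulated chips in a realistic intensity
#' regime; equilibrium constants of full-length duplexes vary over many
#' orders of magnitude, so the matching concentration scale is tiny in
#' the model's arbitrary units.
#'
#' @inheritParams predictIntensities
#' @param targetAlpha desired median spot occupancy. Note the effective
#'   occupancy is bounded above by the emitted synthesis-variant
#'   probability mass (probes with two or more synthesis errors bind
#'   nothing), so targets must stay below that ceiling; the default sits
#'   mid-range of the scanner response.
#' @return named numeric of per-segment concentrations.
#' @export
calibrateConcentrations <- function(design, synthesis, frag,
                                    wash = washModel(0),
                                    params = readNNParams(), tempC = 42,
                                    na = 1, targetAlpha = 0.15,
                                    cache = NULL) {
  if (is.null(cache))
    cache <- keqCache(design@segments, params, tempC, na,
                      washGrid = wash@keqThreshold)
  dm <- .designMatrices(design)
  coef <- .designCoef(dm, cache, frag, wash@keqThreshold)
  rates <- .ratesVector(synthesis)
  nseg <- length(cache$segs)
  medAlpha <- function(lc) {
    a <- .alphaPerProbe(dm, coef, rates, rep(exp(lc), nseg))
    stats::median(a[dm$spotIdx])
  }
  lo <- -200; hi <- 50
  if (medAlpha(hi) <= targetAlpha)
    stop("target occupancy ", targetAlpha, " not attainable: the ",
         "synthesis-error model caps the median effective occupancy at ",
         signif(medAlpha(hi), 3))
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    if (medAlpha(mid) < targetAlpha) lo <- mid else hi <- mid
    if (hi - lo < 1e-10) break
  }
  stats::setNames(rep(exp((lo + hi) / 2), nseg), cache$segNames)
}
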