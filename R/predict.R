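## Forward model: design + parameters -> expected spot intensities.

#' Equilibrium-constant cache for a set of segments
#'
#' Builds a reusable cache of aggregated duplex tables. Tables depend
#' only on the variant sequence, the segments, the NN parameters and the
#' temperature/salt, so one cache serves every fragmentation/wash
#' combination (wash thresholds must be drawn from \code{washGrid}) and
#' every optimizer step; chip designs reuse probe sequences heavily, and
#' each distinct sequence is computed once.
#'
#' @param segments named character vector or
#'   \link[Biostrings]{DNAStringSet}.
#' @param params an \linkS4class{NNParameterSet}.
#' @param tempC temperature, degrees Celsius.
#' @param na sodium concentration, molar.
#' @param washGrid wash thresholds that will be queried (0, no wash, is
#'   always available).
#' @param allowLeftOverhang allow fragments to overhang the probe 5' end.
#' @return an opaque cache object.
#' @export
keqCache <- function(segments, params, tempC = 42, na = 1, washGrid = 0,
                     allowLeftOverhang = TRUE) {
  .keqCache(segments, params, tempC, na,
            washGrid[washGrid > 0], allowLeftOverhang)
}

## variant bookkeeping for all distinct probe sequences of a design
.designMatrices <- function(design) {
  seqs <- unique(design@probes$sequence)
  vds <- lapply(seqs, .variantDesign)
  A <- do.call(rbind, lapply(vds, `[[`, "A"))
  fail <- unlist(lapply(vds, `[[`, "fail"))
  vseq <- unlist(lapply(vds, `[[`, "sequences"))
  probeIdx <- rep(seq_along(seqs), vapply(vds, function(v) length(v$fail),
                                          1L))
  list(seqs = seqs, A = A, fail = fail, vseq = vseq, probeIdx = probeIdx,
       spotIdx = match(design@probes$sequence, seqs))
}

## NUM/DEN coefficient matrices for the design's variants under one
## (frag, wash) combination; variants shorter than 2 bases bind nothing
.designCoef <- function(dm, cache, frag, washThreshold) {
  ok <- nchar(dm$vseq) >= 2L
  cm <- .coefMatrices(cache, dm$vseq[ok], frag, washThreshold)
  nseg <- length(cache$segs)
  NUM <- matrix(0, length(dm$vseq), nseg)
  DEN <- matrix(0, length(dm$vseq), nseg)
  NUM[ok, ] <- cm$num
  DEN[ok, ] <- cm$den
  list(num = NUM, den = DEN)
}

## occupancy per distinct probe sequence given rates and concentrations
.alphaPerProbe <- function(dm, coef, rates, conc) {
  pv <- .variantProbs(dm$A, dm$fail, rates)
  av <- as.numeric(coef$num %*% conc) / (as.numeric(coef$den %*% conc) + 1)
  as.numeric(rowsum(pv * av, dm$probeIdx, reorder = TRUE))
}

.ratesVector <- function(synthesis) {
  c(synthesis@incorporation, synthesis@retention)
}

.orderedConc <- function(concentrations, cache) {
  if (is.null(names(concentrations)))
    stop("concentrations must be named by segment")
  miss <- setdiff(cache$segNames, names(concentrations))
  if (length(miss))
    stop("missing concentration for segment(s): ",
         paste(miss, collapse = ", "))
  conc <- concentrations[cache$segNames]
  if (any(!is.finite(conc)) || any(conc < 0))
    stop("concentrations must be finite and >= 0")
  conc
}

#' Predict expected intensities for a chip design
#'
#' Runs the full forward model for every probe spot: synthesis-error
#' variant enumeration, exhaustive cross-hybridization occupancy with
#' fragmentation and wash, and the Gompertz scanner response.
#'
#' @param design a \linkS4class{ChipDesign}.
#' @param synthesis a \linkS4class{SynthesisModel}.
#' @param concentrations named numeric, concentration per segment.
#' @param frag a \linkS4class{FragmentationModel}.
#' @param wash a \linkS4class{WashModel}.
#' @param scanner a \linkS4class{ScannerModel}.
#' @param params an \linkS4class{NNParameterSet}; defaults to the bundled
#'   literature values.
#' @param tempC,na hybridization temperature (Celsius) and [Na+] (M).
#' @param cache optional cache from \code{\link{keqCache}} built for this
#'   design's segments (its wash grid must contain \code{wash}'s
#'   threshold); built on the fly when NULL.
#' @return data.frame with columns \code{probe_id}, \code{alpha},
#'   \code{expected}.
#' @export
predictIntensities <- function(design, synthesis, concentrations, frag,
                               wash = washModel(0),
                               scanner = scannerModel(),
                               params = readNNParams(), tempC = 42, na = 1,
                               cache = NULL) {
  stopifnot(is(design, "ChipDesign"), is(synthesis, "SynthesisModel"),
            is(frag, "FragmentationModel"), is(wash, "WashModel"),
            is(scanner, "ScannerModel"))
  if (is.null(cache))
    cache <- keqCache(design@segments, params, tempC, na,
                      washGrid = wash@keqThreshold)
  conc <- .orderedConc(concentrations, cache)
  dm <- .designMatrices(design)
  coef <- .designCoef(dm, cache, frag, wash@keqThreshold)
  alphaP <- .alphaPerProbe(dm, coef, .ratesVector(synthesis), conc)
  alpha <- alphaP[dm$spotIdx]
  data.frame(probe_id = design@probes$probe_id, alpha = alpha,
             expected = expectedIntensity(alpha, scanner))
}
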