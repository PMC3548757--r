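## Exhaustive cross-hybridization: every fragment of every segment, on
## both strands, aligned at every offset of a probe variant.

.TAIL_LEVELS <- c("both_cut", "left_open", "right_open", "both_open")

.paramsForCpp <- function(params, tempC, na) {
  list(dH = params@dH, dS = params@dS,
       defined = as.integer(params@defined),
       mismatch = as.integer(params@mismatch),
       ## initiation by terminal-pair class: (A/T, G/C)
       initH = params@initH[c(1L, 2L)],
       initS = params@initS[c(1L, 2L)],
       tempK = celsiusToKelvin(tempC),
       saltTerm = params@saltCoef * log(na))
}

.segList <- function(segments) {
  if (is(segments, "DNAStringSet")) {
    nm <- names(segments)
    segments <- stats::setNames(as.character(segments), nm)
  }
  if (is.null(names(segments)) || any(!nzchar(names(segments))))
    stop("segments must be named")
  lapply(segments, function(s) .encodeSeq(as.character(s)))
}

#' Build the exhaustive equilibrium-constant table for a probe variant
#'
#' Enumerates every fragment (start \code{i}, length \code{j >= 2}) of
#' every segment, on both strands, at every alignment offset leaving at
#' least two paired bases on the probe, and computes each duplex's K_eq
#' under the nearest-neighbor model. Fragment bases overhanging the probe
#' are unpaired and contribute no energy. The \code{tail_class} column
#' records which fragment ends lie on the segment boundary (a molecule
#' end, needing no cut): \code{both_cut}, \code{left_open} (5' end of the
#' strand sequence at the boundary), \code{right_open}, \code{both_open}.
#'
#' @param probeVariant probe sequence 5'->3'; may carry at most one abasic
#'   mark (\code{"_"}); length >= 2 after truncation.
#' @param segments named character vector or
#'   \link[Biostrings]{DNAStringSet} of target segments (forward strand).
#' @param params an \linkS4class{NNParameterSet}.
#' @param tempC hybridization temperature, degrees Celsius.
#' @param na sodium concentration, molar.
#' @param prune drop entries with \code{keq < prune * max(keq)};
#'   \code{prune = 0} guarantees exhaustive output.
#' @param allowLeftOverhang allow fragments to overhang the probe's 5'
#'   (left) end; on by default.
#' @param id identifier stored in the table (defaults to the sequence).
#' @return a \linkS4class{KeqTable}.
#' @export
buildKeqTable <- function(probeVariant, segments, params, tempC = 42,
                          na = 1, prune = 1e-12, allowLeftOverhang = TRUE,
                          id = probeVariant) {
  .checkDNA(probeVariant, "probe variant", allowAbasic = TRUE)
  if (nchar(probeVariant) < 2L) stop("probe shorter than 2 bases")
  if (lengths(regmatches(probeVariant,
                         gregexpr("_", probeVariant, fixed = TRUE))) > 1L)
    stop("at most one abasic mark per probe variant is supported")
  segs <- .segList(segments)
  if (!length(segs)) stop("empty segment list")
  pc <- .paramsForCpp(params, tempC, na)
  res <- cpp_keq_entries(.encodeSeq(probeVariant), segs, pc$dH, pc$dS,
                         pc$defined, pc$mismatch, pc$initH, pc$initS,
                         pc$tempK, pc$saltTerm, allowLeftOverhang)
  if (attr(res, "undef_steps") > 0)
    .diagBump("undefined_double_mismatch_steps", attr(res, "undef_steps"))
  if (attr(res, "clamped") > 0) .diagBump("keq_exponent_clamped",
                                          attr(res, "clamped"))
  e <- data.frame(segment = names(segs)[res$segment],
                  strand = c("forward", "reverse")[res$strand + 1L],
                  i = res$i, j = res$j, k = res$k,
                  tail_class = .TAIL_LEVELS[res$class + 1L],
                  keq = res$keq, stringsAsFactors = FALSE)
  if (prune > 0 && nrow(e))
    e <- e[e$keq >= prune * max(e$keq), , drop = FALSE]
  rownames(e) <- NULL
  new("KeqTable", probeVariantId = id, entries = e, tempK = pc$tempK,
      na = na)
}

setMethod("show", "KeqTable", function(object) {
  cat("KeqTable for probe variant '", object@probeVariantId, "': ",
      nrow(object@entries), " entries over ",
      length(unique(object@entries$segment)), " segment(s) at T = ",
      object@tempK, " K\n", sep = "")
})

#' Washed competitive fraction of bound probes
#'
#' Langmuir occupancy of one probe spot over its full complex forest:
#' \code{alpha = sum(C*K | K >= K_eqW) / (sum(C*K) + 1)}, where the
#' numerator keeps only duplexes surviving the wash threshold while the
#' denominator counts every complex formed during hybridization. Each
#' entry's concentration is \code{C_n * q^(j-1)} times a factor \code{p}
#' per fragment end created by a cut; ends on the segment boundary (the
#' "open" tail classes) are molecule ends and carry factor 1. For interior
#' fragments this is exactly the geometric fragment concentration
#' \code{C p^2 q^(j-1)}.
#'
#' @param table a \linkS4class{KeqTable}.
#' @param frag a \linkS4class{FragmentationModel}.
#' @param concentrations named numeric, concentration per segment.
#' @param wash a \linkS4class{WashModel} (threshold 0 disables the wash).
#' @return fraction bound, in [0, 1).
#' @export
fractionBound <- function(table, frag, concentrations,
                          wash = washModel(0)) {
  stopifnot(is(table, "KeqTable"), is(frag, "FragmentationModel"),
            is(wash, "WashModel"))
  e <- table@entries
  if (!nrow(e)) return(0)
  segs <- unique(e$segment)
  if (any(!segs %in% names(concentrations)))
    stop("missing concentration for segment(s): ",
         paste(setdiff(segs, names(concentrations)), collapse = ", "))
  C <- concentrations[e$segment]
  if (any(!is.finite(C)) || any(C < 0))
    stop("concentrations must be finite and >= 0")
  nCut <- c(both_cut = 2, left_open = 1, right_open = 1,
            both_open = 0)[e$tail_class]
  w <- C * frag@p^nCut * frag@q^(e$j - 1)
  ck <- w * e$keq
  den <- sum(ck) + 1
  num <- sum(ck[e$keq >= wash@keqThreshold])
  num / den
}

#' Wash model constructor
#'
#' @param keqThreshold equilibrium-constant threshold; duplexes below it
#'   are removed by the wash. 0 disables the wash.
#' @return a \linkS4class{WashModel}.
#' @export
washModel <- function(keqThreshold = 0) {
  new("WashModel", keqThreshold = as.numeric(keqThreshold))
}

setMethod("show", "WashModel", function(object) {
  cat("WashModel: K_eq threshold =", object@keqThreshold,
      if (object@keqThreshold == 0) "(wash disabled)", "\n")
})

## ---------------------------------------------------------------------
## Aggregated fast path.
##
## Duplex energies depend only on the energy window on the probe, so all
## fragments sharing a window are grouped: per (segment, left state,
## right state, window length j) we store the total K_eq and the totals
## restricted to K_eq >= each wash-grid value. Side states: cut (interior
## end, factor p), bnd (segment boundary, factor 1), open (fragment
## extends past the probe; the marginal over all extensions is exactly
## factor q). alpha then needs only a weighted sum over a few hundred
## rows for any (p, wash) combination.

.keqAggregate <- function(probeVariant, segs, pc, washGrid,
                          allowLeftOverhang = TRUE) {
  res <- cpp_keq_agg(.encodeSeq(probeVariant), segs, pc$dH, pc$dS,
                     pc$defined, pc$mismatch, pc$initH, pc$initS,
                     pc$tempK, pc$saltTerm, washGrid, allowLeftOverhang)
  if (attr(res, "undef_steps") > 0)
    .diagBump("undefined_double_mismatch_steps", attr(res, "undef_steps"))
  res$agg
}

## Cache of aggregated tables keyed by variant sequence.
.keqCache <- function(segments, params, tempC, na, washGrid,
                      allowLeftOverhang = TRUE) {
  env <- new.env(parent = emptyenv())
  env$segs <- .segList(segments)
  env$segNames <- names(env$segs)
  env$pc <- .paramsForCpp(params, tempC, na)
  env$washGrid <- sort(unique(as.numeric(washGrid)))
  env$allowLeftOverhang <- allowLeftOverhang
  env$tab <- new.env(parent = emptyenv())
  env
}

.cacheGet <- function(cache, variantSeq) {
  hit <- get0(variantSeq, envir = cache$tab, ifnotfound = NULL)
  if (!is.null(hit)) return(hit)
  agg <- .keqAggregate(variantSeq, cache$segs, cache$pc, cache$washGrid,
                       cache$allowLeftOverhang)
  assign(variantSeq, agg, envir = cache$tab)
  agg
}

## per-segment coefficient matrices for a set of variant sequences under
## one (frag, wash) combination: rows = variants, cols = segments
.coefMatrices <- function(cache, variantSeqs, frag, washThreshold) {
  nseg <- length(cache$segs)
  washIdx <- if (washThreshold <= 0) 0L else {
    m <- match(washThreshold, cache$washGrid)
    if (is.na(m))
      stop("wash threshold ", washThreshold,
           " not in the cache's wash grid")
    m
  }
  f <- function(st) c(frag@p, 1, frag@q)[st + 1L]
  NUM <- matrix(0, length(variantSeqs), nseg)
  DEN <- matrix(0, length(variantSeqs), nseg)
  for (v in seq_along(variantSeqs)) {
    agg <- .cacheGet(cache, variantSeqs[[v]])
    if (!nrow(agg)) next
    w <- f(agg[, 2L]) * f(agg[, 3L]) * frag@q^(agg[, 4L] - 1)
    den <- w * agg[, 5L]
    num <- if (washIdx == 0L) den else w * agg[, 5L + washIdx]
    for (s in seq_len(nseg)) {
      sel <- agg[, 1L] == s
      DEN[v, s] <- sum(den[sel])
      NUM[v, s] <- sum(num[sel])
    }
  }
  list(num = NUM, den = DEN)
}
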