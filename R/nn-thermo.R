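## Nearest-neighbor duplex thermodynamics.
##
## Free energy of a gapless probe/fragment duplex is the sum of
## dinucleotide-step terms dH - T*dS over consecutive paired positions,
## plus helix-initiation terms for the terminal pairs and a [Na+]
## correction per phosphate pair. Equilibrium constants follow as
## K_eq = exp(-dG / (R*T)).

## dense index into the 256-entry lookup arrays; x,y top (probe) bases,
## gw,gz the *binding-frame* bases underneath (binding frame = reverse
## complement of the target strand, so a match is base equality).
.stepIndex <- function(x, y, gw, gz) (((x * 4L + y) * 4L + gw) * 4L + gz) + 1L

.parseStepKey <- function(step) {
  if (!grepl("^[ACGT]{2}/[ACGT]{2}$", step)) return(NULL)
  top <- substr(step, 1L, 2L); bot <- substr(step, 4L, 5L)
  tb <- match(strsplit(top, "")[[1]], .BASES) - 1L
  ## bottom strand written 3'->5'; convert to binding frame (complement)
  bb <- match(.COMP[strsplit(bot, "")[[1]]], .BASES) - 1L
  list(x = tb[1L], y = tb[2L], gw = bb[1L], gz = bb[2L])
}

## With A=0,C=1,G=2,T=3, complement(b) == 3-b. The strand-symmetric
## presentation of context (x,y,gw,gz) is (3-gz, 3-gw, 3-y, 3-x): reading
## the duplex from the other strand swaps and reverses both dinucleotides.

.emptyParams <- function(saltCoef) {
  list(steps = data.frame(), dH = numeric(256),
       dS = numeric(256), defined = logical(256), mismatch = logical(256),
       initH = numeric(4), initS = numeric(4), saltCoef = saltCoef)
}

.missingMatchSteps <- function(object) {
  miss <- character(0)
  for (x in 0:3) for (y in 0:3) {
    idx <- .stepIndex(x, y, x, y)  # WC: binding frame equals probe
    if (!object@defined[idx])
      miss <- c(miss, paste0(.BASES[x + 1L], .BASES[y + 1L], "/",
                             .COMP[.BASES[x + 1L]], .COMP[.BASES[y + 1L]]))
  }
  miss
}

#' Load a nearest-neighbor parameter table
#'
#' Reads a TSV with columns \code{step}, \code{dH}, \code{dS}, \code{class}
#' (\code{match}, \code{mismatch} or \code{initiation}); energies in J/mol
#' and J/(K*mol). Step keys use the \code{"XY/WZ"} notation (top strand
#' 5'->3' over bottom strand 3'->5'); initiation rows are keyed
#' \code{init_A/T} and \code{init_G/C}. Both strand-symmetric
#' presentations of each step are registered, so e.g. \code{AT/TA} and its
#' swapped-orientation form resolve identically. The bundled default file
#' carries the unified Watson-Crick values, the 51 published internal
#' mismatch values and the two initiation terms.
#'
#' @param file path to the TSV; \code{NULL} loads the bundled defaults.
#' @param overrides optional data.frame (step, dH, dS, class) replacing
#'   individual entries, e.g. a refitted mismatch table.
#' @param saltCoef Delta-G correction coefficient in J/mol per phosphate
#'   pair, multiplied by \code{ln([Na+])} and (pairs - 1) per helix. The
#'   default is the entropic unified-parameter adjustment; it vanishes at
#'   the 1 M reference concentration.
#' @return an \linkS4class{NNParameterSet}.
#' @export
readNNParams <- function(file = NULL, overrides = NULL, saltCoef = -477) {
  if (is.null(file))
    file <- system.file("extdata", "nn_params_dna.tsv",
                        package = "probeForest", mustWork = TRUE)
  tab <- utils::read.delim(file, comment.char = "#",
                           stringsAsFactors = FALSE)
  need <- c("step", "dH", "dS", "class")
  if (!all(need %in% names(tab)))
    stop("NN parameter file must have columns: ",
         paste(need, collapse = ", "))
  if (anyDuplicated(tab$step)) {
    dup <- tab$step[duplicated(tab$step)][1L]
    stop("duplicate step '", dup, "' in ", file, " (row ",
         which(tab$step == dup)[2L] + 1L, ")")
  }
  if (!is.null(overrides)) {
    stopifnot(all(need %in% names(overrides)))
    hit <- match(overrides$step, tab$step)
    if (anyNA(hit))
      stop("override names unknown step(s): ",
           paste(overrides$step[is.na(hit)], collapse = ", "))
    tab[hit, c("dH", "dS")] <- overrides[, c("dH", "dS")]
  }
  obj <- .emptyParams(saltCoef)
  for (r in seq_len(nrow(tab))) {
    cls <- tab$class[r]
    if (!cls %in% c("match", "mismatch", "initiation"))
      stop("row ", r + 1L, ": unknown class '", cls, "'")
    dH <- tab$dH[r]; dS <- tab$dS[r]
    if (!is.finite(dH) || !is.finite(dS))
      stop("row ", r + 1L, ": malformed dH/dS for step '", tab$step[r], "'")
    if (cls == "initiation") {
      if (tab$step[r] == "init_A/T") bases <- c(1L, 4L)      # A, T
      else if (tab$step[r] == "init_G/C") bases <- c(2L, 3L) # C, G
      else stop("row ", r + 1L, ": initiation step must be ",
                "'init_A/T' or 'init_G/C'")
      obj$initH[bases] <- dH; obj$initS[bases] <- dS
      next
    }
    k <- .parseStepKey(tab$step[r])
    if (is.null(k))
      stop("row ", r + 1L, ": malformed step key '", tab$step[r], "'")
    i1 <- .stepIndex(k$x, k$y, k$gw, k$gz)
    i2 <- .stepIndex(3L - k$gz, 3L - k$gw, 3L - k$y, 3L - k$x)
    for (ii in unique(c(i1, i2))) {
      obj$dH[ii] <- dH; obj$dS[ii] <- dS
      obj$defined[ii] <- TRUE
      obj$mismatch[ii] <- (cls == "mismatch")
    }
  }
  obj$steps <- tab
  new("NNParameterSet", steps = obj$steps, dH = obj$dH, dS = obj$dS,
      defined = obj$defined, mismatch = obj$mismatch, initH = obj$initH,
      initS = obj$initS, saltCoef = obj$saltCoef)
}

#' Scale the enthalpy of one Watson-Crick step
#'
#' Returns a copy of \code{params} with the dH of the named step (and its
#' strand-symmetric presentation) multiplied by \code{ratio}. Used by the
#' one-dimensional nearest-neighbor parameter search.
#'
#' @param params an \linkS4class{NNParameterSet}.
#' @param step step key, e.g. \code{"AA/TT"}.
#' @param ratio multiplicative factor on dH.
#' @return modified \linkS4class{NNParameterSet}.
#' @export
scaleStepEnthalpy <- function(params, step, ratio) {
  k <- .parseStepKey(step)
  if (is.null(k)) stop("unknown step id: ", step)
  i1 <- .stepIndex(k$x, k$y, k$gw, k$gz)
  i2 <- .stepIndex(3L - k$gz, 3L - k$gw, 3L - k$y, 3L - k$x)
  if (!params@defined[i1]) stop("unknown step id: ", step)
  params@dH[unique(c(i1, i2))] <- params@dH[unique(c(i1, i2))] * ratio
  r <- match(step, params@steps$step)
  if (!is.na(r)) params@steps$dH[r] <- params@steps$dH[r] * ratio
  params
}

setMethod("show", "NNParameterSet", function(object) {
  cat("NNParameterSet:",
      sum(object@steps$class == "match"), "WC steps,",
      sum(object@steps$class == "mismatch"), "mismatch steps,",
      "initiation A/T = (", object@initH[1], ",", object@initS[1], "),",
      "G/C = (", object@initH[2], ",", object@initS[2], ")\n")
  cat("  units J/mol, J/(K*mol); salt coefficient", object@saltCoef,
      "J/mol per pair per ln[Na+]\n")
})

## ---------------------------------------------------------------------
## Duplex alignments

#' Gapless probe/fragment duplex alignment
#'
#' Lays a target fragment antiparallel along a probe. The probe is given
#' 5'->3' and may carry abasic marks (\code{"_"}); the fragment is given
#' 5'->3' on its own strand. \code{offset} is the probe position (1-based,
#' 5'->3') paired with the fragment's 5'-most base, so the fragment
#' occupies probe positions \code{offset - j + 1 .. offset} before
#' clipping; bases overhanging either probe end are unpaired and
#' contribute no energy. At least two paired non-abasic positions are
#' required.
#'
#' @param probe probe sequence 5'->3', possibly with \code{"_"} marks.
#' @param fragment fragment sequence 5'->3'.
#' @param offset probe position of the fragment's 5'-most base.
#' @return a list with class \code{"DuplexAlignment"}: probe, fragment,
#'   offset, and \code{pair_states} (match / mismatch / abasic) for the
#'   aligned probe positions \code{first..last}.
#' @export
duplexAlignment <- function(probe, fragment, offset) {
  .checkDNA(probe, "probe", allowAbasic = TRUE)
  .checkDNA(fragment, "fragment")
  P <- nchar(probe); j <- nchar(fragment)
  stopifnot(length(offset) == 1L, offset == round(offset))
  first <- max(1L, offset - j + 1L); last <- min(P, offset)
  if (last - first + 1L < 2L)
    stop("invalid alignment: fewer than 2 aligned positions")
  pb <- strsplit(probe, "")[[1]]
  ## binding frame: reverse complement of the fragment, laid 5'->3' along
  ## the probe; probe position p pairs binding-frame index p-(offset-j)
  bf <- strsplit(.revcomp(fragment), "")[[1]]
  states <- character(last - first + 1L)
  for (p in first:last) {
    b <- bf[p - (offset - j)]
    states[p - first + 1L] <-
      if (pb[p] == "_") "abasic" else if (pb[p] == b) "match" else "mismatch"
  }
  if (sum(states != "abasic") < 2L)
    stop("invalid alignment: fewer than 2 paired (non-abasic) positions")
  structure(list(probe = probe, fragment = fragment, offset = offset,
                 first = first, last = last, pair_states = states),
            class = "DuplexAlignment")
}

#' Duplex free energy under the nearest-neighbor model
#'
#' Sums dinucleotide-step dH - T*dS terms over consecutive paired
#' positions of the alignment, adds initiation terms for the terminal
#' pairs of each helix (G/C initiation when either base of the terminal
#' pair is G or C, A/T otherwise — symmetric in the two strands), and a salt
#' correction per phosphate pair. An abasic probe position breaks the
#' duplex into two sub-helices joined at a nick: the abasic pair and both
#' flanking stacking steps contribute nothing and each sub-helix of at
#' least two pairs incurs its own initiation terms (a single stranded pair
#' left by the nick contributes nothing). Steps whose context carries two
#' mismatched pairs and has no published value contribute zero energy and
#' are counted in \code{\link{pfDiagnostics}}; a missing single-mismatch
#' value is an error naming the step.
#'
#' @param alignment a \code{DuplexAlignment} from
#'   \code{\link{duplexAlignment}}.
#' @param params an \linkS4class{NNParameterSet}.
#' @param tempK temperature in kelvin.
#' @param na sodium concentration, molar.
#' @return free energy in J/mol.
#' @export
deltaG <- function(alignment, params, tempK, na = 1) {
  stopifnot(inherits(alignment, "DuplexAlignment"), tempK > 0, na > 0)
  pb <- .encodeSeq(alignment$probe)
  bf <- .encodeSeq(.revcomp(alignment$fragment))
  first <- alignment$first; last <- alignment$last
  off0 <- alignment$offset - nchar(alignment$fragment)
  ## runs of non-abasic probe positions within the aligned window
  pos <- first:last
  paired <- pb[pos] != 4L
  runs <- rle(paired)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
  total <- 0
  lnNa <- log(na)
  for (r in seq_along(runs$values)) {
    if (!runs$values[r]) next
    a <- pos[starts[r]]; b <- pos[ends[r]]
    len <- b - a + 1L
    if (len < 2L) next
    dH <- 0; dS <- 0
    for (p in a:(b - 1L)) {
      idx <- .stepIndex(pb[p], pb[p + 1L], bf[p - off0], bf[p + 1L - off0])
      if (!params@defined[idx]) {
        nmm <- (pb[p] != bf[p - off0]) + (pb[p + 1L] != bf[p + 1L - off0])
        if (nmm >= 2L) { .diagBump("undefined_double_mismatch_steps"); next }
        stop("no NN parameter for step ",
             .BASES[pb[p] + 1L], .BASES[pb[p + 1L] + 1L], "/",
             .COMP[.BASES[bf[p - off0] + 1L]],
             .COMP[.BASES[bf[p + 1L - off0] + 1L]])
      }
      dH <- dH + params@dH[idx]; dS <- dS + params@dS[idx]
    }
    ## initiation by the terminal pair, G/C if either base of the pair
    ## is G or C — symmetric in the two strands (the partner base is
    ## the complement of the binding-frame base, and {C,G} is closed
    ## under complementation, so the frame base can be tested directly)
    initIdx <- function(p) {
      gc <- pb[p] %in% c(1L, 2L) || bf[p - off0] %in% c(1L, 2L)
      if (gc) 2L else 1L
    }
    dH <- dH + params@initH[initIdx(a)] + params@initH[initIdx(b)]
    dS <- dS + params@initS[initIdx(a)] + params@initS[initIdx(b)]
    total <- total + (dH - tempK * dS) + params@saltCoef * (len - 1L) * lnNa
  }
  total
}

#' Equilibrium constant from free energy
#'
#' \code{K_eq = exp(-dG / (R * T))} with R = 8.314462618 J/(mol*K).
#' Exponents beyond +/-700 are clamped (with a warning) to keep the result
#' finite; the clamp corresponds to K_eq in roughly [1e-304, 1e304].
#'
#' @param dg free energy in J/mol (vectorized).
#' @param tempK temperature in kelvin.
#' @return equilibrium constant(s), strictly positive.
#' @export
keq <- function(dg, tempK) {
  stopifnot(tempK > 0)
  ex <- -dg / (.GAS_CONSTANT * tempK)
  if (any(abs(ex) > 700)) {
    warning("free energy implies exp() overflow; clamping exponent to +/-700")
    ex <- pmin(pmax(ex, -700), 700)
  }
  exp(ex)
}
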