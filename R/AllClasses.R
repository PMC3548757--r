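#' @import methods
#' @importFrom Rcpp sourceCpp
#' @importClassesFrom Biostrings DNAStringSet
#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet width
#' @importFrom stats setNames
#' @useDynLib probeForest, .registration = TRUE
NULL

#' Nearest-neighbor thermodynamic parameter set
#'
#' Holds the dinucleotide-step enthalpy/entropy tables used to score
#' probe/target duplexes: the ten unique Watson-Crick steps, the published
#' internal-mismatch steps, helix initiation terms for terminal G.C and A.T
#' pairs, and the salt-correction coefficient. All energies are stored in
#' J/mol (dH) and J/(K*mol) (dS).
#'
#' Internally the step table is expanded into dense 4x4x4x4 lookup arrays
#' indexed by (top base 1, top base 2, bottom base 1, bottom base 2), with
#' the bottom strand written 3'->5' underneath the top strand, so that both
#' strand-symmetric presentations of every step resolve to the same values.
#'
#' @slot steps data.frame of the loaded rows (step, dH, dS, class).
#' @slot dH,dS numeric arrays of length 256 (dense step lookup).
#' @slot defined logical array of length 256; FALSE marks contexts with no
#'   published value (e.g. most double-mismatch steps), which contribute
#'   zero energy and are counted as diagnostics.
#' @slot initH,initS numeric(4): initiation dH/dS by terminal probe base
#'   (A, C, G, T order).
#' @slot saltCoef numeric(1): Delta-G correction per helix phosphate pair,
#'   multiplied by ln([Na+]); J/mol. Zero effect at 1 M.
#' @exportClass NNParameterSet
setClass("NNParameterSet",
  representation(steps = "data.frame", dH = "numeric", dS = "numeric",
                 defined = "logical", mismatch = "logical",
                 initH = "numeric", initS = "numeric", saltCoef = "numeric"))

setValidity("NNParameterSet", function(object) {
  if (length(object@dH) != 256L || length(object@dS) != 256L ||
      length(object@defined) != 256L)
    return("step lookup arrays must have length 256")
  if (length(object@initH) != 4L || length(object@initS) != 4L)
    return("initiation arrays must have length 4")
  ## every canonical WC step must resolve
  miss <- .missingMatchSteps(object)
  if (length(miss))
    return(paste0("incomplete Watson-Crick step set; missing: ",
                  paste(miss, collapse = ", ")))
  TRUE
})

#' Uniform-fragmentation model with geometric fragment lengths
#'
#' Uniform random cutting of the target: every inter-base junction is cut
#' independently with probability \code{p}, so fragment lengths are
#' geometric with mean \code{mu = 1/p}.
#'
#' @slot mu mean fragment length (bases).
#' @slot p per-junction cut probability, \code{1/mu}.
#' @slot q \code{1 - p}.
#' @exportClass FragmentationModel
setClass("FragmentationModel",
  representation(mu = "numeric", p = "numeric", q = "numeric"))

setValidity("FragmentationModel", function(object) {
  if (length(object@p) != 1L || object@p <= 0 || object@p > 1)
    return("cut probability p must lie in (0, 1]")
  if (abs(object@q - (1 - object@p)) > 1e-12) return("q must equal 1 - p")
  TRUE
})

#' Post-hybridization wash model
#'
#' The wash is modelled as an equilibrium-constant threshold: duplexes with
#' K_eq below the threshold dissociate during the wash and do not
#' contribute to the bound fraction, while competition during the
#' hybridization period itself (the denominator of the occupancy formula)
#' still counts every complex. A threshold of 0 disables the wash.
#'
#' @slot keqThreshold dimensionless equilibrium-constant threshold.
#' @exportClass WashModel
setClass("WashModel", representation(keqThreshold = "numeric"))

setValidity("WashModel", function(object) {
  if (length(object@keqThreshold) != 1L || is.na(object@keqThreshold) ||
      object@keqThreshold < 0)
    return("keqThreshold must be a single non-negative number")
  TRUE
})

#' Scanner response model (Gompertz)
#'
#' Maps the fraction of bound probes to expected fluorescent intensity:
#' \code{I(alpha) = MAX * exp(log(MIN/MAX) * exp(-alpha * GOMP))}, a
#' sigmoid rising from the background intensity MIN at alpha = 0 towards
#' the linear cutoff MAX.
#'
#' @slot min background intensity (scanner units).
#' @slot max linear-cutoff intensity (scanner units).
#' @slot gomp dimensionless shape parameter.
#' @exportClass ScannerModel
setClass("ScannerModel",
  representation(min = "numeric", max = "numeric", gomp = "numeric"))

setValidity("ScannerModel", function(object) {
  if (!(object@min > 0)) return("MIN must be > 0")
  if (!(object@max > object@min)) return("MAX must exceed MIN")
  if (!(object@gomp > 0)) return("GOMP must be > 0")
  TRUE
})

#' Probe synthesis-error model
#'
#' Per-base probabilities that a nucleotide is incorporated correctly
#' during synthesis (no truncation at that base) and that an incorporated
#' nucleotide retains its base afterwards (does not become abasic).
#'
#' @slot incorporation named numeric(4), probabilities for A, C, G, T.
#' @slot retention named numeric(4), probabilities for A, C, G, T.
#' @exportClass SynthesisModel
setClass("SynthesisModel",
  representation(incorporation = "numeric", retention = "numeric"))

setValidity("SynthesisModel", function(object) {
  for (nm in c("incorporation", "retention")) {
    v <- slot(object, nm)
    if (length(v) != 4L || !identical(names(v), c("A", "C", "G", "T")))
      return(paste(nm, "must be numeric(4) named A, C, G, T"))
    if (any(!is.finite(v)) || any(v < 0) || any(v > 1))
      return(paste(nm, "probabilities must lie in [0, 1]"))
  }
  TRUE
})

#' Chip design: probes plus the target segments they can bind
#'
#' @slot probes data.frame with columns probe_id, sequence (5'->3'),
#'   strand ("+"/"-"), segment_id, replicate_group (NA when unreplicated),
#'   locus (ties a forward/reverse probe pair to one target window).
#' @slot segments \link[Biostrings]{DNAStringSet} of target segments
#'   (forward strand), names matching segment_id.
#' @exportClass ChipDesign
setClass("ChipDesign",
  representation(probes = "data.frame", segments = "DNAStringSet"))

setValidity("ChipDesign", function(object) {
  need <- c("probe_id", "sequence", "strand", "segment_id")
  if (!all(need %in% names(object@probes)))
    return(paste("probes must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(object@probes$probe_id))
    return("duplicate probe_id in design")
  bad <- setdiff(unique(object@probes$segment_id), names(object@segments))
  if (length(bad))
    return(paste("probes reference unknown segment_id:",
                 paste(bad, collapse = ", ")))
  if (any(grepl("[^ACGT]", object@probes$sequence)))
    return("probe sequences must be over {A,C,G,T}")
  TRUE
})

#' Exhaustive equilibrium-constant table for one probe variant
#'
#' One row per (segment, strand, fragment start i, fragment length j,
#' offset k, tail class) alignment of a target fragment on the probe.
#' Coordinates i are 1-based on the strand's own 5'->3' sequence (the
#' reverse strand is the reverse complement of the segment); k is the
#' probe-frame position (1-based, 5'->3') of the fragment's 5' end — the
#' probe position paired with its 5'-most base, exceeding the probe
#' length when the fragment overhangs the probe's 3' side.
#' Tail classes record which fragment ends coincide with the
#' segment boundary (no cut needed there): both_cut, left_open,
#' right_open, both_open.
#'
#' @slot probeVariantId character(1).
#' @slot entries data.frame(segment, strand, i, j, k, tail_class, keq).
#' @slot tempK,na hybridization temperature (K) and [Na+] (M) used.
#' @exportClass KeqTable
setClass("KeqTable",
  representation(probeVariantId = "character", entries = "data.frame",
                 tempK = "numeric", na = "numeric"))

setValidity("KeqTable", function(object) {
  e <- object@entries
  need <- c("segment", "strand", "i", "j", "k", "tail_class", "keq")
  if (!all(need %in% names(e)))
    return(paste("entries must have columns:", paste(need, collapse = ", ")))
  if (nrow(e) && any(e$keq <= 0)) return("all keq must be > 0")
  if (anyDuplicated(e[c("segment", "strand", "i", "j", "k", "tail_class")]))
    return("duplicate (segment, strand, i, j, k, tail_class) entry")
  TRUE
})

#' Multiplicative replicate-noise model for simulated chips
#'
#' @slot kind "none" or "lognormal_multiplicative".
#' @slot sigma standard deviation of the log-scale noise.
#' @exportClass NoiseModel
setClass("NoiseModel", representation(kind = "character", sigma = "numeric"))

setValidity("NoiseModel", function(object) {
  if (!object@kind %in% c("none", "lognormal_multiplicative"))
    return("kind must be 'none' or 'lognormal_multiplicative'")
  if (object@sigma < 0) return("sigma must be >= 0")
  TRUE
})

#' Result of fitting the model to one chip
#'
#' @slot synthesis fitted \linkS4class{SynthesisModel}.
#' @slot concentrations named numeric, fitted per-segment concentrations.
#' @slot mu,keqThreshold fragmentation / wash grid point selected (highest
#'   Pearson correlation; ties towards smaller threshold, then smaller mu).
#' @slot objective sum of squared intensity differences at the optimum.
#' @slot corRaw,corLog Pearson correlation between observed and expected
#'   intensities on the raw and log scale.
#' @slot predicted data.frame(probe_id, observed, expected).
#' @slot converged logical; FALSE if the minimizer hit max_iterations.
#' @slot grid data.frame of per-grid-point summaries.
#' @exportClass FitResult
setClass("FitResult",
  representation(synthesis = "SynthesisModel", concentrations = "numeric",
                 mu = "numeric", keqThreshold = "numeric",
                 objective = "numeric", corRaw = "numeric", corLog = "numeric",
                 predicted = "data.frame", converged = "logical",
                 grid = "data.frame"))

setValidity("FitResult", function(object) {
  if (length(object@corRaw) == 1L && is.finite(object@corRaw) &&
      abs(object@corRaw) > 1 + 1e-12) return("corRaw outside [-1, 1]")
  if (length(object@objective) == 1L && is.finite(object@objective) &&
      object@objective < 0) return("objective must be >= 0")
  TRUE
})
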