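## Internal helpers shared across modules.

.BASES <- c("A", "C", "G", "T")
.GAS_CONSTANT <- 8.314462618  # J/(mol*K)

## Integer coding used by the C++ core: A=0, C=1, G=2, T=3, abasic "_"=4.
.encodeSeq <- function(x) {
  v <- match(strsplit(x, "")[[1]], c(.BASES, "_")) - 1L
  if (anyNA(v)) stop("sequence contains characters outside {A,C,G,T,_}: ", x)
  v
}

.decodeSeq <- function(v) paste(c(.BASES, "_")[v + 1L], collapse = "")

.COMP <- c(A = "T", C = "G", G = "C", T = "A")

.revcomp <- function(x) {
  paste(rev(.COMP[strsplit(x, "")[[1]]]), collapse = "")
}

.checkDNA <- function(x, what = "sequence", allowAbasic = FALSE) {
  pat <- if (allowAbasic) "[^ACGT_]" else "[^ACGT]"
  if (length(x) != 1L || is.na(x) || !nzchar(x) || grepl(pat, x))
    stop(what, " must be a non-empty string over {A,C,G,T",
         if (allowAbasic) ",_", "}: got '", x, "'")
  invisible(x)
}

#' Convert degrees Celsius to kelvin
#'
#' Hybridization temperatures are configured in degrees Celsius (the
#' protocol scale); all thermodynamic computation is carried out in kelvin.
#'
#' @param tempC temperature in degrees Celsius.
#' @return temperature in kelvin.
#' @export
celsiusToKelvin <- function(tempC) {
  stopifnot(is.numeric(tempC), all(tempC > -273.15))
  tempC + 273.15
}

## Run code under a fixed RNG state without disturbing the caller's stream.
.withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

## Package-level diagnostics counters (e.g. NN steps with no published
## value, missing observed intensities skipped during fitting).
.diagEnv <- new.env(parent = emptyenv())

.diagBump <- function(name, by = 1L) {
  cur <- get0(name, envir = .diagEnv, ifnotfound = 0L)
  assign(name, cur + by, envir = .diagEnv)
  invisible(NULL)
}

#' Read or reset package diagnostics counters
#'
#' The thermodynamic core counts events that are handled silently by
#' design, such as dinucleotide steps with two mismatched pairs and no
#' published parameter value (scored as zero energy) and missing observed
#' intensities skipped by the fitting objective.
#'
#' @param reset logical; clear the counters after reading.
#' @return named list of counters.
#' @export
pfDiagnostics <- function(reset = FALSE) {
  out <- as.list(.diagEnv)
  if (reset) rm(list = ls(.diagEnv), envir = .diagEnv)
  out
}

.msg <- function(verbose, ...) if (isTRUE(verbose)) message(...)
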