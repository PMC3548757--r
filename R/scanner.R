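## Scanner response: Gompertz map from occupancy to intensity.

#' Scanner model constructor
#'
#' @param min background intensity (scanner units); the intensity of a
#'   spot with nothing bound.
#' @param max linear-cutoff intensity; the supremum of the response.
#' @param gomp Gompertz shape parameter.
#' @return a \linkS4class{ScannerModel}.
#' @export
scannerModel <- function(min = 100, max = 65536, gomp = 7) {
  new("ScannerModel", min = min, max = max, gomp = gomp)
}

setMethod("show", "ScannerModel", function(object) {
  cat("ScannerModel: MIN =", object@min, ", MAX =", object@max,
      ", GOMP =", object@gomp, "\n")
})

#' Expected intensity from fraction bound
#'
#' Gompertz response
#' \code{I(alpha) = MAX * exp(log(MIN/MAX) * exp(-alpha * GOMP))} (natural
#' logarithm): strictly increasing in alpha, equal to the background MIN
#' at alpha = 0, approaching the linear cutoff MAX as alpha grows.
#'
#' @param alpha fraction bound, >= 0 (vectorized).
#' @param model a \linkS4class{ScannerModel}.
#' @return expected intensity in [MIN, MAX).
#' @export
expectedIntensity <- function(alpha, model) {
  stopifnot(is(model, "ScannerModel"))
  validObject(model)
  if (any(!is.finite(alpha)) || any(alpha < 0))
    stop("alpha must be finite and >= 0")
  model@max * exp(log(model@min / model@max) * exp(-alpha * model@gomp))
}
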