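## Probe synthesis errors: truncations and abasic sites.
##
## Synthesis proceeds from the 3' end; base m = 1 is the 3'-most base of
## the probe (the last character of the 5'->3' sequence string). A
## truncation at base m leaves the 3'-anchored prefix 1..m-1; an abasic
## site at base m leaves the full-length backbone with the base lost.
## Probes with two or more errors are assumed not to bind (occupancy 0).

#' Synthesis-error model constructor
#'
#' @param incorporation probabilities that A, C, G, T incorporate
#'   correctly during synthesis (named or in A, C, G, T order).
#' @param retention probabilities that an incorporated A, C, G, T retains
#'   its base (does not become abasic).
#' @return a \linkS4class{SynthesisModel}.
#' @export
synthesisModel <- function(incorporation, retention) {
  fix <- function(v) {
    if (is.null(names(v))) names(v) <- c("A", "C", "G", "T")
    v[c("A", "C", "G", "T")]
  }
  new("SynthesisModel", incorporation = fix(incorporation),
      retention = fix(retention))
}

setMethod("show", "SynthesisModel", function(object) {
  cat("SynthesisModel\n  incorporation:",
      paste(sprintf("%s=%.3f", names(object@incorporation),
                    object@incorporation), collapse = " "),
      "\n  retention:   ",
      paste(sprintf("%s=%.3f", names(object@retention),
                    object@retention), collapse = " "), "\n")
})

#' Probability that a probe is synthesized full length with no errors
#'
#' Product over the probe's base composition of the incorporation and
#' retention probabilities:
#' \code{p_F = prod(S_b^n_b) * prod(B_b^n_b)} for b in A, C, G, T.
#'
#' @param probeSeq probe sequence 5'->3' over A, C, G, T.
#' @param model a \linkS4class{SynthesisModel}.
#' @return probability in [0, 1].
#' @export
fullLengthProbability <- function(probeSeq, model) {
  .checkDNA(probeSeq, "probe")
  stopifnot(is(model, "SynthesisModel"))
  n <- table(factor(strsplit(probeSeq, "")[[1]], levels = c("A", "C", "G", "T")))
  prod(model@incorporation^as.numeric(n)) *
    prod(model@retention^as.numeric(n))
}

#' Enumerate zero- and one-error probe variants with probabilities
#'
#' Emits the full-length probe, every single-abasic variant and every
#' single-truncation variant with exact probabilities; all remaining
#' probability mass (two or more errors) is the residual class, which is
#' assigned zero binding. Base numbering starts at the 3' end (base 1 =
#' 3'-most) because synthesis starts there.
#'
#' Probabilities: full length \code{p_F} as in
#' \code{\link{fullLengthProbability}}; abasic at base m
#' \code{p_F (1 - B_m) / B_m} (computed in the equivalent direct-product
#' form, which also covers \code{B_m = 0}); truncation at base m
#' \code{prod_(b<m)(S_b B_b) * (1 - S_m)} — synthesis halts at the first
#' failed incorporation and all retained bases are intact.
#'
#' @inheritParams fullLengthProbability
#' @return data.frame with columns \code{variant_class} (full /
#'   abasic / truncated), \code{position} (base index from the 3' end; NA
#'   for full), \code{sequence} (5'->3'; abasic sites marked \code{"_"};
#'   truncations may be shorter than 2 bases or empty, and bind nothing),
#'   and \code{probability}; the residual (>= 2 error) mass is in
#'   \code{attr(, "residual")}. Emitted + residual probabilities sum to 1.
#' @export
variantSet <- function(probeSeq, model) {
  .checkDNA(probeSeq, "probe")
  stopifnot(is(model, "SynthesisModel"))
  chars <- strsplit(probeSeq, "")[[1]]
  P <- length(chars)
  S <- model@incorporation[chars]  # indexed 5'->3'
  B <- model@retention[chars]
  ## base m (from 3' end) is character index P - m + 1
  idx3 <- function(m) P - m + 1L
  pF <- prod(S) * prod(B)
  rows <- list()
  rows[[1]] <- data.frame(variant_class = "full", position = NA_integer_,
                          sequence = probeSeq, probability = pF)
  for (m in seq_len(P)) {
    ci <- idx3(m)
    ## abasic at m: all bases incorporated and retained except base m
    ## loses its base: prod(S) * prod(B[-ci]) * (1 - B[ci])
    pA <- prod(S) * prod(B[-ci]) * (1 - B[ci])
    sq <- chars; sq[ci] <- "_"
    rows[[length(rows) + 1L]] <-
      data.frame(variant_class = "abasic", position = m,
                 sequence = paste(sq, collapse = ""), probability = pA)
  }
  for (m in seq_len(P)) {
    below <- if (m > 1L) seq(idx3(m - 1L), P) else integer(0)
    pT <- prod(S[below]) * prod(B[below]) * (1 - S[idx3(m)])
    rows[[length(rows) + 1L]] <-
      data.frame(variant_class = "truncated", position = m,
                 sequence = if (m > 1L)
                   substr(probeSeq, idx3(m - 1L), P) else "",
                 probability = pT)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (any(out$probability < -1e-12))
    stop("negative variant probability; model values outside [0,1]?")
  out$probability <- pmax(out$probability, 0)
  attr(out, "residual") <- max(0, 1 - sum(out$probability))
  out
}

#' Combine per-variant occupancies into one spot occupancy
#'
#' Weighted average of per-variant bound fractions by their synthesis
#' probabilities: \code{alpha = sum(p_x * alpha_x)}; the residual
#' (two-or-more-error) class contributes zero.
#'
#' @param variants data.frame from \code{\link{variantSet}}.
#' @param alpha numeric vector of per-variant bound fractions in [0, 1],
#'   aligned with the rows of \code{variants}.
#' @return spot occupancy in [0, 1].
#' @export
effectiveAlpha <- function(variants, alpha) {
  stopifnot(nrow(variants) == length(alpha))
  if (any(!is.finite(alpha)) || any(alpha < 0) || any(alpha > 1))
    stop("alpha values must lie in [0, 1]")
  sum(variants$probability * alpha)
}

## ---------------------------------------------------------------------
## Vectorized variant machinery for the fit loop.
##
## With rates r = (S_A, S_C, S_G, S_T, B_A, B_C, B_G, B_T), every emitted
## variant probability has the form exp(A %*% log r) * (1 - r[fail]) with
## a count row A and one failing rate (fail = 0 for the full-length
## variant). This lets one matrix product evaluate all variants of all
## probes at every optimizer step.

.variantDesign <- function(probeSeq) {
  chars <- strsplit(probeSeq, "")[[1]]
  P <- length(chars)
  code <- match(chars, .BASES)           # 1..4, indexed 5'->3'
  cnt <- tabulate(code, 4L)
  idx3 <- function(m) P - m + 1L
  seqs <- character(2L * P + 1L)
  A <- matrix(0, 2L * P + 1L, 8L)
  fail <- integer(2L * P + 1L)
  A[1L, ] <- c(cnt, cnt); fail[1L] <- 0L; seqs[1L] <- probeSeq
  r <- 1L
  for (m in seq_len(P)) {        # abasic variants
    r <- r + 1L
    ci <- idx3(m)
    row <- c(cnt, cnt); row[4L + code[ci]] <- row[4L + code[ci]] - 1L
    A[r, ] <- row
    fail[r] <- 4L + code[ci]
    sq <- chars; sq[ci] <- "_"
    seqs[r] <- paste(sq, collapse = "")
  }
  for (m in seq_len(P)) {        # truncation variants
    r <- r + 1L
    below <- if (m > 1L) code[seq(idx3(m - 1L), P)] else integer(0)
    cb <- tabulate(below, 4L)
    A[r, ] <- c(cb, cb)
    fail[r] <- code[idx3(m)]
    seqs[r] <- if (m > 1L) substr(probeSeq, idx3(m - 1L), P) else ""
  }
  list(A = A, fail = fail, sequences = seqs)
}

.variantProbs <- function(A, fail, rates) {
  lr <- log(pmax(rates, .Machine$double.xmin))
  p <- exp(as.numeric(A %*% lr))
  mult <- rep(1, length(fail))
  has <- fail > 0L
  mult[has] <- 1 - rates[fail[has]]
  p * mult
}
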