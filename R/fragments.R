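## Target fragmentation: uniform random cutting with geometrically
## distributed fragment lengths.

#' Fragmentation model from a mean fragment size
#'
#' Uniform cutting places a cut at every inter-base junction independently
#' with probability \code{p}; fragment lengths between cuts are then
#' geometric with mean \code{mu}, giving the mapping \code{p = 1/mu}.
#'
#' @param mu mean fragment length in bases (>= 1).
#' @return a \linkS4class{FragmentationModel}.
#' @export
fragmentationModel <- function(mu) {
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu) || mu < 1)
    stop("mu must be a single number >= 1")
  new("FragmentationModel", mu = mu, p = 1 / mu, q = 1 - 1 / mu)
}

setMethod("show", "FragmentationModel", function(object) {
  cat("FragmentationModel: mu =", object@mu, " (p =", object@p,
      ", q =", object@q, ")\n")
})

#' Concentration of an interior fragment
#'
#' For a fragment created by cuts at both ends (both ends strictly inside
#' the segment), the concentration of a length-\code{j} fragment starting
#' anywhere is \code{C * p^2 * q^(j-1)}: two cuts and \code{j - 1} uncut
#' internal junctions. Position-invariant under uniform cutting.
#'
#' @param C overall concentration of the target segment.
#' @param model a \linkS4class{FragmentationModel}.
#' @param j fragment length in bases (>= 1; vectorized).
#' @return fragment concentration(s).
#' @export
fragmentConcentration <- function(C, model, j) {
  stopifnot(is(model, "FragmentationModel"), C >= 0)
  if (any(j < 1 | j != round(j))) stop("j must be an integer >= 1")
  C * model@p^2 * model@q^(j - 1)
}

#' Concentration of fragments extending past a point
#'
#' Closed form for target molecules with a cut at one end that extend at
#' least \code{j} bases without a further cut and continue an unknown
#' number of bases beyond (e.g. past the end of the probe):
#' \code{C * p * q^j}, the tail sum of the interior-fragment
#' concentrations over all longer extensions.
#'
#' @inheritParams fragmentConcentration
#' @param j number of bases extended without a cut (>= 1; vectorized).
#' @return tail concentration(s).
#' @export
tailConcentration <- function(C, model, j) {
  stopifnot(is(model, "FragmentationModel"), C >= 0)
  if (any(j < 1 | j != round(j))) stop("j must be an integer >= 1")
  C * model@p * model@q^j
}

#' Concentration of fragments running past both reference points
#'
#' The two-sided analogue of \code{\link{tailConcentration}}: fragments
#' spanning a \code{j}-base window with no cut inside it nor at either
#' flanking junction, extending an unknown distance on both sides:
#' \code{C * q^(j+1)}.
#'
#' @inheritParams fragmentConcentration
#' @param j window length in bases (>= 1; vectorized).
#' @return concentration(s).
#' @export
bothOpenConcentration <- function(C, model, j) {
  stopifnot(is(model, "FragmentationModel"), C >= 0)
  if (any(j < 1 | j != round(j))) stop("j must be an integer >= 1")
  C * model@q^(j + 1)
}

#' Enumerate all target subsequences
#'
#' Yields every subsequence (start \code{i}, length \code{j}) of a segment
#' with \code{j >= min_len}, each exactly once — the exhaustive fragment
#' set the hybridization model scores against every probe position. The
#' count for \code{min_len = 2} is \code{L*(L-1)/2}.
#'
#' @param L segment length in bases (or a character segment sequence).
#' @param min_len minimum subsequence length (default 2).
#' @return data.frame with columns \code{i}, \code{j} (1-based inclusive
#'   start; length).
#' @export
enumerateSubsequences <- function(L, min_len = 2L) {
  if (is.character(L)) L <- nchar(L)
  stopifnot(length(L) == 1L, L == round(L), min_len >= 1L)
  if (L < min_len) return(data.frame(i = integer(0), j = integer(0)))
  ii <- integer(0); jj <- integer(0)
  for (j in seq.int(min_len, L)) {
    i <- seq_len(L - j + 1L)
    ii <- c(ii, i); jj <- c(jj, rep.int(j, length(i)))
  }
  d <- data.frame(i = ii, j = jj)
  d <- d[order(d$i, d$j), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Draw fragments from the cutting process
#'
#' Simulates uniform cutting of a length-\code{L} segment: each of the
#' \code{L - 1} junctions is cut independently with probability \code{p};
#' returns the fragments (start, length) of one realization. Segment ends
#' are molecule ends and need no cut.
#'
#' @param L segment length.
#' @param model a \linkS4class{FragmentationModel}.
#' @param n number of independent realizations.
#' @return data.frame with columns \code{rep}, \code{i}, \code{j}.
#' @export
sampleFragments <- function(L, model, n = 1L) {
  stopifnot(is(model, "FragmentationModel"), L >= 1)
  out <- vector("list", n)
  for (r in seq_len(n)) {
    cuts <- which(stats::runif(L - 1L) < model@p)
    starts <- c(1L, cuts + 1L)
    ends <- c(cuts, L)
    out[[r]] <- data.frame(rep = r, i = starts, j = ends - starts + 1L)
  }
  do.call(rbind, out)
}
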