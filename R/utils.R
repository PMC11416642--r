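#' Numerically stable log-sum-exp
#'
#' @param x numeric vector of log-scale values.
#' @return \code{log(sum(exp(x)))} computed without overflow.
#' @export
logSumExp <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Numerically stable log of a difference of exponentials
#'
#' Computes \code{log(exp(a) - exp(b))} for \code{a >= b}. Values of
#' \code{b} exceeding \code{a} by less than \code{tol} are treated as equal
#' (returning \code{-Inf}); larger violations are an error.
#'
#' @param a,b log-scale scalars.
#' @param tol tolerance for \code{b > a} rounding slop.
#' @return log-scale difference.
#' @export
logDiffExp <- function(a, b, tol = 1e-8) {
  if (b > a) {
    if (b - a > tol) {
      stop("logDiffExp: second argument exceeds the first beyond tolerance")
    }
    return(-Inf)
  }
  if (a == b) return(-Inf)
  a + log1p(-exp(b - a))
}

#' Rank-based inverse normal transformation
#'
#' Maps a numeric vector to normal quantiles of its mid-ranks, the transform
#' routinely applied to protein abundance phenotypes before QTL mapping.
#' Ties are broken by average rank.
#'
#' @param x numeric vector.
#' @return transformed vector with (near) standard normal margins.
#' @export
rankInverseNormal <- function(x) {
  stats::qnorm((rank(x, ties.method = "average") - 0.5) / length(x))
}

#' Round half away from zero
#'
#' Base R rounds half to even; benchmark percentages are reported with
#' conventional half-up rounding to match printed tables.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded vector.
#' @export
roundHalfUp <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Counter-based derivation of per-stage seeds from one user-facing seed.
# Keeps derived seeds within 32-bit integer range.
deriveSeed <- function(seed, counter) {
  as.integer((as.numeric(seed) %% 1000003) * 2011 + 7919 * counter) %% 2147483647L
}

softmax <- function(x) {
  m <- max(x)
  e <- exp(x - m)
  e / sum(e)
}
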