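#' Sample from a truncated normal distribution
#'
#' Draws from a normal distribution with underlying mean `mean` and standard
#' deviation `sd`, conditioned on the interval `[lo, hi]`, by inverse-CDF
#' sampling. This is the marginal model of the synthetic field generator:
#' the published per-class descriptive statistics supply `mean`/`sd` and the
#' published extrema supply `lo`/`hi`. Note that the realised moments of a
#' truncated sample differ from the underlying `mean` and `sd`; see
#' [truncnorm_moments()].
#'
#' @param mean,sd Underlying (untruncated) normal parameters; `sd > 0`.
#' @param lo,hi Truncation bounds, `lo < hi`.
#' @param n Number of draws.
#' @param seed Optional integer seed; the same seed gives identical draws.
#' @return A numeric vector of length `n`, all values in `[lo, hi]`.
#' @export
#' @examples
#' x <- sample_truncnorm(6397.26, 281.74, 6026.13, 7012.88, 100, seed = 1)
#' range(x)
sample_truncnorm <- function(mean, sd, lo, hi, n, seed = NULL) {
  if (!is.numeric(sd) || sd <= 0) abort("`sd` must be > 0.")
  if (!(lo < hi)) abort("`lo` must be strictly less than `hi`.")
  if (n < 1) abort("`n` must be at least 1.")
  if (!is.null(seed)) set.seed(seed)
  qtruncnorm(runif(n), mean, sd, lo, hi)
}

# inverse CDF of the truncated normal, u in [0, 1]
qtruncnorm <- function(u, mean, sd, lo, hi) {
  p_lo <- pnorm(lo, mean, sd)
  p_hi <- pnorm(hi, mean, sd)
  x <- qnorm(p_lo + u * (p_hi - p_lo), mean, sd)
  pmin(pmax(x, lo), hi)
}

#' Moments of a truncated normal distribution
#'
#' Closed-form mean and standard deviation of a normal distribution with
#' underlying parameters `mean` and `sd` truncated to `[lo, hi]`. Used to
#' state what sample moments the generator is expected to reproduce: with
#' bounds a modest number of SDs from the mean, the truncated SD is
#' substantially smaller than the underlying `sd`.
#'
#' @inheritParams sample_truncnorm
#' @return A named numeric vector with elements `mean` and `sd`.
#' @export
#' @examples
#' truncnorm_moments(8393, 736.69, 7000, 9500)
truncnorm_moments <- function(mean, sd, lo, hi) {
  if (sd <= 0) abort("`sd` must be > 0.")
  if (!(lo < hi)) abort("`lo` must be strictly less than `hi`.")
  a <- (lo - mean) / sd
  b <- (hi - mean) / sd
  z <- pnorm(b) - pnorm(a)
  m <- mean + sd * (dnorm(a) - dnorm(b)) / z
  v <- sd^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / z -
                 ((dnorm(a) - dnorm(b)) / z)^2)
  c(mean = m, sd = sqrt(v))
}
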