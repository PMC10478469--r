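#' Fit min-max scalers for network inputs and target
#'
#' Per-feature affine maps onto `[-1, 1]` for the three nutrient inputs and
#' for yield. Yield is first converted from kg/ha to t/ha (divide by 1000)
#' so that inverse-scaled predictions — and hence the error metrics — come
#' out in t/ha. The `[-1, 1]` range keeps the tanh hidden layer away from
#' saturation.
#'
#' @param X Numeric matrix or data frame of inputs (n x 3).
#' @param y Numeric vector of yields in kg/ha.
#' @return An object of class `npk_scalers`: per-feature `lo`/`hi` for `X`
#'   and for yield (t/ha).
#' @export
fit_scalers <- function(X, y) {
  X <- as.matrix(X)
  rng <- apply(X, 2, range)
  if (any(rng[1, ] == rng[2, ])) {
    abort("Constant feature: min-max scaling is undefined.")
  }
  y_t <- y / 1000
  if (min(y_t) == max(y_t)) abort("Constant target: scaling is undefined.")
  structure(
    list(x_lo = rng[1, ], x_hi = rng[2, ],
         y_lo = min(y_t), y_hi = max(y_t)),
    class = "npk_scalers"
  )
}

scale_to_unit <- function(v, lo, hi) 2 * (v - lo) / (hi - lo) - 1
scale_from_unit <- function(s, lo, hi) (s + 1) / 2 * (hi - lo) + lo

scale_x <- function(scalers, X) {
  X <- as.matrix(X)
  sweep(sweep(X, 2, scalers$x_lo), 2, (scalers$x_hi - scalers$x_lo) / 2,
        "/") - 1
}

# y in kg/ha -> scaled
scale_y <- function(scalers, y) {
  scale_to_unit(y / 1000, scalers$y_lo, scalers$y_hi)
}

# scaled -> t/ha
unscale_y <- function(scalers, s) {
  scale_from_unit(s, scalers$y_lo, scalers$y_hi)
}
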