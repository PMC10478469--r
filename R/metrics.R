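#' Model accuracy metrics
#'
#' The three accuracy measures used to compare yield models, with `F` the
#' predicted and `T` the true values:
#' coefficient of determination
#' \eqn{R^2 = 1 - \sum(F_i - T_i)^2 / \sum(T_i - \bar T)^2},
#' root mean square error
#' \eqn{RMSE = \sqrt{\sum(F_i - T_i)^2 / n}}, and mean absolute error
#' \eqn{MAE = \sum|F_i - T_i| / n}. When predictions and truths are in
#' t/ha, so are RMSE and MAE.
#'
#' @param predicted,actual Numeric vectors of equal length.
#' @return A scalar.
#' @export
#' @examples
#' eval_r2(c(1, 2, 3), c(1, 2, 4))
#' eval_rmse(c(0, 2), c(0, 0))
#' eval_mae(c(0, 2), c(0, 0))
eval_r2 <- function(predicted, actual) {
  check_metric_input(predicted, actual)
  if (length(actual) < 2 || sd(actual) == 0) {
    abort("R2 is undefined for a constant (or length-1) truth vector.")
  }
  1 - sum((predicted - actual)^2) / sum((actual - mean(actual))^2)
}

#' @rdname eval_r2
#' @export
eval_rmse <- function(predicted, actual) {
  check_metric_input(predicted, actual)
  sqrt(mean((predicted - actual)^2))
}

#' @rdname eval_r2
#' @export
eval_mae <- function(predicted, actual) {
  check_metric_input(predicted, actual)
  mean(abs(predicted - actual))
}

check_metric_input <- function(predicted, actual) {
  if (length(predicted) != length(actual)) {
    abort("`predicted` and `actual` must have equal length.")
  }
  if (length(actual) < 1) abort("Need at least 1 observation.")
  invisible(NULL)
}

#' Relative change between two metric values, in percent
#'
#' `direction = "higher"` reports how much larger `new` is than
#' `reference` (`100 * (new - reference) / reference`);
#' `direction = "decrease"` reports how much smaller
#' (`100 * (reference - new) / reference`). Rounded to one decimal, the
#' presentation used when comparing methods (e.g. an R-squared "12.9%
#' higher", an RMSE "decreased by 86.7%").
#'
#' @param reference Baseline value (non-zero).
#' @param new Comparison value.
#' @param direction `"higher"` or `"decrease"`.
#' @return Percent change, one decimal.
#' @export
#' @examples
#' relative_change(0.85, 0.96, "higher")
#' relative_change(0.45, 0.06, "decrease")
relative_change <- function(reference, new,
                            direction = c("higher", "decrease")) {
  direction <- match.arg(direction)
  if (any(reference == 0)) abort("`reference` must be non-zero.")
  pct <- if (direction == "higher") {
    100 * (new - reference) / reference
  } else {
    100 * (reference - new) / reference
  }
  round(pct, 1)
}
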