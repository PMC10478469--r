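#' Descriptive statistics of a measurement series
#'
#' Max, min, mean, sample standard deviation (n - 1 denominator) and
#' coefficient of variation, the summary layout used throughout the
#' yield-graded survey tables.
#'
#' @param values Numeric vector, `n >= 2`, all finite.
#' @return A one-row tibble: `n`, `max`, `min`, `mean`, `sd`, `cv_percent`
#'   (CV = 100 * sd / mean, rounded to 1 decimal).
#' @export
#' @examples
#' describe(c(6100, 6400, 6350, 6800))
describe <- function(values) {
  if (length(values) < 2) abort("`values` must have at least 2 elements.")
  if (!all(is.finite(values))) abort("`values` must all be finite.")
  m <- mean(values)
  if (m == 0) abort("CV is undefined for a series with mean 0.")
  s <- sd(values)
  tibble(
    n = length(values), max = max(values), min = min(values),
    mean = m, sd = s, cv_percent = cv_percent(s, m)
  )
}

#' Coefficient of variation in percent
#'
#' `100 * sd / mean`, rounded to one decimal — the presentation used in the
#' survey's descriptive tables, applicable directly to published
#' mean/SD pairs.
#'
#' @param sd,mean Standard deviation and mean of the series; `mean != 0`.
#' @return CV in percent, one decimal.
#' @export
#' @examples
#' cv_percent(281.74, 6397.26)
cv_percent <- function(sd, mean) {
  if (any(mean == 0)) abort("CV is undefined for mean 0.")
  round(100 * sd / mean, 1)
}

#' Stage-wise descriptive report of a field table
#'
#' [describe()] applied to yield (per class) and to every
#' stage x analyte x class nutrient series of a field tibble.
#'
#' @param fields A field tibble (see [generate_fields()]).
#' @return A tidy tibble, one row per series: `series` (`"yield"` or an
#'   analyte), `stage` (`NA` for yield), `yield_class`, and the
#'   [describe()] columns.
#' @export
descriptive_report <- function(fields) {
  yield_rows <- fields |>
    dplyr::group_by(.data$yield_class) |>
    dplyr::reframe(describe(.data$yield_kg_ha)) |>
    dplyr::mutate(series = "yield", stage = NA_character_)
  nutrient_rows <- fields |>
    tidyr::pivot_longer(dplyr::all_of(conc_columns()),
                        names_to = c("stage", "series"), names_sep = "_(?=[A-Z])",
                        values_to = "value") |>
    dplyr::group_by(.data$yield_class, .data$stage, .data$series) |>
    dplyr::reframe(describe(.data$value))
  dplyr::bind_rows(yield_rows, nutrient_rows) |>
    dplyr::select("series", "stage", "yield_class", "n", "max", "min",
                  "mean", "sd", "cv_percent")
}

#' Shapiro-Wilk normality assessment of yields
#'
#' Tests whether a yield sample is consistent with a normal distribution,
#' the assumption under which the survey splits fields into two yield
#' grades at 6000 kg/ha.
#'
#' @param yields Numeric vector, `n >= 3`, nonconstant.
#' @param alpha Significance level for the verdict (default 0.05).
#' @return A one-row tibble: `statistic` (Shapiro-Wilk W), `p_value`,
#'   `verdict` (`"consistent with normal"` iff `p_value >= alpha`).
#' @export
normality_assess <- function(yields, alpha = 0.05) {
  if (length(yields) < 3) abort("Need at least 3 observations.")
  if (sd(yields) == 0) abort("Normality test is undefined for constant input.")
  sw <- shapiro.test(yields)
  tibble(
    statistic = unname(sw$statistic), p_value = sw$p.value,
    verdict = if (sw$p.value >= alpha) "consistent with normal" else
      "not consistent with normal"
  )
}

#' Pearson correlation with a two-sided t test
#'
#' Pearson's r between two series and the two-sided p-value of the
#' t statistic `r * sqrt((n - 2) / (1 - r^2))`, flagged for significance at
#' the 0.01 level as in the survey's correlation screening.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`, finite, nonconstant.
#' @return A one-row tibble: `r`, `p_value`, `n`, `significant_at_01`.
#' @export
#' @examples
#' pearson_with_test(1:10, (1:10) * 2 + rnorm(10))
pearson_with_test <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 3) abort("Need at least 3 observations.")
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    abort("Inputs must be finite.")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Correlation is undefined for a constant series.")
  }
  n <- length(x)
  r <- cor(x, y)
  p <- if (abs(r) == 1) 0 else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tstat), df = n - 2)
  }
  tibble(r = r, p_value = p, n = n, significant_at_01 = p < 0.01)
}

#' Nutrient-yield correlation report of a field table
#'
#' [pearson_with_test()] between every stage x analyte nutrient series and
#' yield, within each yield class — the screening that motivates using
#' petiole concentrations both as monitor variables and as yield
#' predictors.
#'
#' @param fields A field tibble.
#' @return A tidy tibble, one row per stage x analyte x class cell, with
#'   `stage`, `analyte`, `yield_class` and the [pearson_with_test()]
#'   columns.
#' @export
correlation_report <- function(fields) {
  fields |>
    tidyr::pivot_longer(dplyr::all_of(conc_columns()),
                        names_to = c("stage", "analyte"),
                        names_sep = "_(?=[A-Z])", values_to = "value") |>
    dplyr::group_by(.data$stage, .data$analyte, .data$yield_class) |>
    dplyr::reframe(pearson_with_test(.data$value, .data$yield_kg_ha)) |>
    dplyr::arrange(match(.data$stage, npk_stages),
                   match(.data$analyte, npk_analytes), .data$yield_class)
}
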