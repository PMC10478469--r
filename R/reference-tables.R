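#' Published yield descriptive statistics by yield class
#'
#' Descriptive statistics of seed-cotton yield for the two yield grades used
#' throughout the package: fields below the 6000 kg/ha cut-off (`LOW`,
#' surveyed range 4800-6000 kg/ha) and fields at or above it (`HIGH`,
#' 6000-7100 kg/ha). These values parameterise the synthetic generator's
#' yield marginals and are the reference for descriptive-statistics checks.
#'
#' @return A tibble with columns `yield_class`, `mean`, `sd`, `lo`, `hi`
#'   (all kg/ha) and `cv_pct` (printed coefficient of variation, %).
#' @export
#' @examples
#' yield_marginals()
yield_marginals <- function() {
  tibble(
    yield_class = c("HIGH", "LOW"),
    mean = c(6397.26, 5493.09),
    sd = c(281.74, 331.86),
    lo = c(6026.13, 4833.89),
    hi = c(7012.88, 5963.11),
    cv_pct = c(4.4, 6.0)
  )
}

#' Published petiole nutrient descriptive statistics
#'
#' Stage-wise descriptive statistics of petiole sap nitrate-nitrogen
#' (`NO3N`), phosphate-phosphorus (`PO4P`) and potassium (`KK`)
#' concentrations (mg/L), separately for the two yield grades. They define
#' the synthetic generator's nutrient marginals, and their `lo`/`hi` columns
#' are the raw material of the yield-graded monitor intervals (see
#' [build_grade_table()]).
#'
#' @return A tibble with columns `yield_class`, `stage`, `analyte`, `mean`,
#'   `sd`, `lo`, `hi` (mg/L) and `cv_pct` (printed CV, %).
#' @export
#' @examples
#' nutrient_marginals()
nutrient_marginals <- function() {
  low <- tribble_marg("LOW", list(
    # stage       analyte  max    min    mean  sd      cv
    c("full_bud",   "NO3N", 9500, 7000, 8393, 736.69, 8.8),
    c("full_bloom", "NO3N", 7000, 5000, 6327, 597.66, 9.5),
    c("full_boll",  "NO3N", 5500, 3000, 4703, 710.26, 15.1),
    c("full_bud",   "PO4P", 180, 85, 152, 28.96, 19.1),
    c("full_bloom", "PO4P", 300, 200, 261, 29.48, 11.3),
    c("full_boll",  "PO4P", 200, 100, 163, 30.24, 18.6),
    c("full_bud",   "KK", 9000, 7000, 8200, 624.22, 7.6),
    c("full_bloom", "KK", 7000, 5000, 6213, 597.54, 9.6),
    c("full_boll",  "KK", 4000, 2000, 3253, 599.27, 18.4)
  ))
  high <- tribble_marg("HIGH", list(
    c("full_bud",   "NO3N", 11000, 9000, 9798, 608.94, 6.2),
    c("full_bloom", "NO3N", 8500, 6500, 7640, 705.95, 9.2),
    c("full_boll",  "NO3N", 7500, 5000, 6556, 842.29, 12.9),
    c("full_bud",   "PO4P", 265, 100, 204, 50.65, 24.8),
    c("full_bloom", "PO4P", 400, 270, 348, 43.98, 12.6),
    c("full_boll",  "PO4P", 300, 185, 252, 38.63, 15.3),
    c("full_bud",   "KK", 10000, 8000, 9230, 578.26, 6.3),
    c("full_bloom", "KK", 8500, 6000, 7574, 813.36, 10.7),
    c("full_boll",  "KK", 6500, 4000, 5580, 725.34, 13.0)
  ))
  dplyr::bind_rows(low, high)
}

tribble_marg <- function(class, rows) {
  purrr::map_dfr(rows, function(r) {
    tibble(
      yield_class = class, stage = r[[1]], analyte = r[[2]],
      mean = as.numeric(r[[5]]), sd = as.numeric(r[[6]]),
      lo = as.numeric(r[[4]]), hi = as.numeric(r[[3]]),
      cv_pct = as.numeric(r[[7]])
    )
  })
}

#' Published nutrient-yield correlation targets
#'
#' The reported stage-wise Pearson correlations between a petiole nutrient
#' and seed-cotton yield, per yield class. Only six of the eighteen
#' stage x analyte x class cells were reported; the remaining cells carry the
#' generator's default target of 0.80 and are marked `reported = FALSE`.
#'
#' @return A tibble with columns `stage`, `analyte`, `yield_class`, `r`
#'   and `reported`.
#' @export
#' @examples
#' dplyr::filter(reference_correlations(), reported)
reference_correlations <- function() {
  grid <- tidyr::expand_grid(
    stage = npk_stages, analyte = npk_analytes, yield_class = npk_classes
  )
  reported <- tibble(
    stage = c("full_bloom", "full_bud", "full_boll",
              "full_boll", "full_bloom", "full_bud"),
    analyte = c("NO3N", "NO3N", "PO4P", "PO4P", "KK", "KK"),
    yield_class = c("LOW", "HIGH", "LOW", "HIGH", "LOW", "HIGH"),
    r_reported = c(0.93, 0.85, 0.92, 0.87, 0.90, 0.81)
  )
  grid |>
    dplyr::left_join(reported, by = c("stage", "analyte", "yield_class")) |>
    dplyr::mutate(
      reported = !is.na(.data$r_reported),
      r = dplyr::coalesce(.data$r_reported, 0.80)
    ) |>
    dplyr::select("stage", "analyte", "yield_class", "r", "reported")
}

#' Published model comparison metrics
#'
#' The reference comparison of the three yield-prediction methods (plain
#' backpropagation `BP`, sparrow-search-initialised `SSO-BP` and
#' grey-wolf-initialised `GWO-BP`) per growth stage, on the 80-field
#' modeling set and the 20-field independent validation set. These cells are
#' inputs to [relative_change()] when reproducing the reported percentage
#' improvements; they are not recomputable from synthetic data because the
#' original field survey is not public.
#'
#' @return A tibble with columns `stage`, `method`, `split`, `n`, `r2`,
#'   `rmse` and `mae` (errors in t/ha).
#' @export
reference_model_metrics <- function() {
  rows <- list(
    c("full_bud", "SSO-BP", 0.85, 0.21, 0.16, 0.96, 0.06, 0.05),
    c("full_bud", "GWO-BP", 0.95, 0.12, 0.10, 0.95, 0.09, 0.08),
    c("full_bud", "BP", 0.82, 0.23, 0.18, 0.85, 0.45, 0.42),
    c("full_bloom", "SSO-BP", 0.85, 0.20, 0.17, 0.95, 0.07, 0.06),
    c("full_bloom", "GWO-BP", 0.91, 0.16, 0.13, 0.91, 0.10, 0.08),
    c("full_bloom", "BP", 0.83, 0.22, 0.17, 0.83, 0.12, 0.11),
    c("full_boll", "SSO-BP", 0.93, 0.17, 0.12, 0.91, 0.09, 0.07),
    c("full_boll", "GWO-BP", 0.96, 0.11, 0.08, 0.90, 0.10, 0.08),
    c("full_boll", "BP", 0.88, 0.19, 0.14, 0.88, 0.17, 0.15)
  )
  purrr::map_dfr(rows, function(r) {
    tibble(
      stage = r[[1]], method = r[[2]],
      split = c("modeling", "validation"),
      n = c(80L, 20L),
      r2 = as.numeric(c(r[[3]], r[[6]])),
      rmse = as.numeric(c(r[[4]], r[[7]])),
      mae = as.numeric(c(r[[5]], r[[8]]))
    )
  })
}
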