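#' Fit and compare the yield models on survey and validation fields
#'
#' The modeling/validation protocol: for each growth stage, the stage's
#' three petiole concentrations are the inputs and yield the target; each
#' method (`"BP"`, `"SSO-BP"`, `"GWO-BP"`) is fitted on all survey fields
#' and evaluated on both the survey ("modeling") and the independent
#' validation split, in t/ha. Under the default synthetic survey this
#' gives the canonical 80-field modeling / 20-field validation layout.
#'
#' Per-stage seeds are derived deterministically from `seed`; within a
#' stage, the plain network's initialisation seed and the optimizers'
#' seed are shared across methods so comparisons are paired.
#'
#' @param survey Field tibble of retained survey records.
#' @param validation Field tibble of independent validation records.
#' @param methods Character subset of `c("SSO-BP", "GWO-BP", "BP")`.
#' @param stages Character subset of the growth stages.
#' @param bp_config A [bp_config()] (its seed is overridden per stage).
#' @param opt_config An [optimizer_config()] template (algorithm and seed
#'   overridden per method/stage).
#' @param seed Base integer seed.
#' @return An `npk_report`: a tibble with one row per
#'   stage x method x split (`stage`, `method`, `split`, `n`, `r2`,
#'   `rmse`, `mae`; errors in t/ha), carrying the fitted models in
#'   `attr(, "models")`.
#' @export
#' @examples
#' \donttest{
#' spec <- generator_spec(seed = 42)
#' fields <- generate_fields(spec)
#' report <- run_protocol(
#'   dplyr::filter(fields, split == "survey"),
#'   dplyr::filter(fields, split == "validation"),
#'   stages = "full_bud", seed = 1
#' )
#' report
#' }
run_protocol <- function(survey, validation,
                         methods = c("SSO-BP", "GWO-BP", "BP"),
                         stages = npk_stages,
                         bp_config = petiolenpk::bp_config(),
                         opt_config = optimizer_config("SSO"),
                         seed = 1) {
  methods <- match.arg(methods, several.ok = TRUE)
  stages <- match.arg(stages, npk_stages, several.ok = TRUE)
  models <- list()
  rows <- purrr::map_dfr(seq_along(stages), function(si) {
    stage <- stages[si]
    cols <- paste(stage, npk_analytes, sep = "_")
    if (!all(cols %in% names(survey)) ||
        !all(cols %in% names(validation))) {
      abort(paste0("Missing concentration columns for stage ", stage, "."))
    }
    stage_seed <- seed + si
    purrr::map_dfr(methods, function(method) {
      algorithm <- switch(method, "BP" = "none",
                          "SSO-BP" = "SSO", "GWO-BP" = "GWO")
      bp_cfg <- bp_config
      bp_cfg$seed <- stage_seed
      opt_cfg <- opt_config
      opt_cfg$seed <- stage_seed + 500L
      if (algorithm != "none") opt_cfg$algorithm <- algorithm
      fit <- optimize_then_train(algorithm, survey[cols],
                                 survey$yield_kg_ha, bp_cfg, opt_cfg)
      models[[paste(stage, method, sep = ".")]] <<- fit
      purrr::map_dfr(
        list(modeling = survey, validation = validation),
        function(split_data) {
          pred <- bp_forward(fit, split_data[cols])
          truth <- split_data$yield_kg_ha / 1000
          tibble(n = length(truth),
                 r2 = eval_r2(pred, truth),
                 rmse = eval_rmse(pred, truth),
                 mae = eval_mae(pred, truth))
        },
        .id = "split"
      ) |>
        dplyr::mutate(stage = stage, method = method, .before = 1)
    })
  })
  structure(
    dplyr::select(rows, "stage", "method", "split", "n", "r2", "rmse",
                  "mae"),
    models = models, seed = seed,
    class = c("npk_report", class(rows))
  )
}

#' Pairwise relative changes between methods of a comparison report
#'
#' [relative_change()] applied to every ordered method pair within each
#' stage and split of an `npk_report` (or any tibble with the same metric
#' columns): R-squared compared as "higher", RMSE and MAE as "decrease".
#'
#' @param report An `npk_report` or compatible tibble.
#' @return A tibble with one row per stage x split x method pair:
#'   `stage`, `split`, `method`, `reference`, `r2_change_pct`,
#'   `rmse_change_pct`, `mae_change_pct` (percent, one decimal).
#' @export
#' @examples
#' relative_change_table(reference_model_metrics())
relative_change_table <- function(report) {
  report <- as_tibble(report)
  purrr::map_dfr(split(report, report[c("stage", "split")]), function(cell) {
    if (nrow(cell) < 2) return(NULL)
    pairs <- tidyr::expand_grid(method = cell$method,
                                reference = cell$method) |>
      dplyr::filter(.data$method != .data$reference)
    purrr::pmap_dfr(pairs, function(method, reference) {
      m <- cell[cell$method == method, ]
      r <- cell[cell$method == reference, ]
      tibble(
        stage = m$stage, split = m$split,
        method = method, reference = reference,
        r2_change_pct = relative_change(r$r2, m$r2, "higher"),
        rmse_change_pct = relative_change(r$rmse, m$rmse, "decrease"),
        mae_change_pct = relative_change(r$mae, m$mae, "decrease")
      )
    })
  })
}

#' @export
tidy.npk_report <- function(x, ...) as_tibble(x)

#' @export
glance.npk_report <- function(x, ...) {
  tibble(
    stages = length(unique(x$stage)),
    methods = length(unique(x$method)),
    n_modeling = max(x$n[x$split == "modeling"]),
    n_validation = max(x$n[x$split == "validation"]),
    best_validation_r2 = max(x$r2[x$split == "validation"])
  )
}

#' @export
autoplot.npk_report <- function(object, metric = c("r2", "rmse", "mae"),
                                ...) {
  metric <- match.arg(metric)
  ggplot2::ggplot(
    as_tibble(object),
    ggplot2::aes(x = .data$stage, y = .data[[metric]],
                 fill = .data$method)
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~split) +
    ggplot2::labs(
      x = NULL, fill = NULL,
      y = switch(metric, r2 = expression(R^2),
                 rmse = "RMSE (t/ha)", mae = "MAE (t/ha)")
    ) +
    ggplot2::theme_minimal()
}

#' Write a comparison report and its relative changes as CSV
#'
#' Metrics are written rounded to 2 decimals and percentages to 1 decimal,
#' the presentation convention of the survey's comparison table.
#'
#' @param report An `npk_report`.
#' @param path Metrics CSV path.
#' @param changes_path Optional path for the pairwise relative-change CSV.
#' @return `report`, invisibly.
#' @export
write_report <- function(report, path, changes_path = NULL) {
  out <- as_tibble(report) |>
    dplyr::mutate(dplyr::across(c("r2", "rmse", "mae"), ~ round(.x, 2)))
  readr::write_csv(out, path, progress = FALSE)
  if (!is.null(changes_path)) {
    readr::write_csv(relative_change_table(report), changes_path,
                     progress = FALSE)
  }
  invisible(report)
}
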