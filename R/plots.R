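#' @export
autoplot.grade_table <- function(object, ...) {
  dat <- as_tibble(object) |>
    dplyr::mutate(
      stage = factor(.data$stage, levels = npk_stages),
      yield_class = factor(.data$yield_class, levels = npk_classes)
    )
  ggplot2::ggplot(
    dat,
    ggplot2::aes(x = .data$stage, ymin = .data$lo, ymax = .data$hi,
                 colour = .data$yield_class)
  ) +
    ggplot2::geom_linerange(position = ggplot2::position_dodge(0.5),
                            linewidth = 2) +
    ggplot2::facet_wrap(~analyte, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "Sufficiency interval (mg/L)",
                  colour = "Yield class") +
    ggplot2::theme_minimal()
}

#' Scatter plot of a nutrient series against yield
#'
#' Visualises the per-class nutrient-yield relationship that underlies
#' both the correlation screening and the yield models.
#'
#' @param fields A field tibble.
#' @param stage Growth stage.
#' @param analyte One of `"NO3N"`, `"PO4P"`, `"KK"`.
#' @return A ggplot object.
#' @export
plot_nutrient_yield <- function(fields, stage = "full_bloom",
                                analyte = "NO3N") {
  col <- paste(stage, analyte, sep = "_")
  if (!col %in% names(fields)) abort(paste0("No column ", col, "."))
  ggplot2::ggplot(
    fields,
    ggplot2::aes(x = .data[[col]], y = .data$yield_kg_ha,
                 colour = .data$yield_class)
  ) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = paste0(analyte, " at ", gsub("_", " ", stage),
                             " (mg/L)"),
                  y = "Yield (kg/ha)", colour = "Yield class") +
    ggplot2::theme_minimal()
}
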