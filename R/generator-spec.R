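#' Specify the synthetic field-survey generator
#'
#' Bundles everything [generate_fields()] needs: per-class truncated-normal
#' marginals for yield and for each stage x analyte nutrient series, target
#' nutrient-yield Pearson correlations, sample counts, the abnormal-sample
#' fraction, quantization settings, and a seed. Defaults reproduce the
#' published survey conditions: 30 LOW-class and 50 HIGH-class valid survey
#' fields split at 6000 kg/ha, 20 independent HIGH-class validation fields,
#' a 0.2 abnormal fraction (mirroring 20 of 100 raw fields excluded), the
#' published marginal statistics, the six published correlation targets
#' (0.80 for unreported cells), and instrument-style quantization of
#' readings (nearest 100 mg/L for NO3N and KK, nearest 5 mg/L for PO4P).
#'
#' @param yield Tibble of yield marginals as [yield_marginals()]:
#'   columns `yield_class`, `mean`, `sd`, `lo`, `hi`.
#' @param nutrients Tibble of nutrient marginals as [nutrient_marginals()]:
#'   columns `yield_class`, `stage`, `analyte`, `mean`, `sd`, `lo`, `hi`.
#' @param corr Tibble of correlation targets as [reference_correlations()]:
#'   columns `stage`, `analyte`, `yield_class`, `r`, each `r` in (0, 1).
#' @param n_low,n_high Survey field counts per yield class.
#' @param n_validation Independent validation field count (HIGH-class
#'   parameters).
#' @param outlier_fraction Fraction of records flagged abnormal by
#'   [inject_outliers()]; in `[0, 0.5)`.
#' @param quantize Quantize nutrient readings to instrument-style steps?
#' @param seed Integer seed; the whole dataset is a deterministic function
#'   of the spec.
#' @return An object of class `generator_spec`.
#' @export
#' @examples
#' spec <- generator_spec(seed = 42)
#' spec$counts
generator_spec <- function(yield = yield_marginals(),
                           nutrients = nutrient_marginals(),
                           corr = reference_correlations(),
                           n_low = 30, n_high = 50, n_validation = 20,
                           outlier_fraction = 0.2,
                           quantize = TRUE,
                           seed = 42) {
  spec <- structure(
    list(
      yield = as_tibble(yield)[c("yield_class", "mean", "sd", "lo", "hi")],
      nutrients = as_tibble(nutrients)[
        c("yield_class", "stage", "analyte", "mean", "sd", "lo", "hi")],
      corr = as_tibble(corr)[c("stage", "analyte", "yield_class", "r")],
      counts = c(n_low = as.integer(n_low), n_high = as.integer(n_high),
                 n_validation = as.integer(n_validation)),
      outlier_fraction = outlier_fraction,
      quantize = isTRUE(quantize),
      quant_steps = c(NO3N = 100, PO4P = 5, KK = 100),
      seed = as.integer(seed)
    ),
    class = "generator_spec"
  )
  validate_generator_spec(spec)
}

validate_generator_spec <- function(spec) {
  marg <- dplyr::bind_rows(
    dplyr::mutate(spec$yield, what = "yield"),
    dplyr::mutate(spec$nutrients,
                  what = paste(.data$stage, .data$analyte, sep = "_"))
  )
  bad <- marg$lo >= marg$mean | marg$mean >= marg$hi | marg$sd <= 0
  if (any(bad)) {
    abort(paste0(
      "Invalid marginal(s): every marginal needs lo < mean < hi and sd > 0. ",
      "Offending: ",
      paste(marg$what[bad], marg$yield_class[bad], collapse = "; ")
    ))
  }
  if (any(spec$corr$r < 0 | spec$corr$r >= 1)) {
    off <- spec$corr[spec$corr$r < 0 | spec$corr$r >= 1, ]
    abort(paste0(
      "Correlation targets must lie in [0, 1). Offending: ",
      paste(off$stage, off$analyte, off$yield_class, collapse = "; ")
    ))
  }
  if (nrow(spec$corr) != 18 ||
      anyDuplicated(spec$corr[c("stage", "analyte", "yield_class")])) {
    abort("`corr` must hold exactly one r per stage x analyte x class cell.")
  }
  if (any(spec$counts < 1)) abort("All counts must be at least 1.")
  if (spec$outlier_fraction < 0 || spec$outlier_fraction >= 0.5) {
    abort("`outlier_fraction` must lie in [0, 0.5).")
  }
  spec
}

#' @export
print.generator_spec <- function(x, ...) {
  cat("<generator_spec>\n")
  cat("  survey fields:", x$counts[["n_low"]], "LOW +",
      x$counts[["n_high"]], "HIGH; validation:",
      x$counts[["n_validation"]], "(HIGH)\n")
  cat("  outlier fraction:", x$outlier_fraction,
      " quantize:", x$quantize, " seed:", x$seed, "\n")
  invisible(x)
}

#' Read a generator spec from a YAML or JSON file
#'
#' The file may override any of [generator_spec()]'s scalar settings and,
#' under `marginals:` / `correlations:`, individual table cells. Unlisted
#' values keep their defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` spec file.
#' @return A `generator_spec`.
#' @export
read_generator_spec <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  args <- raw[intersect(
    names(raw),
    c("n_low", "n_high", "n_validation", "outlier_fraction",
      "quantize", "seed")
  )]
  spec <- do.call(generator_spec, args)
  for (ov in raw$correlations) {
    sel <- spec$corr$stage == ov$stage & spec$corr$analyte == ov$analyte &
      spec$corr$yield_class == ov$yield_class
    if (!any(sel)) abort("Unknown correlation cell in spec file.")
    spec$corr$r[sel] <- ov$r
  }
  for (ov in raw$marginals) {
    sel <- spec$nutrients$stage == ov$stage &
      spec$nutrients$analyte == ov$analyte &
      spec$nutrients$yield_class == ov$yield_class
    if (!any(sel)) abort("Unknown marginal cell in spec file.")
    for (f in intersect(names(ov), c("mean", "sd", "lo", "hi"))) {
      spec$nutrients[[f]][sel] <- ov[[f]]
    }
  }
  validate_generator_spec(spec)
}
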