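#' Generate a synthetic yield-graded field survey
#'
#' Draws a complete synthetic survey: `n_low` + `n_high` survey fields and
#' `n_validation` independent validation fields (HIGH-class parameters,
#' emulating an experimental field managed like the high-yield survey
#' fields). Within each yield class, seed-cotton yield and the nine
#' stage x analyte nutrient series are generated jointly from a Gaussian
#' copula with truncated-normal marginals: yield's latent normal score is
#' the common factor, and each nutrient's latent score correlates with it
#' so that the sample Pearson correlation approaches the spec's target.
#' Correlation targeting is rank-based (the latent correlation is set by
#' Spearman matching, `2 * sin(pi * r / 6)`), which survives the monotone
#' truncation and quantization transforms.
#'
#' @param spec A [generator_spec()].
#' @return A tibble with one row per field: `field_id`, `split`
#'   (`"survey"`/`"validation"`), `yield_class`, `yield_kg_ha`, `abnormal`
#'   (all `FALSE`; see [inject_outliers()]), and nine concentration columns
#'   named `{stage}_{analyte}` in mg/L.
#' @export
#' @examples
#' fields <- generate_fields(generator_spec(seed = 42))
#' dplyr::count(fields, split, yield_class)
generate_fields <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  validate_generator_spec(spec)
  set.seed(spec$seed)
  blocks <- list(
    generate_class_block(spec, "LOW", spec$counts[["n_low"]], "survey"),
    generate_class_block(spec, "HIGH", spec$counts[["n_high"]], "survey"),
    generate_class_block(spec, "HIGH", spec$counts[["n_validation"]],
                         "validation")
  )
  out <- dplyr::bind_rows(blocks)
  n_survey <- sum(out$split == "survey")
  out$field_id <- c(sprintf("S%03d", seq_len(n_survey)),
                    sprintf("V%03d", seq_len(nrow(out) - n_survey)))
  dplyr::select(out, "field_id", "split", "yield_class", "yield_kg_ha",
                "abnormal", dplyr::all_of(conc_columns()))
}

generate_class_block <- function(spec, class, n, split) {
  ym <- spec$yield[spec$yield$yield_class == class, ]
  nm <- spec$nutrients[spec$nutrients$yield_class == class, ]
  # canonical column order
  nm <- nm[match(conc_columns(), paste(nm$stage, nm$analyte, sep = "_")), ]
  cr <- spec$corr[spec$corr$yield_class == class, ]
  r <- cr$r[match(paste(nm$stage, nm$analyte, sep = "_"),
                  paste(cr$stage, cr$analyte, sep = "_"))]
  rho <- 2 * sin(pi * r / 6) # Spearman-matched latent correlation
  assert_positive_definite(rho, nm, class)

  z_yield <- rnorm(n)
  yield <- qtruncnorm(pnorm(z_yield), ym$mean, ym$sd, ym$lo, ym$hi)
  conc <- purrr::map(seq_len(nrow(nm)), function(j) {
    z <- rho[j] * z_yield + sqrt(1 - rho[j]^2) * rnorm(n)
    x <- qtruncnorm(pnorm(z), nm$mean[j], nm$sd[j], nm$lo[j], nm$hi[j])
    if (spec$quantize) {
      step <- spec$quant_steps[[nm$analyte[j]]]
      x <- round(x / step) * step
    }
    x
  })
  names(conc) <- paste(nm$stage, nm$analyte, sep = "_")
  tibble(
    field_id = NA_character_, split = split, yield_class = class,
    yield_kg_ha = round(yield, 2), abnormal = FALSE, !!!conc
  )
}

# the one-factor latent correlation matrix (yield score as factor) is
# positive definite whenever all |rho| < 1; checked explicitly so a
# hand-edited spec fails with the offending cells named
assert_positive_definite <- function(rho, nm, class) {
  k <- length(rho)
  m <- diag(1 - rho^2, k) + tcrossprod(rho)
  full <- rbind(c(1, rho), cbind(rho, m))
  ev <- eigen(full, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    abort(paste0(
      "Latent correlation matrix for class ", class,
      " is not positive definite; offending targets: ",
      paste(nm$stage[abs(rho) >= 1], nm$analyte[abs(rho) >= 1],
            collapse = ", ")
    ))
  }
  invisible(full)
}

#' Flag a fraction of fields as abnormal by displacing their yield
#'
#' Emulates the survey's abnormal fields, whose recorded yields deviate
#' grossly from the nutrient-yield relationship: `floor(fraction * n)`
#' randomly chosen records get `abnormal = TRUE` and their yield replaced
#' by a value displaced at least 3 class-SDs from the class mean (random
#' sign, class bounds ignored for the displaced value). All other records
#' are untouched; nutrient readings are
#' never altered, so the displaced fields stand off the per-class yield fit
#' and are the intended prey of [filter_abnormal()].
#'
#' @param records A field tibble from [generate_fields()].
#' @param spec The [generator_spec()] used (supplies class SDs and the
#'   default fraction).
#' @param fraction Fraction of `records` to flag; defaults to
#'   `spec$outlier_fraction`. Must lie in `[0, 0.5)`.
#' @param seed Integer seed for the displacement draws; defaults to
#'   `spec$seed + 1` so the whole raw dataset is one deterministic function
#'   of the spec.
#' @return `records` with `abnormal` set and yields displaced on the
#'   flagged rows.
#' @export
inject_outliers <- function(records, spec, fraction = spec$outlier_fraction,
                            seed = spec$seed + 1L) {
  stopifnot(inherits(spec, "generator_spec"))
  if (fraction < 0 || fraction >= 0.5) {
    abort("`fraction` must lie in [0, 0.5).")
  }
  k <- floor(fraction * nrow(records))
  if (k == 0) return(records)
  set.seed(seed)
  idx <- sample(nrow(records), k)
  class_sd <- setNames(spec$yield$sd, spec$yield$yield_class)
  class_mean <- setNames(spec$yield$mean, spec$yield$yield_class)
  sign <- sample(c(-1, 1), k, replace = TRUE)
  magnitude <- (3 + runif(k)) * class_sd[records$yield_class[idx]]
  records$yield_kg_ha[idx] <- round(
    class_mean[records$yield_class[idx]] + sign * magnitude, 2)
  records$abnormal[idx] <- TRUE
  records
}

#' Write / read a field table as CSV
#'
#' One row per field with the column layout of [generate_fields()]; UTF-8,
#' header row, `.` decimal separator. Two writes of the same tibble are
#' byte-identical.
#'
#' @param fields A field tibble.
#' @param path File path.
#' @return `write_fields()` returns `fields` invisibly; `read_fields()`
#'   returns the field tibble.
#' @export
write_fields <- function(fields, path) {
  readr::write_csv(fields, path, progress = FALSE)
  invisible(fields)
}

#' @rdname write_fields
#' @export
read_fields <- function(path) {
  readr::read_csv(
    path, progress = FALSE,
    col_types = readr::cols(
      field_id = readr::col_character(),
      split = readr::col_character(),
      yield_class = readr::col_character(),
      abnormal = readr::col_logical(),
      .default = readr::col_double()
    )
  )
}
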