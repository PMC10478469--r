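#' Remove abnormal fields that deviate from the nutrient-yield fit
#'
#' Within each yield class and growth stage, yield is regressed on the
#' three petiole concentrations of that stage by ordinary least squares;
#' a field whose studentized residual exceeds `threshold` in magnitude at
#' any stage is removed. The screen runs for `passes` rounds (default 2):
#' gross outliers inflate the first fit's residual scale and can mask one
#' another, so after removing the first round's hits the models are refit
#' once and the survivors are screened again. This is the screening that
#' separated the survey's valid fields from the abnormal ones whose yields
#' deviated grossly from the nutrient-yield relationship.
#'
#' @param records A field tibble with at least 10 records per yield class.
#' @param threshold Studentized-residual cut-off (default 2; `Inf`
#'   disables removal).
#' @param passes Maximum number of flag-and-refit rounds (default 2).
#' @return A list with elements `retained` (field tibble) and `removed`
#'   (field tibble plus `offending_stages`, a comma-separated string of the
#'   stages whose fit flagged the field).
#' @export
#' @examples
#' spec <- generator_spec(seed = 42)
#' raw <- inject_outliers(generate_fields(spec), spec)
#' out <- filter_abnormal(dplyr::filter(raw, split == "survey"))
#' nrow(out$retained)
filter_abnormal <- function(records, threshold = 2, passes = 2) {
  counts <- table(records$yield_class)
  if (any(counts < 10)) {
    abort("Need at least 10 records per yield class to fit the screen.")
  }
  active <- records
  removed_ids <- character(0)
  offending <- character(0)
  for (pass in seq_len(passes)) {
    flags <- matrix(FALSE, nrow(active), length(npk_stages),
                    dimnames = list(NULL, npk_stages))
    for (class in unique(active$yield_class)) {
      in_class <- active$yield_class == class
      if (sum(in_class) < 10) next # too few left to refit reliably
      for (stage in npk_stages) {
        cols <- paste(stage, npk_analytes, sep = "_")
        dat <- active[in_class, c("yield_kg_ha", cols)]
        names(dat) <- c("y", "x1", "x2", "x3")
        fit <- lm(y ~ x1 + x2 + x3, data = dat)
        if (fit$rank < 4) {
          abort(paste0("Singular design matrix for class ", class,
                       " at stage ", stage, "."))
        }
        flags[in_class, stage] <- abs(rstudent(fit)) > threshold
      }
    }
    any_flag <- rowSums(flags) > 0
    if (!any(any_flag)) break
    removed_ids <- c(removed_ids, active$field_id[any_flag])
    offending <- c(offending, apply(
      flags[any_flag, , drop = FALSE], 1,
      function(f) paste(npk_stages[f], collapse = ",")
    ))
    active <- active[!any_flag, ]
  }
  removed <- records[match(removed_ids, records$field_id), ]
  removed$offending_stages <- offending
  list(retained = active, removed = removed)
}
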