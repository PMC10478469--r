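#' Build the yield-graded nutrient monitor table
#'
#' Turns per-cell descriptive statistics into the monitor system: for every
#' stage x yield-class x analyte cell the sufficiency interval is the
#' observed `[min, max]` of that cell. Applied to the published descriptive
#' statistics this reproduces the published monitor table exactly.
#'
#' @param stats A tibble with one row per cell and columns `stage`,
#'   `yield_class`, `analyte`, `min`, `max`; all 18 cells must be present.
#' @param yield_ranges Named character vector labelling each class with its
#'   yield interval (kg/ha).
#' @return A `grade_table`: a tibble with columns `stage`, `yield_class`,
#'   `yield_range`, `analyte`, `lo`, `hi`. Intervals are closed on both
#'   sides.
#' @export
#' @examples
#' build_grade_table(
#'   dplyr::rename(nutrient_marginals(), min = lo, max = hi)
#' )
build_grade_table <- function(stats,
                              yield_ranges = c(LOW = "4800-6000",
                                               HIGH = "6000-7100")) {
  needed <- tidyr::expand_grid(
    stage = npk_stages, yield_class = npk_classes, analyte = npk_analytes
  )
  tab <- dplyr::inner_join(
    needed, as_tibble(stats),
    by = c("stage", "yield_class", "analyte")
  )
  if (nrow(tab) < nrow(needed)) {
    missing <- dplyr::anti_join(needed, tab,
                                by = c("stage", "yield_class", "analyte"))
    abort(paste0(
      "Missing grade cells: ",
      paste(missing$stage, missing$yield_class, missing$analyte,
            collapse = "; ")
    ))
  }
  tab <- tab |>
    dplyr::mutate(lo = .data$min, hi = .data$max,
                  yield_range = unname(yield_ranges[.data$yield_class])) |>
    dplyr::select("stage", "yield_class", "yield_range", "analyte",
                  "lo", "hi")
  if (any(tab$lo >= tab$hi)) {
    bad <- tab[tab$lo >= tab$hi, ]
    abort(paste0("Degenerate interval(s) (lo >= hi): ",
                 paste(bad$stage, bad$yield_class, bad$analyte,
                       collapse = "; ")))
  }
  structure(tab, class = c("grade_table", class(tab)))
}

#' The default monitor table built from the published statistics
#'
#' [build_grade_table()] applied to the published per-cell extrema.
#'
#' @return A `grade_table`.
#' @export
#' @examples
#' default_grade_table()
default_grade_table <- function() {
  build_grade_table(
    dplyr::rename(nutrient_marginals(), min = "lo", max = "hi")
  )
}

#' Classify a petiole sample against the monitor table
#'
#' Checks the three concentrations of one stage against both yield classes'
#' sufficiency intervals (closed intervals; a shared endpoint belongs to
#' both classes). Each analyte contributes a compatibility vote per class;
#' the aggregate class is the majority, with ties resolved to `LOW` — the
#' conservative choice, avoiding over-stating yield potential. Status is
#' `"unique"` when exactly one class receives votes, `"overlap"` when both
#' do, and `"out_of_range"` when any analyte falls outside both intervals
#' (aggregate `"undetermined"` when all three do).
#'
#' @param grade_table A `grade_table` (e.g. [default_grade_table()]).
#' @param stage One of `"full_bud"`, `"full_bloom"`, `"full_boll"`.
#' @param no3,po4,k Petiole concentrations (mg/L), all positive.
#' @return A one-row tibble: `stage`, per-analyte compatible-class strings
#'   (`NO3N_classes`, `PO4P_classes`, `KK_classes`; `""` if none),
#'   `aggregate` (`"LOW"`, `"HIGH"` or `"undetermined"`) and `status`.
#' @export
#' @examples
#' classify_sample(default_grade_table(), "full_bud", 10000, 220, 9500)
classify_sample <- function(grade_table, stage, no3, po4, k) {
  if (!stage %in% npk_stages) {
    abort(paste0("Unknown stage: ", stage, "."))
  }
  conc <- c(NO3N = no3, PO4P = po4, KK = k)
  if (any(conc <= 0)) abort("Concentrations must be positive.")
  votes <- purrr::map(npk_analytes, function(a) {
    cell <- grade_table[grade_table$stage == stage &
                          grade_table$analyte == a, ]
    cls <- cell$yield_class[conc[[a]] >= cell$lo & conc[[a]] <= cell$hi]
    intersect(npk_classes, cls) # fixed order
  })
  names(votes) <- npk_analytes
  tally <- vapply(npk_classes,
                  function(cl) sum(vapply(votes, function(v) cl %in% v,
                                          logical(1))),
                  numeric(1))
  n_empty <- sum(vapply(votes, length, integer(1)) == 0)
  aggregate <- if (all(tally == 0)) "undetermined" else
    if (tally[["HIGH"]] > tally[["LOW"]]) "HIGH" else "LOW"
  status <- if (n_empty > 0) "out_of_range" else
    if (sum(tally > 0) == 1) "unique" else "overlap"
  tibble(
    stage = stage,
    NO3N_classes = paste(votes$NO3N, collapse = ","),
    PO4P_classes = paste(votes$PO4P, collapse = ","),
    KK_classes = paste(votes$KK, collapse = ","),
    aggregate = aggregate, status = status
  )
}

#' Classify every field of a field table at every stage
#'
#' Vectorised [classify_sample()] over a field tibble.
#'
#' @param fields A field tibble.
#' @param grade_table A `grade_table`.
#' @return A tibble with one row per field x stage, the [classify_sample()]
#'   columns plus `field_id` and `yield_class` (the generated truth, for
#'   comparison).
#' @export
classify_fields <- function(fields, grade_table = default_grade_table()) {
  purrr::map_dfr(seq_len(nrow(fields)), function(i) {
    purrr::map_dfr(npk_stages, function(st) {
      row <- classify_sample(
        grade_table, st,
        fields[[paste0(st, "_NO3N")]][i],
        fields[[paste0(st, "_PO4P")]][i],
        fields[[paste0(st, "_KK")]][i]
      )
      dplyr::mutate(row, field_id = fields$field_id[i],
                    yield_class = fields$yield_class[i], .before = 1)
    })
  })
}

#' Write / read a grade table as JSON
#'
#' Serialised as nested objects keyed stage, then yield class, then
#' analyte, each holding the `[lo, hi]` interval in mg/L.
#'
#' @param grade_table A `grade_table`.
#' @param path File path.
#' @return `write_grade_table()` returns the table invisibly;
#'   `read_grade_table()` returns a `grade_table`.
#' @export
write_grade_table <- function(grade_table, path) {
  nested <- purrr::map(split(grade_table, grade_table$stage), function(st) {
    purrr::map(split(st, st$yield_class), function(cl) {
      out <- purrr::map(split(cl, cl$analyte),
                        function(a) c(a$lo, a$hi))
      out$yield_range <- cl$yield_range[1]
      out
    })
  })
  jsonlite::write_json(nested, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(grade_table)
}

#' @rdname write_grade_table
#' @export
read_grade_table <- function(path) {
  nested <- jsonlite::read_json(path, simplifyVector = TRUE)
  rows <- purrr::map_dfr(names(nested), function(st) {
    purrr::map_dfr(names(nested[[st]]), function(cl) {
      cell <- nested[[st]][[cl]]
      purrr::map_dfr(setdiff(names(cell), "yield_range"), function(a) {
        tibble(stage = st, yield_class = cl, analyte = a,
               min = cell[[a]][1], max = cell[[a]][2])
      })
    })
  })
  build_grade_table(rows)
}
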