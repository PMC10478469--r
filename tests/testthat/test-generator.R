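spec42 <- generator_spec(seed = 42)

conc_cols <- function() {
  as.vector(t(outer(c("full_bud", "full_bloom", "full_boll"),
                    c("NO3N", "PO4P", "KK"), paste, sep = "_")))
}

test_that("the default survey has the published layout and class rules", {
  fields <- generate_fields(spec42)
  expect_equal(nrow(fields), 100)
  counts <- dplyr::count(fields, split, yield_class)
  expect_equal(counts$n[counts$split == "survey"], c(50, 30)) # HIGH, LOW
  expect_equal(counts$n[counts$split == "validation"], 20)
  expect_equal(unique(fields$yield_class[fields$split == "validation"]),
               "HIGH")
  expect_true(all(fields$yield_kg_ha[fields$yield_class == "LOW"] < 6000))
  expect_true(all(fields$yield_kg_ha[fields$yield_class == "HIGH"] >= 6000))
  expect_true(all(as.matrix(fields[conc_cols()]) > 0))
  expect_false(any(fields$abnormal))
})

test_that("yields stay inside their class's published bounds", {
  fields <- generate_fields(spec42)
  ym <- yield_marginals()
  for (cl in c("LOW", "HIGH")) {
    y <- fields$yield_kg_ha[fields$yield_class == cl]
    expect_true(all(y >= ym$lo[ym$yield_class == cl] &
                      y <= ym$hi[ym$yield_class == cl]))
  }
})

test_that("quantized readings are exact multiples of their step", {
  fields <- generate_fields(spec42)
  for (col in conc_cols()) {
    step <- if (grepl("PO4P", col)) 5 else 100
    expect_true(all(fields[[col]] %% step == 0), label = col)
  }
})

test_that("regeneration under the same seed is bit-identical, including CSV", {
  f1 <- generate_fields(spec42)
  f2 <- generate_fields(generator_spec(seed = 42))
  expect_identical(f1, f2)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_fields(f1, p1)
  write_fields(f2, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  expect_equal(as.data.frame(read_fields(p1)), as.data.frame(f1))
})

test_that("zero correlation targets yield independent series", {
  corr0 <- dplyr::mutate(reference_correlations(), r = 0)
  spec <- generator_spec(corr = corr0, n_low = 5000, n_high = 5000,
                         n_validation = 1, seed = 5)
  fields <- generate_fields(spec)
  survey <- dplyr::filter(fields, split == "survey")
  for (cl in c("LOW", "HIGH")) {
    dat <- survey[survey$yield_class == cl, ]
    r <- cor(dat$full_bloom_NO3N, dat$yield_kg_ha)
    expect_lt(abs(r), 0.05)
  }
})

test_that("reported correlation targets are recovered at large n", {
  spec <- generator_spec(n_low = 5000, n_high = 5000, n_validation = 1,
                         seed = 9)
  survey <- dplyr::filter(generate_fields(spec), split == "survey")
  low <- survey[survey$yield_class == "LOW", ]
  expect_lt(abs(cor(low$full_bloom_NO3N, low$yield_kg_ha) - 0.93), 0.05)
  high <- survey[survey$yield_class == "HIGH", ]
  expect_lt(abs(cor(high$full_bud_NO3N, high$yield_kg_ha) - 0.85), 0.05)
})

test_that("spec validation names offending entries", {
  expect_error(generator_spec(n_low = 0), "counts")
  expect_error(generator_spec(outlier_fraction = 0.5), "outlier_fraction")
  bad_corr <- reference_correlations()
  bad_corr$r[1] <- 1.2
  expect_error(generator_spec(corr = bad_corr), "\\[0, 1\\)")
  bad_marg <- nutrient_marginals()
  bad_marg$sd[3] <- -1
  expect_error(generator_spec(nutrients = bad_marg), "Invalid marginal")
})

test_that("a YAML spec file can override counts, seed and table cells", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "n_low: 8", "n_high: 9", "seed: 3",
    "correlations:",
    "  - {stage: full_bud, analyte: NO3N, yield_class: LOW, r: 0.5}",
    "marginals:",
    "  - {stage: full_bud, analyte: NO3N, yield_class: LOW, mean: 8000}"
  ), path)
  spec <- read_generator_spec(path)
  expect_equal(unname(spec$counts[c("n_low", "n_high")]), c(8L, 9L))
  expect_equal(spec$seed, 3L)
  expect_equal(
    spec$corr$r[spec$corr$stage == "full_bud" &
                  spec$corr$analyte == "NO3N" &
                  spec$corr$yield_class == "LOW"], 0.5)
  expect_equal(
    spec$nutrients$mean[spec$nutrients$stage == "full_bud" &
                          spec$nutrients$analyte == "NO3N" &
                          spec$nutrients$yield_class == "LOW"], 8000)
})

test_that("outlier injection flags exactly floor(fraction * n) records", {
  fields <- generate_fields(spec42)
  raw <- inject_outliers(fields, spec42, fraction = 0.2)
  expect_equal(sum(raw$abnormal), 20)
  untouched <- raw[!raw$abnormal, ]
  expect_identical(untouched, fields[!raw$abnormal, ])
})

test_that("flagged yields sit at least 3 class-SDs from the class mean", {
  fields <- generate_fields(spec42)
  raw <- inject_outliers(fields, spec42, fraction = 0.2)
  ym <- yield_marginals()
  flagged <- raw[raw$abnormal, ]
  m <- ym$mean[match(flagged$yield_class, ym$yield_class)]
  s <- ym$sd[match(flagged$yield_class, ym$yield_class)]
  expect_true(all(abs(flagged$yield_kg_ha - m) >= 3 * s - 0.01))
})

test_that("zero fraction leaves records untouched; bad fractions error", {
  fields <- generate_fields(spec42)
  expect_identical(inject_outliers(fields, spec42, fraction = 0), fields)
  expect_error(inject_outliers(fields, spec42, fraction = 0.6), "fraction")
  expect_error(inject_outliers(fields, spec42, fraction = -0.1), "fraction")
})
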