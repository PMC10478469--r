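Package: petiolenpk
Title: Yield-Graded Cotton Petiole NPK Monitoring and Neural Yield Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for building and applying a yield-graded nutrient monitoring
    system for drip-irrigated cotton based on petiole sap nitrate-nitrogen,
    phosphate-phosphorus and potassium concentrations at three growth stages,
    and for predicting seed-cotton yield from those concentrations with a
    three-layer backpropagation network whose initial weights are tuned by
    sparrow-search or grey-wolf metaheuristics. Includes a seeded synthetic
    field-survey generator (Gaussian copula over truncated-normal marginals)
    that reproduces the statistical structure of a two-class yield-graded
    survey, descriptive and correlation screening, abnormal-sample filtering
    by studentized residuals, grade-table construction and classification,
    and a comparison protocol reporting R-squared, RMSE and MAE on modeling
    and independent validation sets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    yaml,
    ggplot2,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
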