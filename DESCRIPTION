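Package: tsklm
Title: Granular TSK Linguistic Models for Interval Prediction of Energy Expenditure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits Takagi-Sugeno-Kang linguistic models (TSK-LM) whose fuzzy
    rules are extracted by context-based fuzzy c-means clustering over
    triangular linguistic contexts on the output variable. Predictions are
    fuzzy numbers, reported as lower/modal/upper intervals. Includes the
    conventional linguistic-model baseline, a seeded synthetic generator for
    correlated heart-rate / movement-index / energy-expenditure data, a
    zero-crossing movement-index signal utility, and a repeated train/test
    evaluation harness with RMSE grid search over the numbers of contexts
    and clusters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
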