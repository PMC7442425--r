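Package: safetysignal
Title: Observational Drug-Safety Signal Estimation with Empirical Calibration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for observational drug-safety estimation on
    longitudinal claims-style data: drug-era construction with gap stitching,
    new-user active-comparator cohorts, large-scale LASSO propensity scores
    with quintile stratification and standardized-mean-difference balance
    diagnostics, Cox hazard-ratio estimation conditioned on propensity strata,
    negative-control empirical calibration of p-values and confidence
    intervals, a self-controlled case series estimator fitted by conditional
    Poisson regression, and I-squared-gated random-effects meta-analysis with
    small-cell masking. Ships a synthetic claims-data generator with known
    ground truth so every stage is testable without access to real data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    readr,
    jsonlite,
    glmnet,
    survival,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
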