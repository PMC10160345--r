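Package: nutricook
Title: Predicting Cooked-Food Micronutrient Profiles from Raw Composition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling how cooking changes the micronutrient profile
    of single-ingredient foods. Implements curation of raw/cooked food pairs
    from SR-Legacy-style composition tables, two corrections for the yield
    bias induced by the per-100 g reporting convention (solid-content scaling
    and process-invariant-nutrient scaling), anomaly detection and filtering,
    per-nutrient per-process regression with grid-search cross-validation and
    sequential feature selection, retention-factor baselines, and a synthetic
    data generator with known yields and retentions for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    glmnet,
    nnet,
    purrr,
    ranger,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
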