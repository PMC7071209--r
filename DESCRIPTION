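Package: ppgr
Title: Predicting Postprandial Glycemic Responses from Meal Composition and
    Continuous Glucose Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for predicting postprandial glycemic
    responses (PPGR) in pregnant women with and without gestational diabetes
    from meal composition, glycemic index and load, continuous glucose
    monitoring (CGM) traces, and patient characteristics. Implements a
    five-rule glycemic index assignment hierarchy and mixed-meal GI/GL
    arithmetic, CGM-to-meal-diary record linkage with timing-based exclusion
    rules, extraction of eight PPGR outcome measures (BG60, BGMax, BGRise,
    AUC and incremental AUC over 60 and 120 minutes), record- and
    patient-level data filters, design-matrix assembly with group-mean
    imputation and one-hot encoding, forward stepwise regression, and
    regularized regression (orthogonal matching pursuit, LARS lasso, lasso,
    ridge, elastic net) with grouped cross-validation and patient-level
    train/test splits. A synthetic cohort generator with a planted linear
    PPGR signal provides ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    glmnet,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
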