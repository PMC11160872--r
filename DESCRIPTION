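Package: stagedrisk
Title: Staged Uncertainty-Gated Risk Prediction with Bootstrap Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage (cascade) risk prediction for settings where one block
    of predictors is cheap to collect (clinical variables) and a second block
    is expensive (imaging-derived features). A bootstrap ensemble fit on the
    cheap block yields a per-subject predicted probability and an uncertainty
    (the standard deviation of base-model probabilities); an explicit deferral
    rule retains confident Stage-1 predictions and cascades uncertain subjects
    to a Stage-2 ensemble that also uses the expensive block. Includes the
    surrounding machinery: a synthetic cohort generator, caret-convention
    near-zero-variance and correlation filters with recursive feature
    elimination, spatial-sign preprocessing, threshold tuning by a scaled
    weighted AUC objective, nested cross-validation, DeLong and McNemar model
    comparisons, uncertainty-percentile AUC analysis, and baseline-statistics
    tables (chi-square, Fisher exact, Welch t from group summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
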