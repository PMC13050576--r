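Package: earlygdm
Title: Synthetic-Cohort Machine Learning Pipeline for First-Trimester
    Gestational Diabetes Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a high-risk antenatal cohort with a threshold-triggered
    probabilistic gestational diabetes outcome model, and runs the full
    downstream analysis: leakage-safe preprocessing with SMOTE class
    rebalancing, a seven-method consensus feature-importance ranking, an
    eleven-algorithm classification benchmark with support-weighted metrics,
    additive Shapley-style per-feature attribution (Kernel SHAP), and
    deterministic clinical tiering of first-trimester laboratory values.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    class,
    e1071,
    glmnet,
    jsonlite,
    ranger,
    xgboost
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
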