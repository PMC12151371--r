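Package: adhera
Title: Multi-Scale Medication Adherence Labeling, Simulation and Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for longitudinal medication-adherence analysis from
    electronic pill-bottle (MEMS) event logs. Converts timestamped
    bottle-opening records into daily and weekly adherence labels, builds
    lagged dynamic feature tensors and survey-derived static features,
    simulates synthetic cohorts with planted behavioral structure, and fits
    a dual-branch fusion classifier (LSTM over recent adherence dynamics
    plus a feedforward branch over static covariates) alongside classical
    baselines inside a leakage-safe, subject-level nested cross-validation
    pipeline with SMOTE rebalancing, L1-based feature selection with lag
    expansion, and gradient-based feature attributions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    glmnet,
    randomForest,
    e1071,
    xgboost,
    optparse
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
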