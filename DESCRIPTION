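Package: pdmotor
Title: Digital Motor Assessment Analysis for Parkinson's Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing smartphone-administered motor assessments of
    Parkinson's disease. Simulates raw touchscreen and accelerometer session
    streams for an eleven-task battery with a single latent severity driving
    effect sizes, extracts the per-task feature set (tapping counts and
    intervals, declining-frequency slopes, tracing and drawing kinematics,
    tremor spectral summaries, gait timing), runs repeated-holdout diagnosis
    and severity classification under three labelling schemes across five
    model families, and quantifies feature and task importance with
    Shapley-value attributions, including a tapping-task-only ablation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    nnet,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
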