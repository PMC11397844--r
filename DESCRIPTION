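Package: digibm
Title: Digital Biomarker Feature Engineering and Screening Models for
    Wearable Sensor Assessments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for engineering disease- and behavior-relevant
    features from consumer-grade smartwatch and smartphone sensor streams
    (triaxial accelerometry, voice recordings, touch-event logs and trial
    tables) collected during a multidomain movement-disorder assessment
    battery, and for the downstream analyses a screening study runs on
    them: univariate feature selectivity, Monte-Carlo subject-wise
    cross-validated comparison of nine classifiers under parametric
    feature selection/reduction, cross-environment (clinic vs. home)
    generalization with repeated-measures ANOVA, and intraclass-correlation
    reliability. A built-in synthetic-cohort generator emulates the signal
    classes the pipeline is designed to detect (tremor-band oscillations,
    step impulse trains, glottal pulse trains, tap renewal processes) so
    the full pipeline is testable end to end without access-restricted
    study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    yaml,
    jsonlite,
    signal,
    pracma,
    MASS,
    glmnet,
    e1071,
    rpart,
    nnet,
    ranger,
    xgboost,
    generics,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
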