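Package: ckdwatch
Title: Early Prediction of Canine Chronic Kidney Disease from Longitudinal
    Health Records
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An end-to-end, testable replica of a veterinary clinical
    informatics workflow that predicts future chronic kidney disease (CKD)
    in dogs from routine laboratory results in longitudinal electronic
    health records (EHR).  Provides rule-based cohort labeling anchored on
    an evaluation age (T0), outlier masking and eligibility filtering,
    chained nonparametric imputation of missing laboratory values,
    truncation augmentation for early-detection training, a small
    recurrent neural network trained by backpropagation through time, and
    a prevalence-adjusted, time-horizon evaluation protocol (sensitivity,
    specificity, accuracy, PPV/NPV with normal-approximation intervals).
    A calibrated synthetic-EHR generator supplies cohorts with the
    statistical structure the analysis assumes, so the whole pipeline is
    exercised without access to proprietary hospital records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    ranger,
    readr,
    stats,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
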