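Package: gazerel
Title: Gaze-Derived Relevance Labeling and Modeling for ICU Record Review
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying whether eye-tracking dwell times can replace
    manual checkbox annotation when training models that predict which parts
    of an ICU patient record a physician will find relevant. Includes a
    synthetic-data generator for patient cohorts and review sessions (60 Hz
    gaze streams over a scrolling interface plus manual selections), dynamic
    area-of-interest dwell computation and threshold labeling, clinical
    time-series feature construction with preprocessing and two imputation
    schemes, per-item cross-validated model selection over three classifier
    families, and paired evaluation of gaze-trained versus manually trained
    models with bootstrap AUROC confidence intervals and a Wilcoxon
    signed-rank comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    glmnet,
    e1071,
    ranger
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
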