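Package: lobdetect
Title: Loss-of-Balance Event Detection from Wearable Inertial Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pipeline for detecting loss-of-balance (LOB) events, such as
    trips and slips, in multi-day real-world walking recordings from three
    body-worn inertial measurement units (both feet and the lower trunk).
    Includes strapdown foot-trajectory reconstruction with zero-velocity
    updates, stride segmentation, spatiotemporal gait feature extraction
    over sliding windows, event-overlap labeling, class-imbalance-aware
    training of regularized logistic regression and bidirectional LSTM
    classifiers under leave-one-participant-out validation, window- and
    event-level evaluation with bootstrap confidence intervals, grouped
    permutation feature importance, and a synthetic cohort generator with
    ground-truth events for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
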