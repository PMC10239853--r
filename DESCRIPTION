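Package: deepeeg
Title: Deep EEG Features with Shallow Classifiers for Epileptic Seizure
    Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end pipeline for automatic epileptic seizure detection
    from single-channel EEG epochs. A fixed 24-layer one-dimensional
    convolutional network is trained on raw amplitude vectors; the 23x128
    feature map of its last max-pooling layer is compressed to a
    128-dimensional vector by 128 independent one-component principal
    component projections (one per channel); seven shallow classifiers are
    then evaluated under stratified 10-fold cross-validation across
    binary, ternary and five-class case definitions, with sensitivity,
    specificity, accuracy, predictive values, Matthews correlation, F1
    and ROC/AUC reporting. Includes a seeded synthetic EEG epoch
    generator so the full pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    e1071,
    class,
    randomForest,
    xgboost,
    rpart,
    nnet
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
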