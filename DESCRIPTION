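Package: ltetrolet
Title: L-Tetrolet Textural Features and Hybrid Feature Selection for EEG Sleep Staging
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Six-class sleep-stage classification of 30-second EEG epochs from
    handcrafted textural features. Implements the L-tetrolet pattern operator
    (an L-tetromino comparison template producing 8-bit codes from sliding
    4x4 window matrices), a multiple-pooling multilevel decomposition that
    yields 10,960 features per epoch, a three-stage hybrid feature selector
    (threshold pruning, positive-ReliefF pruning, iterative neighborhood
    component analysis with cross-validated loss), and cubic-SVM evaluation
    under stratified 10-fold cross-validation. Includes a seeded synthetic
    EEG epoch generator, a minimal EDF reader/writer with annotation
    sidecars, and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    e1071,
    jsonlite,
    data.table,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    rpart,
    MASS,
    class,
    randomForest,
    optparse,
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
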