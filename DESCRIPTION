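Package: qsarbind
Title: QSAR Models for Drug Plasma-Protein Binding by Heuristic Regression
    and Support Vector Regression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Forecasts the binding rate of plasma protein (BRPP, in percent)
    of drug compounds from molecular descriptors. Implements two
    quantitative structure-activity relationship (QSAR) estimators: a
    heuristic forward-selection multiple linear regression with descriptor
    pretreatment filters and a pairwise-collinearity cap, and
    epsilon-insensitive support vector regression with a Gaussian kernel
    solved by exact pairwise dual updates. Both are evaluated by
    leave-one-out cross-validation, with coordinate-wise hyperparameter
    search, a synthetic descriptor-matrix generator for benchmarking, and a
    packaged 70-compound validation dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    yaml,
    optparse
Config/testthat/edition: 3
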