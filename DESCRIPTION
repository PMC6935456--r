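Package: conslayer
Title: Integrative Neural Networks with a Gene-Wise Consolidation Layer
    for Multi-Study Biomarker Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits a feedforward neural network whose hidden layer is
    consolidated gene-by-gene across multiple aligned omics studies, with a
    lasso-penalized logistic output layer so that the consolidation-to-output
    coefficients perform gene selection. Includes ridge-based initialization,
    a Newton-style update for the penalized output weights with a smooth
    sign approximation, full-batch gradient updates for the remaining
    weights, a multivariate-normal multi-study simulator with optional
    all-noise studies, regularization-path and cross-validation tools for
    the penalty, and a repetition harness reporting sensitivity,
    specificity and the Youden J index of gene selection.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
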