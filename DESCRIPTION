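Package: aucbench
Title: Honest Performance Estimation for Gene-Expression Classifiers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds and evaluates binary gene-expression classifiers across
    difficulty levels. Provides cumulative Fisher-information difficulty
    scoring with permutation significance, five univariate feature-selection
    rules (Welch t with optional correlation filtering or meta-feature
    averaging, BSS/WSS, mean difference), eight fixed-hyperparameter
    classifiers (LDA, DLDA, QDA, logistic regression, KNN, RBF-SVM), nested
    two-level cross-validation with inner feature-count tuning, repeated
    stratified cross-validation and leave-pair-out bootstrap AUC estimators
    with delta-method standard errors, validation-set variance decomposition,
    inverse-sample-size learning curves, and feature-set congruence (kappa and
    hypergeometric gene-set enrichment). A synthetic two-class Gaussian
    expression generator with known Bayes AUC supplies ground truth for
    end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    e1071,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
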