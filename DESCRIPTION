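Package: refnoise
Title: Label-Noise Robustness Experiments for Radiomics Feature Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates uncertainty in the clinical reference standard of
    binary-outcome radiomics studies by injecting graded, balance-preserving
    label noise into the training partition of a feature table, running a
    feature-selection by classifier grid (Mann-Whitney U, recursive feature
    elimination, L1-penalized logistic regression, minimum-redundancy
    maximum-relevance; random forest and lasso-logistic classifiers) under
    stratified cross-validation, and quantifying how feature-selection
    stability (multi-set Jaccard similarity) and model performance (AUC,
    accuracy, sensitivity, specificity) degrade when evaluated against
    permuted versus true references on training and hold-out data. Includes
    a synthetic feature-table generator with known informative features and
    a closed-form expectation for the AUC observed against noisy labels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    randomForest,
    jsonlite,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    ggplot2,
    yaml,
    optparse
Config/testthat/edition: 3
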