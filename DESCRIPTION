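Package: foldleak
Title: Measuring Optimism Bias from Feature Selection Outside Cross-Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the optimism bias that arises in high-dimensional
    tabular (radiomics-style) classification when filter feature selection is
    applied to the whole dataset before cross-validation (a data leak) instead
    of nested inside each training fold. Provides a synthetic-data generator
    with controlled dimensionality, correlation blocks, planted signal,
    prevalence and missingness; column-mean imputation and z-score
    normalization; seven filter feature-selection methods (t-score, F-score,
    mutual information maximization, ReliefF, minimum-redundancy
    maximum-relevance, LASSO entry order, SVM recursive feature elimination);
    seven classifiers behind a single fit/predict-probability contract;
    stratified k-fold splitting with the leaky and the nested training scheme;
    and micro-averaged evaluation with paired bootstrap significance tests and
    a bias-versus-dimensionality regression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    e1071,
    ranger,
    nnet,
    xgboost,
    withr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
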