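Package: sbpbench
Title: Neutral Benchmarking of Learning Methods for Predicting Blood Pressure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A simulation framework for neutral comparison of statistical and
    machine learning methods that predict a continuous clinical outcome
    (discharge systolic blood pressure). Provides Gaussian-copula synthesis of
    mixed continuous/binary patient cohorts calibrated to published marginal
    summaries, six prediction methods (linear regression with restricted cubic
    splines, the lasso, ridge regression, gradient-boosted trees, random
    forests, and single-hidden-layer neural networks) behind one fit/predict
    contract, tenfold cross-validated grid search for hyperparameter tuning,
    learner-anchored residual-bootstrap data-generating processes, and
    factorial Monte Carlo evaluation by squared-Pearson R-squared, mean squared
    error, and mean absolute error.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    withr,
    glmnet,
    randomForest,
    nnet,
    xgboost
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
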