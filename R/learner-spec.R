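LEARNER_METHODS <- c("ols_rcs", "lasso", "ridge", "boosted_trees",
                     "random_forest", "nnet1", "intercept_only")

#' Specify a prediction method and its hyperparameters
#'
#' The six benchmark methods share one specification object:
#' \describe{
#'   \item{`ols_rcs`}{linear regression by OLS with every continuous
#'     predictor expanded by a restricted cubic spline; `knots` (3..7).}
#'   \item{`lasso`, `ridge`}{L1-/L2-penalized linear regression on
#'     standardized predictors; `lambda >= 0` (intercept unpenalized).}
#'   \item{`boosted_trees`}{stagewise regression trees on the squared-error
#'     gradient; `interaction_depth`, `learning_rate`, `n_trees`
#'     (default 100, no early stopping), `subsample` (default 1 for
#'     determinism).}
#'   \item{`random_forest`}{`mtry` candidate variables per split,
#'     `min_node_size` leaf floor, `n_trees` (default 500).}
#'   \item{`nnet1`}{single hidden layer of `hidden_units` logistic units
#'     with a linear output and L2 `weight_decay`; inputs standardized,
#'     initial weights Uniform(-0.5, 0.5) from the fit seed, quasi-Newton
#'     optimization with at most 500 iterations.}
#' }
#' `intercept_only` (no hyperparameters) is a diagnostic baseline predicting
#' `mean(y)` everywhere.
#'
#' @param method one of `"ols_rcs"`, `"lasso"`, `"ridge"`,
#'   `"boosted_trees"`, `"random_forest"`, `"nnet1"`, `"intercept_only"`.
#' @param ... named hyperparameters as above.
#' @return An object of class `learner_spec`.
#' @export
#' @examples
#' learner_spec("boosted_trees", interaction_depth = 4, learning_rate = 0.065)
#' learner_spec("ols_rcs", knots = 3)
learner_spec <- function(method, ...) {
  method <- match.arg(method, LEARNER_METHODS)
  hp <- list(...)
  bad <- function(msg) stop("learner_spec('", method, "'): ", msg,
                            call. = FALSE)
  need <- function(field, check, msg) {
    v <- hp[[field]]
    if (is.null(v)) bad(paste0("hyperparameter '", field, "' is required"))
    if (!is.numeric(v) || length(v) != 1L || !check(v)) bad(msg)
    v
  }
  hp <- switch(method,
    ols_rcs = list(
      knots = as.integer(need("knots", function(v) v >= 3 && v <= 7,
                              "'knots' must be in 3..7"))),
    lasso = ,
    ridge = list(
      lambda = need("lambda", function(v) v >= 0, "'lambda' must be >= 0")),
    boosted_trees = list(
      interaction_depth = as.integer(need("interaction_depth",
        function(v) v >= 1, "'interaction_depth' must be >= 1")),
      learning_rate = need("learning_rate", function(v) v >= 0,
                           "'learning_rate' must be >= 0"),
      n_trees = as.integer(hp$n_trees %||% 100L),
      subsample = hp$subsample %||% 1),
    random_forest = list(
      mtry = as.integer(need("mtry", function(v) v >= 1, "'mtry' must be >= 1")),
      min_node_size = as.integer(need("min_node_size", function(v) v >= 1,
                                      "'min_node_size' must be >= 1")),
      n_trees = as.integer(hp$n_trees %||% 500L)),
    nnet1 = list(
      hidden_units = as.integer(need("hidden_units", function(v) v >= 1,
                                     "'hidden_units' must be >= 1")),
      weight_decay = need("weight_decay", function(v) v >= 0,
                          "'weight_decay' must be >= 0"),
      maxit = as.integer(hp$maxit %||% 500L)),
    intercept_only = list()
  )
  if (method == "boosted_trees" &&
      (hp$subsample <= 0 || hp$subsample > 1)) {
    bad("'subsample' must lie in (0, 1]")
  }
  structure(list(method = method, hyperparameters = hp),
            class = "learner_spec")
}

#' @export
print.learner_spec <- function(x, ...) {
  hp <- x$hyperparameters
  cat("Learner spec: ", x$method,
      if (length(hp)) paste0(" (", paste(names(hp), unlist(hp), sep = " = ",
                                         collapse = ", "), ")"),
      "\n", sep = "")
  invisible(x)
}

#' Tuned hyperparameters packaged per cohort
#'
#' Returns complete [learner_spec()] objects for all six methods with the
#' tuned values shipped for the packaged cohorts: AMI — boosted trees depth 4,
#' learning rate 0.065; random forest mtry 6, node size 20; OLS 3 knots;
#' neural network 5 hidden units, decay 0.05; lasso lambda 0.08596; ridge
#' lambda 0.56553. CHF — depth 4, rate 0.065; mtry 8, node size 20; 5 knots;
#' 6 hidden units, decay 0; lasso 0.03323; ridge 0.96881.
#'
#' @param cohort `"ami"` or `"chf"`.
#' @return Named list of `learner_spec` objects
#'   (`ols_rcs`, `lasso`, `ridge`, `boosted_trees`, `random_forest`, `nnet1`).
#' @export
default_hyperparameters <- function(cohort = c("ami", "chf")) {
  cohort <- match.arg(cohort)
  if (cohort == "ami") {
    list(
      ols_rcs = learner_spec("ols_rcs", knots = 3),
      lasso = learner_spec("lasso", lambda = 0.08596),
      ridge = learner_spec("ridge", lambda = 0.56553),
      boosted_trees = learner_spec("boosted_trees", interaction_depth = 4,
                                   learning_rate = 0.065),
      random_forest = learner_spec("random_forest", mtry = 6,
                                   min_node_size = 20),
      nnet1 = learner_spec("nnet1", hidden_units = 5, weight_decay = 0.05)
    )
  } else {
    list(
      ols_rcs = learner_spec("ols_rcs", knots = 5),
      lasso = learner_spec("lasso", lambda = 0.03323),
      ridge = learner_spec("ridge", lambda = 0.96881),
      boosted_trees = learner_spec("boosted_trees", interaction_depth = 4,
                                   learning_rate = 0.065),
      random_forest = learner_spec("random_forest", mtry = 8,
                                   min_node_size = 20),
      nnet1 = learner_spec("nnet1", hidden_units = 6, weight_decay = 0)
    )
  }
}
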