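#' Fit a prediction method to a covariate table
#'
#' One fit contract for all methods: `fit_learner` trains the method named by
#' `spec` on the predictors in `X` and the continuous outcome `y`, and the
#' returned object predicts through [predict.fitted_learner()] using exactly
#' the training column schema (standardization parameters and spline knots
#' are learned on the training data only and stored).
#'
#' For `ols_rcs`, each continuous predictor is expanded by [rcs_basis()] at
#' [place_knots()] locations, binary predictors enter as-is, and the residual
#' standard deviation is estimated as `sqrt(RSS / (n - p))` with `p` the
#' number of fitted parameters.
#'
#' @param spec a [learner_spec()].
#' @param X data.frame of predictors (no missing values; binary columns coded
#'   0/1).
#' @param y numeric outcome vector of length `nrow(X)`.
#' @param seed RNG seed governing any stochastic element of the fit (forest
#'   bootstrap, boosting subsampling, neural-network initial weights); the
#'   same `(spec, X, y, seed)` yields identical predictions.
#' @return An object of class `fitted_learner` carrying `spec`, the training
#'   `schema` (column names and kinds), the opaque fitted state, and for
#'   `ols_rcs` also the per-predictor knots, coefficient vector and
#'   `residual_sd`.
#' @export
#' @examples
#' cfg <- load_cohort_config("ami")
#' x <- simulate_covariates(cfg, "derivation", n = 300, seed = 1)
#' mod <- calibrate_outcome_model(cfg, x, signal_fraction = 0.5)
#' y <- generate_outcome(mod, x, seed = 2)
#' fit <- fit_learner(learner_spec("ols_rcs", knots = 3), x, y)
#' head(predict(fit, x))
fit_learner <- function(spec, X, y, seed = 1) {
  stopifnot(inherits(spec, "learner_spec"), is.data.frame(X))
  y <- as.numeric(y)
  if (nrow(X) != length(y)) {
    stop("y must have one value per row of X", call. = FALSE)
  }
  if (anyNA(X) || anyNA(y)) stop("inputs contain missing values", call. = FALSE)
  kinds <- variable_kinds(X)
  fitted <- switch(spec$method,
    ols_rcs = fit_ols_rcs(spec, X, y, kinds),
    lasso = fit_glmnet(spec, X, y, alpha = 1),
    ridge = fit_glmnet(spec, X, y, alpha = 0),
    boosted_trees = fit_boosted(spec, X, y, seed),
    random_forest = fit_forest(spec, X, y, seed),
    nnet1 = fit_nnet1(spec, X, y, seed),
    intercept_only = list(mean = mean(y))
  )
  structure(
    c(list(spec = spec,
           schema = list(names = names(X), kinds = kinds),
           n_train = nrow(X)),
      fitted),
    class = "fitted_learner"
  )
}

# design matrix for ols_rcs: rcs expansion of continuous columns, binary as-is
build_rcs_design <- function(X, kinds, knots) {
  blocks <- lapply(names(X), function(v) {
    if (kinds[[v]] == "continuous") {
      B <- rcs_basis(X[[v]], knots[[v]])
      colnames(B) <- paste0(v, c("", paste0("'", seq_len(ncol(B) - 1))))
      B
    } else {
      matrix(X[[v]], ncol = 1, dimnames = list(NULL, v))
    }
  })
  do.call(cbind, blocks)
}

fit_ols_rcs <- function(spec, X, y, kinds) {
  k <- spec$hyperparameters$knots
  knots <- lapply(stats::setNames(names(X), names(X)), function(v) {
    if (kinds[[v]] == "continuous") place_knots(X[[v]], k) else NULL
  })
  D <- cbind(`(Intercept)` = 1, build_rcs_design(X, kinds, knots))
  n <- nrow(D); p <- ncol(D)
  if (n <= p) {
    stop("ols_rcs rank failure: n = ", n, " <= p = ", p,
         " fitted parameters", call. = FALSE)
  }
  qr_fit <- qr(D)
  if (qr_fit$rank < p) {
    stop("ols_rcs rank failure: design has rank ", qr_fit$rank, " < ", p,
         call. = FALSE)
  }
  coefs <- qr.coef(qr_fit, y)
  res <- y - drop(D %*% coefs)
  list(knots = knots,
       coefficients = coefs,
       residual_sd = sqrt(sum(res^2) / (n - p)))
}

predict_ols_rcs <- function(object, X) {
  D <- cbind(`(Intercept)` = 1,
             build_rcs_design(X, object$schema$kinds, object$knots))
  drop(D %*% object$coefficients)
}

fit_glmnet <- function(spec, X, y, alpha) {
  lambda <- spec$hyperparameters$lambda
  x <- as.matrix(X)
  # descending path ending exactly at the requested lambda so predict(s =
  # lambda) hits a computed point rather than interpolating
  path <- if (lambda > 0) lambda * c(100, 10, 1) else c(1, 0.1, 0)
  fit <- glmnet::glmnet(x, y, alpha = alpha, lambda = path,
                        standardize = TRUE, thresh = 1e-12)
  list(glmnet = fit, lambda = lambda)
}

predict_glmnet <- function(object, X) {
  drop(glmnet::predict.glmnet(object$glmnet, as.matrix(X),
                              s = object$lambda))
}

fit_boosted <- function(spec, X, y, seed) {
  hp <- spec$hyperparameters
  dm <- xgboost::xgb.DMatrix(as.matrix(X), label = y)
  params <- list(max_depth = hp$interaction_depth,
                 eta = hp$learning_rate,
                 subsample = hp$subsample,
                 colsample_bytree = 1,
                 lambda = 0, alpha = 0, min_child_weight = 1,
                 objective = "reg:squarederror",
                 base_score = mean(y),
                 nthread = 1,
                 seed = seed_substream(seed, "boosted_trees"))
  bst <- withr::with_seed(seed_substream(seed, "boosted_trees"),
                          xgboost::xgb.train(params = params, data = dm,
                                             nrounds = hp$n_trees,
                                             verbose = 0))
  list(booster = bst)
}

predict_boosted <- function(object, X) {
  stats::predict(object$booster, xgboost::xgb.DMatrix(as.matrix(X)))
}

fit_forest <- function(spec, X, y, seed) {
  hp <- spec$hyperparameters
  mtry <- min(hp$mtry, ncol(X))
  rf <- withr::with_seed(
    seed_substream(seed, "random_forest"),
    randomForest::randomForest(x = X, y = y, ntree = hp$n_trees,
                               mtry = mtry, nodesize = hp$min_node_size)
  )
  list(forest = rf)
}

predict_forest <- function(object, X) {
  unname(stats::predict(object$forest, newdata = X))
}

fit_nnet1 <- function(spec, X, y, seed) {
  hp <- spec$hyperparameters
  x <- as.matrix(X)
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  xs <- sweep(sweep(x, 2, center, "-"), 2, scale, "/")
  h <- hp$hidden_units
  n_wts <- (ncol(xs) + 1) * h + (h + 1)
  wts <- withr::with_seed(seed_substream(seed, "nnet1"),
                          stats::runif(n_wts, -0.5, 0.5))
  net <- withr::with_seed(
    seed_substream(seed, "nnet1"),
    nnet::nnet(x = xs, y = y, size = h, decay = hp$weight_decay,
               linout = TRUE, maxit = hp$maxit, Wts = wts,
               abstol = 1e-8, reltol = 1e-8, trace = FALSE,
               MaxNWts = n_wts + 1)
  )
  list(net = net, center = center, scale = scale,
       converged = net$convergence == 0)
}

predict_nnet1 <- function(object, X) {
  x <- as.matrix(X)
  xs <- sweep(sweep(x, 2, object$center, "-"), 2, object$scale, "/")
  drop(stats::predict(object$net, xs))
}

#' @export
print.fitted_learner <- function(x, ...) {
  cat("Fitted learner: ", x$spec$method, " on ", x$n_train, " subjects, ",
      length(x$schema$names), " predictors\n", sep = "")
  if (x$spec$method == "ols_rcs") {
    cat("  residual sd: ", round(x$residual_sd, 4), " mmHg\n", sep = "")
  }
  invisible(x)
}

#' Predict from a fitted learner
#'
#' Deterministic given the fitted state; applies the knots and
#' standardization learned at fit time. The new table must carry exactly the
#' training columns, in the training order.
#'
#' @param object a [fit_learner()] result.
#' @param newdata data.frame matching the training schema.
#' @param ... unused.
#' @return Numeric prediction vector (mmHg).
#' @export
predict.fitted_learner <- function(object, newdata, ...) {
  stopifnot(is.data.frame(newdata))
  if (!identical(names(newdata), object$schema$names)) {
    stop("newdata columns do not match the training schema", call. = FALSE)
  }
  if (anyNA(newdata)) stop("newdata contains missing values", call. = FALSE)
  switch(object$spec$method,
         ols_rcs = predict_ols_rcs(object, newdata),
         lasso = ,
         ridge = predict_glmnet(object, newdata),
         boosted_trees = predict_boosted(object, newdata),
         random_forest = predict_forest(object, newdata),
         nnet1 = predict_nnet1(object, newdata),
         intercept_only = rep(object$mean, nrow(newdata)))
}

#' Serialize a fitted learner to a versioned file
#'
#' Writes the method identity, hyperparameters, schema, and fitted state to a
#' single file so a data-generating process can be rebuilt later;
#' [read_learner()] restores an object whose predictions are identical to the
#' original's.
#'
#' @param object a `fitted_learner`.
#' @param path file path.
#' @return `write_learner` returns `path` invisibly; `read_learner` returns
#'   the restored `fitted_learner`.
#' @export
write_learner <- function(object, path) {
  stopifnot(inherits(object, "fitted_learner"))
  payload <- unclass(object)
  if (object$spec$method == "boosted_trees") {
    # xgboost handles are external pointers; store the raw model bytes
    payload$booster <- NULL
    payload$booster_raw <- xgboost::xgb.save.raw(object$booster)
  }
  saveRDS(list(format = "sbpbench_learner", version = 1L, payload = payload),
          path)
  invisible(path)
}

#' @rdname write_learner
#' @export
read_learner <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "sbpbench_learner")) {
    stop("not a serialized learner file: ", path, call. = FALSE)
  }
  payload <- obj$payload
  if (!is.null(payload$booster_raw)) {
    payload$booster <- xgboost::xgb.load.raw(payload$booster_raw)
    payload$booster_raw <- NULL
  }
  structure(payload, class = "fitted_learner")
}
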