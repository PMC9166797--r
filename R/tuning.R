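#' Random K-fold assignment
#'
#' Randomly divides `n` subjects into `K` approximately equally-sized groups
#' (fold sizes differ by at most one).
#'
#' @param n number of subjects (`n >= K`).
#' @param K number of folds (default 10).
#' @param seed RNG seed; identical seeds give identical assignments.
#' @return Integer vector of fold labels in `1..K`, one per subject.
#' @export
make_folds <- function(n, K = 10, seed = 1) {
  n <- as.integer(n); K <- as.integer(K)
  if (is.na(K) || K < 2L) stop("K must be >= 2", call. = FALSE)
  if (is.na(n) || n < K) stop("n must be >= K", call. = FALSE)
  withr::with_seed(seed, sample(rep_len(seq_len(K), n)))
}

#' Cross-validated predictive R-squared
#'
#' For each fold, fits the method on the other `K - 1` folds, predicts the
#' held-out fold, and computes the squared Pearson correlation between
#' observed and predicted outcomes on that fold; returns the K-fold average.
#' A held-out fold on which the correlation is undefined (zero variance in
#' the outcomes or the predictions) is recorded as R-squared 0 with a
#' warning.
#'
#' @param spec a [learner_spec()].
#' @param X,y training predictors and outcome.
#' @param folds fold labels from [make_folds()] covering the data.
#' @param seed base seed for the per-fold fits.
#' @return Mean cross-validated R-squared, with attribute `per_fold`.
#' @export
cv_r2 <- function(spec, X, y, folds, seed = 1) {
  stopifnot(length(folds) == nrow(X), length(y) == nrow(X))
  ks <- sort(unique(folds))
  per_fold <- vapply(ks, function(k) {
    test <- folds == k
    fit <- fit_learner(spec, X[!test, , drop = FALSE], y[!test],
                       seed = seed_substream(seed, k))
    pred <- predict(fit, X[test, , drop = FALSE])
    if (stats::sd(y[test]) == 0 || stats::sd(pred) == 0) {
      warning("fold ", k, ": R-squared undefined (zero variance); ",
              "recorded as 0", call. = FALSE)
      0
    } else {
      r2_pearson(y[test], pred)
    }
  }, numeric(1))
  structure(mean(per_fold), per_fold = per_fold)
}

#' Cross-validated grid search
#'
#' Evaluates [cv_r2()] at every hyperparameter point of an ordered grid with
#' one fold assignment fixed for the whole search, and selects the point with
#' the highest mean cross-validated R-squared (ties resolved in favour of the
#' earliest grid point in the declared order).
#'
#' @param method learner method name (see [learner_spec()]).
#' @param grid data.frame with one row per grid point and one column per
#'   hyperparameter, or a list of named hyperparameter lists; see
#'   [default_grid()].
#' @param X,y data.
#' @param seed RNG seed (folds and per-point fits).
#' @param K number of folds (default 10).
#' @return An object of class `grid_result`: `table` (the grid plus
#'   `mean_cv_r2`), `per_fold` (points x folds matrix), `selected` (row index
#'   of the winner), `spec` (the winning [learner_spec()]), and `folds`.
#' @export
grid_search <- function(method, grid, X, y, seed = 1, K = 10) {
  if (is.data.frame(grid)) {
    grid_df <- grid
    points <- lapply(seq_len(nrow(grid)), function(i) as.list(grid[i, , drop = FALSE]))
  } else if (is.list(grid) && length(grid) > 0) {
    points <- grid
    grid_df <- do.call(rbind, lapply(grid, as.data.frame))
  } else {
    stop("grid must be a nonempty data.frame or list of points", call. = FALSE)
  }
  if (length(points) == 0L) stop("grid must be nonempty", call. = FALSE)
  folds <- make_folds(nrow(X), K, seed = seed_substream(seed, "folds"))
  res <- lapply(seq_along(points), function(i) {
    spec <- do.call(learner_spec, c(list(method = method), points[[i]]))
    cv_r2(spec, X, y, folds, seed = seed_substream(seed, i))
  })
  mean_r2 <- vapply(res, as.numeric, numeric(1))
  per_fold <- do.call(rbind, lapply(res, attr, "per_fold"))
  selected <- which.max(mean_r2)  # earliest point wins ties
  grid_df$mean_cv_r2 <- mean_r2
  structure(
    list(table = grid_df, per_fold = per_fold, selected = selected,
         spec = do.call(learner_spec,
                        c(list(method = method), points[[selected]])),
         folds = folds),
    class = "grid_result"
  )
}

#' @export
print.grid_result <- function(x, ...) {
  cat("Grid search over ", nrow(x$table), " points, ",
      length(unique(x$folds)), "-fold CV\n", sep = "")
  cat("Selected point ", x$selected, ":\n", sep = "")
  print(x$spec)
  invisible(x)
}

#' Default tuning grids
#'
#' The shipped search grids: `nnet1` crosses 2..15 hidden units with weight
#' decay in \{0, 0.01, 0.05, 0.1, 0.5\}; `boosted_trees` crosses interaction
#' depth 1..5 with learning rate in \{0.005, 0.01, 0.035, 0.065, 0.1\};
#' `random_forest` crosses `mtry` in `floor(p/6)..floor(p/2)` with minimum
#' node size in \{5, 10, 20, 50\}; `ols_rcs` searches 3..6 knots.
#'
#' @param method learner method name.
#' @param p number of predictors (needed for `random_forest`).
#' @return data.frame of grid points in declared order.
#' @export
default_grid <- function(method, p = NULL) {
  switch(method,
    nnet1 = expand.grid(hidden_units = 2:15,
                        weight_decay = c(0, 0.01, 0.05, 0.1, 0.5)),
    boosted_trees = expand.grid(interaction_depth = 1:5,
                                learning_rate = c(0.005, 0.01, 0.035,
                                                  0.065, 0.1)),
    random_forest = {
      if (is.null(p)) stop("p is required for the random_forest grid",
                           call. = FALSE)
      expand.grid(mtry = max(1L, floor(p / 6)):max(1L, floor(p / 2)),
                  min_node_size = c(5, 10, 20, 50))
    },
    ols_rcs = data.frame(knots = 3:6),
    stop("no default grid for method '", method, "'", call. = FALSE))
}

#' Select the penalty of a lasso or ridge model on a lambda path
#'
#' Builds a 100-point log-spaced path from `lambda_max` (the smallest penalty
#' at which all lasso slopes are zero, `max |<x_j, y - ybar>| / n` on
#' standardized predictors; for ridge, 1000 times that value, the usual
#' scaled analog) down to `1e-4 * lambda_max`, and returns the path value
#' minimizing tenfold cross-validated MSE (exact ties resolved toward the
#' larger, i.e. more heavily shrunk, penalty).
#'
#' @param method `"lasso"` or `"ridge"`.
#' @param X,y data (at least two predictors; non-constant outcome).
#' @param seed RNG seed (folds).
#' @param K number of folds (default 10).
#' @param one_se if `TRUE`, apply the one-standard-error rule instead:
#'   largest lambda whose CV MSE is within one SE of the minimum.
#' @return Selected lambda, with attributes `path` and `cv_mse`.
#' @export
select_lambda <- function(method = c("lasso", "ridge"), X, y, seed = 1,
                          K = 10, one_se = FALSE) {
  method <- match.arg(method)
  x <- as.matrix(X)
  if (ncol(x) < 2L) stop("at least 2 predictors are required", call. = FALSE)
  if (stats::sd(y) == 0) stop("outcome is constant", call. = FALSE)
  n <- nrow(x)
  # glmnet-style standardization (1/n variance denominator)
  xc <- sweep(x, 2, colMeans(x), "-")
  sdn <- sqrt(colMeans(xc^2))
  sdn[sdn == 0] <- 1
  xs <- sweep(xc, 2, sdn, "/")
  lambda_max <- max(abs(crossprod(xs, y - mean(y)))) / n
  if (method == "ridge") lambda_max <- 1000 * lambda_max
  path <- exp(seq(log(lambda_max), log(lambda_max * 1e-4), length.out = 100))

  alpha <- if (method == "lasso") 1 else 0
  folds <- make_folds(n, K, seed = seed_substream(seed, "lambda_folds"))
  fold_mse <- matrix(NA_real_, K, length(path))
  for (k in seq_len(K)) {
    test <- folds == k
    fit <- glmnet::glmnet(x[!test, , drop = FALSE], y[!test], alpha = alpha,
                          lambda = path, standardize = TRUE)
    pred <- glmnet::predict.glmnet(fit, x[test, , drop = FALSE], s = path)
    fold_mse[k, ] <- colMeans((y[test] - pred)^2)
  }
  cv_mse <- colMeans(fold_mse)
  if (one_se) {
    se_min <- stats::sd(fold_mse[, which.min(cv_mse)]) / sqrt(K)
    idx <- which(cv_mse <= min(cv_mse) + se_min)[1]  # path is decreasing
  } else {
    idx <- which.min(cv_mse)  # first index = largest lambda on exact ties
  }
  structure(path[idx], path = path, cv_mse = cv_mse)
}
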