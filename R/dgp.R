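#' Build a learner-anchored data-generating process
#'
#' Fits the anchor method once on the base derivation sample, computes its
#' predictions on the derivation covariates and on the validation covariates
#' (bootstrap-expanded to `expand_to` rows to remove validation-sample
#' noise), and stores the residual source used to simulate outcomes: the
#' empirical pool of derivation residuals `y - yhat` for all anchors except
#' `ols_rcs`, which instead uses Gaussian residuals with the standard
#' deviation estimated from the OLS fit.
#'
#' @param anchor_spec a [learner_spec()] with fixed (pre-tuned)
#'   hyperparameters.
#' @param x_derivation,y_derivation base derivation covariates and outcome.
#' @param x_validation base validation covariates.
#' @param expand_to validation rows after bootstrap expansion
#'   (default 100000).
#' @param seed RNG seed (anchor fit and bootstrap expansion substreams).
#' @param y_validation optional base validation outcomes; required only for
#'   `validation_residuals = "validation"`.
#' @param validation_residuals where validation-sample residual draws come
#'   from: `"derivation"` (default) reuses the derivation pool;
#'   `"validation"` draws from the empirical pool of base validation
#'   residuals instead (empirical anchors only).
#' @return An object of class `generating_process`.
#' @export
build_dgp <- function(anchor_spec, x_derivation, y_derivation, x_validation,
                      expand_to = 100000, seed = 1, y_validation = NULL,
                      validation_residuals = c("derivation", "validation")) {
  validation_residuals <- match.arg(validation_residuals)
  stopifnot(inherits(anchor_spec, "learner_spec"))
  if (is.null(y_derivation)) {
    stop("derivation outcome is required to anchor a DGP", call. = FALSE)
  }
  expand_to <- as.integer(expand_to)
  if (is.na(expand_to) || expand_to < 1L) {
    stop("expand_to must be >= 1", call. = FALSE)
  }
  anchor <- fit_learner(anchor_spec, x_derivation, y_derivation,
                        seed = seed_substream(seed, "anchor_fit"))
  yhat_deriv <- predict(anchor, x_derivation)
  x_valid <- bootstrap_expand(x_validation, expand_to,
                              seed = seed_substream(seed, "expand"))
  yhat_valid <- predict(anchor, x_valid)
  residual_source <- if (anchor_spec$method == "ols_rcs") {
    list(mode = "gaussian", sigma = anchor$residual_sd)
  } else {
    list(mode = "empirical", pool = y_derivation - yhat_deriv)
  }
  residual_source_validation <- NULL
  if (validation_residuals == "validation") {
    if (anchor_spec$method == "ols_rcs") {
      stop("validation_residuals = \"validation\" applies only to ",
           "empirical-pool anchors", call. = FALSE)
    }
    if (is.null(y_validation)) {
      stop("y_validation is required for validation_residuals = ",
           "\"validation\"", call. = FALSE)
    }
    residual_source_validation <-
      list(mode = "empirical",
           pool = y_validation - predict(anchor, x_validation))
  }
  structure(
    list(anchor_spec = anchor_spec, anchor = anchor,
         x_derivation = x_derivation, yhat_derivation = yhat_deriv,
         x_validation = x_valid, yhat_validation = yhat_valid,
         residual_source = residual_source,
         residual_source_validation = residual_source_validation,
         seed = seed),
    class = "generating_process"
  )
}

#' @export
print.generating_process <- function(x, ...) {
  rs <- x$residual_source
  cat("Data-generating process anchored on ", x$anchor_spec$method, "\n",
      "  derivation: ", nrow(x$x_derivation), " subjects; validation: ",
      nrow(x$x_validation), " (bootstrap-expanded)\n",
      "  residual source: ", rs$mode,
      if (rs$mode == "gaussian") paste0(" (sigma = ", round(rs$sigma, 3), ")")
      else paste0(" (pool of ", length(rs$pool), ")"),
      "\n", sep = "")
  invisible(x)
}

#' Theoretical R-squared ceiling of a data-generating process
#'
#' The signal proportion `var(yhat_valid) / (var(yhat_valid) + var(resid))`:
#' the validation R-squared an oracle that knows the anchor's predictions
#' would attain in expectation.
#'
#' @param gp a [build_dgp()] result.
#' @return Signal proportion in `[0, 1]`.
#' @export
dgp_signal_proportion <- function(gp) {
  stopifnot(inherits(gp, "generating_process"))
  vr <- if (gp$residual_source$mode == "gaussian") {
    gp$residual_source$sigma^2
  } else {
    stats::var(gp$residual_source$pool)
  }
  vs <- stats::var(gp$yhat_validation)
  vs / (vs + vr)
}

#' Simulate one replicate pair of derivation/validation datasets
#'
#' For every subject in the derivation and validation samples, the simulated
#' outcome is the anchor's prediction plus a residual drawn i.i.d. from the
#' DGP's residual source (with replacement from the empirical pool, or
#' Normal(0, sigma^2) for the Gaussian source). Derivation and validation
#' draws use independent substreams of `seed`; covariates are the frozen base
#' covariates.
#'
#' @param gp a [build_dgp()] result.
#' @param seed RNG seed for this replicate.
#' @return An object of class `replicate_pair`: lists `derivation` and
#'   `validation`, each holding `x` (covariates) and `y` (simulated outcome),
#'   plus the replicate `seed`.
#' @export
simulate_pair <- function(gp, seed = 1) {
  stopifnot(inherits(gp, "generating_process"))
  rs_valid <- gp$residual_source_validation %||% gp$residual_source
  draw <- function(rs, n, stream) {
    if (rs$mode == "empirical") {
      if (length(rs$pool) == 0L) stop("empty residual pool", call. = FALSE)
      withr::with_seed(seed_substream(seed, stream),
                       sample(rs$pool, n, replace = TRUE))
    } else {
      withr::with_seed(seed_substream(seed, stream),
                       stats::rnorm(n, 0, rs$sigma))
    }
  }
  structure(
    list(derivation = list(x = gp$x_derivation,
                           y = gp$yhat_derivation +
                             draw(gp$residual_source,
                                  length(gp$yhat_derivation), "deriv")),
         validation = list(x = gp$x_validation,
                           y = gp$yhat_validation +
                             draw(rs_valid,
                                  length(gp$yhat_validation), "valid")),
         seed = seed),
    class = "replicate_pair"
  )
}

#' Generate a sequence of replicate pairs
#'
#' Replicate `r` uses the substream `(base_seed, r)`, so replicates are
#' independent, any subset can be regenerated in isolation, and a callback
#' can consume pairs one at a time without holding all `R` in memory.
#'
#' @param gp a [build_dgp()] result.
#' @param R number of replicates (`R >= 1`).
#' @param base_seed master seed for the replicate substreams.
#' @param FUN optional `function(pair, r)` applied to each pair as it is
#'   generated; when supplied, the list of `FUN` results is returned instead
#'   of the pairs themselves (streaming mode).
#' @return List of `R` `replicate_pair` objects, or of `FUN` results.
#' @export
generate_replicates <- function(gp, R, base_seed = 1, FUN = NULL) {
  R <- as.integer(R)
  if (is.na(R) || R < 1L) stop("R must be >= 1", call. = FALSE)
  lapply(seq_len(R), function(r) {
    pair <- simulate_pair(gp, seed = seed_substream(base_seed, r))
    if (is.null(FUN)) pair else FUN(pair, r)
  })
}
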