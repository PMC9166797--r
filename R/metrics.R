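#' Predictive accuracy metrics
#'
#' `r2_pearson` is the square of the Pearson correlation between observed and
#' predicted outcomes (a proportion in `[0, 1]`, invariant to affine maps of
#' the predictions with nonzero slope — it measures association, not
#' agreement). `mse` and `mae` are the mean squared and mean absolute
#' prediction errors `mean((y - yhat)^2)` and `mean(|y - yhat|)`.
#'
#' @param y observed outcomes.
#' @param yhat predicted outcomes, same length.
#' @return A single number: R-squared in `[0, 1]`, MSE in mmHg^2, MAE in
#'   mmHg.
#' @export
#' @examples
#' r2_pearson(c(1, 2, 3, 4), c(1, 2, 2, 4))
#' mse(c(0, 2), c(1, 1))
r2_pearson <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) >= 2)
  if (stats::sd(y) == 0 || stats::sd(yhat) == 0) {
    stop("R-squared is undefined when either vector has zero variance",
         call. = FALSE)
  }
  stats::cor(y, yhat)^2
}

#' @rdname r2_pearson
#' @export
mse <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) >= 1)
  mean((y - yhat)^2)
}

#' @rdname r2_pearson
#' @export
mae <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) >= 1)
  mean(abs(y - yhat))
}

#' Evaluate a set of methods on one replicate pair
#'
#' Fits each method on the simulated derivation sample, predicts the
#' simulated validation sample, and records the three metrics. Hyperparameters
#' are taken as fixed in the specs (tuned once on base data, not re-tuned per
#' replicate). A failed fit, or a fit whose validation R-squared is undefined
#' (constant predictions), yields `NA` metrics for that method with a
#' warning, never a silent zero.
#'
#' @param pair a [simulate_pair()] result.
#' @param method_specs named list of [learner_spec()] objects.
#' @param seed base seed for the per-method fits.
#' @param dgp_id label of the generating process (carried into the records).
#' @param replicate replicate index (carried into the records).
#' @return data.frame with one row per method: `dgp_id`, `method`,
#'   `replicate`, `r2`, `mse`, `mae`, `failed`.
#' @export
evaluate_replicate <- function(pair, method_specs, seed = 1,
                               dgp_id = NA_character_, replicate = NA_integer_) {
  stopifnot(inherits(pair, "replicate_pair"), is.list(method_specs))
  if (is.null(names(method_specs))) {
    names(method_specs) <- vapply(method_specs, `[[`, character(1), "method")
  }
  rows <- lapply(names(method_specs), function(m) {
    rec <- data.frame(dgp_id = dgp_id, method = m, replicate = replicate,
                      r2 = NA_real_, mse = NA_real_, mae = NA_real_,
                      failed = FALSE, stringsAsFactors = FALSE)
    res <- tryCatch({
      fit <- fit_learner(method_specs[[m]], pair$derivation$x,
                         pair$derivation$y, seed = seed_substream(seed, m))
      pred <- predict(fit, pair$validation$x)
      y <- pair$validation$y
      list(r2 = if (stats::sd(pred) > 0 && stats::sd(y) > 0) {
        r2_pearson(y, pred)
      } else NA_real_,
      mse = mse(y, pred), mae = mae(y, pred))
    }, error = function(e) {
      warning("method '", m, "' failed on replicate ", replicate, ": ",
              conditionMessage(e), call. = FALSE)
      NULL
    })
    if (is.null(res)) {
      rec$failed <- TRUE
    } else {
      if (is.na(res$r2)) {
        warning("method '", m, "': validation R-squared undefined ",
                "(constant predictions); recorded as NA", call. = FALSE)
      }
      rec$r2 <- res$r2; rec$mse <- res$mse; rec$mae <- res$mae
    }
    rec
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Aggregate per-replicate performance records
#'
#' Computes the mean and standard deviation (n - 1 denominator) of each
#' metric per (generating process, method) cell, excluding missing records
#' but reporting how many were used.
#'
#' @param records data.frame of rows from [evaluate_replicate()].
#' @return Long-format data.frame: `dgp_id`, `method`, `metric`, `mean`,
#'   `sd`, `n`.
#' @export
summarize_performance <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) > 0)
  cells <- unique(records[, c("dgp_id", "method")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- records$dgp_id %in% cells$dgp_id[i] &
      records$method == cells$method[i]
    do.call(rbind, lapply(c("r2", "mse", "mae"), function(metric) {
      v <- records[[metric]][sel]
      v <- v[!is.na(v)]
      data.frame(dgp_id = cells$dgp_id[i], method = cells$method[i],
                 metric = metric,
                 mean = if (length(v)) mean(v) else NA_real_,
                 sd = if (length(v) > 1) stats::sd(v) else 0,
                 n = length(v), stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
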