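#' Simulate a covariate table by a Gaussian copula
#'
#' Draws a latent multivariate normal with the configured correlation, then
#' maps each latent column to its marginal: continuous columns become
#' `mean + sd * z`, binary columns become `1(z > qnorm(1 - prevalence))` so
#' the marginal prevalence is respected while correlation with the other
#' predictors is inherited from the latent scale.
#'
#' @param config a [cohort_config()].
#' @param role which sample's marginals to use, `"derivation"` or
#'   `"validation"`.
#' @param n number of subjects (defaults to the configured size for `role`).
#' @param seed RNG seed; identical `(config, role, n, seed)` reproduce the
#'   identical table.
#' @return A `data.frame` of class `covariate_table` with one column per
#'   configured predictor (binary columns coded 0/1) and provenance
#'   attributes `cohort_id`, `role`, `seed` and `kinds` (named character
#'   vector of column kinds).
#' @export
#' @examples
#' cfg <- load_cohort_config("ami")
#' x <- simulate_covariates(cfg, "derivation", n = 100, seed = 1)
#' dim(x)
simulate_covariates <- function(config, role = c("derivation", "validation"),
                                n = NULL, seed = 1) {
  stopifnot(inherits(config, "cohort_config"))
  role <- match.arg(role)
  if (is.null(n)) {
    n <- if (role == "derivation") config$n_derivation else config$n_validation
  }
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be a positive integer", call. = FALSE)

  p <- length(config$variables)
  R <- correlation_matrix(config)
  ed <- eigen(R, symmetric = TRUE)
  if (min(ed$values) < -1e-8) {
    stop("latent correlation matrix is not positive semidefinite",
         call. = FALSE)
  }
  A <- ed$vectors %*% diag(sqrt(pmax(ed$values, 0)), p)
  Z <- withr::with_seed(seed, matrix(stats::rnorm(n * p), n, p) %*% t(A))

  marg <- role_marginals(config, role)
  cols <- vector("list", p)
  for (j in seq_len(p)) {
    cols[[j]] <- if (marg$kind[j] == "continuous") {
      marg$mean[j] + marg$sd[j] * Z[, j]
    } else {
      # prevalence 0 -> threshold +Inf -> all zeros; prevalence 1 -> all ones
      as.numeric(Z[, j] > stats::qnorm(1 - marg$prevalence[j]))
    }
  }
  names(cols) <- marg$name
  out <- as.data.frame(cols, optional = TRUE)
  if (n == 0L) out <- out[0L, , drop = FALSE]
  as_covariate_table(out,
                     kinds = stats::setNames(marg$kind, marg$name),
                     cohort_id = config$cohort_id, role = role, seed = seed)
}

as_covariate_table <- function(df, kinds = NULL, cohort_id = NA_character_,
                               role = NA_character_, seed = NA_integer_) {
  attr(df, "kinds") <- kinds
  attr(df, "cohort_id") <- cohort_id
  attr(df, "role") <- role
  attr(df, "seed") <- seed
  class(df) <- unique(c("covariate_table", class(df)))
  df
}

#' Column kinds of a covariate table
#'
#' Returns the per-column kind (`"continuous"`/`"binary"`), taken from the
#' table's `kinds` attribute when present and inferred from the values
#' otherwise (a column whose values all lie in \{0, 1\} is treated as binary).
#'
#' @param x a data.frame of predictors.
#' @return Named character vector over the columns of `x`.
#' @export
variable_kinds <- function(x) {
  k <- attr(x, "kinds")
  if (!is.null(k) && all(names(x) %in% names(k))) {
    return(k[names(x)])
  }
  vapply(x, function(col) {
    if (all(col %in% c(0, 1))) "binary" else "continuous"
  }, character(1))
}

#' Calibrate a linear reference outcome model to a target marginal
#'
#' Constructs the known ground truth the simulations use in place of observed
#' outcomes: a linear model on internally standardized predictors whose
#' generated outcome has (on the supplied covariates) mean `target_mean`,
#' variance `target_sd^2`, and a chosen fraction of that variance carried by
#' the linear predictor. Raw coefficients are rescaled by one common factor so
#' that `var(linear predictor) = signal_fraction * target_sd^2`, the intercept
#' centres the linear predictor at `target_mean`, and
#' `noise_sd = target_sd * sqrt(1 - signal_fraction)`.
#'
#' @param config a [cohort_config()]; the outcome marginal for the table's
#'   sample role supplies `target_mean`/`target_sd`.
#' @param covariates a covariate table drawn from `config` (its `role`
#'   attribute selects the outcome marginal; derivation if absent).
#' @param signal_fraction proportion of outcome variance explained by the
#'   linear predictor, in `[0, 1)`. This is the theoretical R-squared ceiling
#'   of the synthetic truth.
#' @param raw_coefficients optional unscaled per-predictor coefficients (on
#'   the standardized scale); drawn reproducibly from `seed` as standard
#'   normals when omitted.
#' @param seed RNG seed for the default coefficient draw.
#' @return An object of class `calibrated_outcome_model` with elements
#'   `coefficients`, `center`, `scale`, `intercept`, `noise_sd`,
#'   `target_mean`, `target_sd`, `signal_fraction`.
#' @export
calibrate_outcome_model <- function(config, covariates, signal_fraction = 0.2,
                                    raw_coefficients = NULL, seed = 1) {
  stopifnot(inherits(config, "cohort_config"), is.data.frame(covariates))
  if (!is.numeric(signal_fraction) || signal_fraction < 0 ||
      signal_fraction >= 1) {
    stop("signal_fraction must lie in [0, 1)", call. = FALSE)
  }
  nms <- cohort_variable_names(config)
  if (!identical(names(covariates), nms)) {
    stop("covariate columns do not match the configuration's variables",
         call. = FALSE)
  }
  role <- attr(covariates, "role") %||% "derivation"
  if (!role %in% c("derivation", "validation")) role <- "derivation"
  target_mean <- config$outcome[[role]]$mean
  target_sd <- config$outcome[[role]]$sd

  X <- as.matrix(covariates)
  p <- ncol(X)
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  Xs <- sweep(sweep(X, 2, center, "-"), 2, scale, "/")

  raw <- raw_coefficients %||%
    withr::with_seed(seed_substream(seed, "raw_coefficients"),
                     stats::rnorm(p))
  if (length(raw) != p) {
    stop("raw_coefficients must have one value per predictor", call. = FALSE)
  }

  if (signal_fraction == 0) {
    beta <- stats::setNames(numeric(p), nms)
    intercept <- target_mean
  } else {
    lp_raw <- drop(Xs %*% raw)
    v <- stats::var(lp_raw)
    if (!is.finite(v) || v <= 0) {
      stop("constant linear predictor: cannot calibrate a positive ",
           "signal_fraction", call. = FALSE)
    }
    beta <- stats::setNames(raw * sqrt(signal_fraction * target_sd^2 / v), nms)
    intercept <- target_mean - mean(drop(Xs %*% beta))
  }
  noise_sd <- target_sd * sqrt(1 - signal_fraction)
  structure(
    list(coefficients = beta, center = center, scale = scale,
         intercept = intercept, noise_sd = noise_sd,
         target_mean = target_mean, target_sd = target_sd,
         signal_fraction = signal_fraction),
    class = "calibrated_outcome_model"
  )
}

#' @export
print.calibrated_outcome_model <- function(x, ...) {
  cat("Calibrated outcome model: ", length(x$coefficients), " predictors\n",
      "  target marginal ", x$target_mean, " +/- ", x$target_sd, " mmHg\n",
      "  signal fraction ", x$signal_fraction,
      ", noise sd ", round(x$noise_sd, 3), " mmHg\n", sep = "")
  invisible(x)
}

#' Generate outcomes from a calibrated model
#'
#' `y_i = intercept + sum_j beta_j x_ij (standardized) + eps_i` with
#' `eps_i ~ Normal(0, noise_sd^2)` i.i.d.; reproducible given `seed`.
#'
#' @param model a [calibrate_outcome_model()] result.
#' @param covariates covariate table whose columns match the model.
#' @param seed RNG seed for the noise draw.
#' @return Numeric outcome vector (mmHg).
#' @export
generate_outcome <- function(model, covariates, seed = 1) {
  stopifnot(inherits(model, "calibrated_outcome_model"))
  if (!identical(names(covariates), names(model$coefficients))) {
    stop("covariate columns do not match the model's coefficients",
         call. = FALSE)
  }
  X <- as.matrix(covariates)
  Xs <- sweep(sweep(X, 2, model$center, "-"), 2, model$scale, "/")
  lp <- model$intercept + drop(Xs %*% model$coefficients)
  eps <- withr::with_seed(seed, stats::rnorm(nrow(X), 0, model$noise_sd))
  lp + eps
}

#' Expand a table by bootstrap resampling
#'
#' Draws `m` rows with replacement from a source table, carrying every column
#' (an outcome column included) along. Used to grow a validation sample to a
#' large fixed size so external-performance estimates are not dominated by
#' validation-sample noise.
#'
#' @param table source data.frame (nonempty when `m > 0`).
#' @param m number of output rows (`m = 0` returns an empty table with the
#'   same columns).
#' @param seed RNG seed; reproducible.
#' @return A data.frame with `m` rows, each identical to some source row.
#' @export
bootstrap_expand <- function(table, m, seed = 1) {
  stopifnot(is.data.frame(table))
  m <- as.integer(m)
  if (is.na(m) || m < 0L) stop("m must be a nonnegative integer", call. = FALSE)
  if (m == 0L) {
    out <- table[0L, , drop = FALSE]
  } else {
    if (nrow(table) == 0L) {
      stop("cannot bootstrap-expand an empty table", call. = FALSE)
    }
    idx <- withr::with_seed(seed,
                            sample.int(nrow(table), m, replace = TRUE))
    out <- table[idx, , drop = FALSE]
  }
  rownames(out) <- NULL
  for (a in c("kinds", "cohort_id", "role")) {
    attr(out, a) <- attr(table, a)
  }
  class(out) <- class(table)
  out
}

#' Baseline-characteristics comparison table
#'
#' Summarises each shared variable in two samples and tests the difference:
#' continuous variables by mean +/- SD per sample and a two-sample t-test,
#' binary variables by N (%) and a chi-squared test on the 2 x 2 counts.
#'
#' @param derivation,validation data.frames sharing the same columns; an
#'   outcome column may be included and is summarised like any continuous
#'   variable.
#' @return A data.frame with one row per variable: `variable`, `kind`,
#'   formatted `derivation`/`validation` summaries, numeric
#'   `mean_derivation`, `sd_derivation`, `mean_validation`, `sd_validation`
#'   (continuous) or prevalences (binary), and `p_value`.
#' @export
baseline_table <- function(derivation, validation) {
  stopifnot(is.data.frame(derivation), is.data.frame(validation))
  if (!identical(names(derivation), names(validation))) {
    stop("derivation and validation tables must share the same columns",
         call. = FALSE)
  }
  kinds <- variable_kinds(derivation)
  rows <- lapply(names(derivation), function(v) {
    xd <- derivation[[v]]
    xv <- validation[[v]]
    if (kinds[[v]] == "continuous") {
      p <- if (stats::sd(xd) == 0 && stats::sd(xv) == 0) {
        if (mean(xd) == mean(xv)) 1 else 0
      } else {
        stats::t.test(xd, xv)$p.value
      }
      data.frame(
        variable = v, kind = "continuous",
        derivation = sprintf("%.2f ± %.2f", mean(xd), stats::sd(xd)),
        validation = sprintf("%.2f ± %.2f", mean(xv), stats::sd(xv)),
        mean_derivation = mean(xd), sd_derivation = stats::sd(xd),
        mean_validation = mean(xv), sd_validation = stats::sd(xv),
        p_value = p, stringsAsFactors = FALSE)
    } else {
      counts <- rbind(c(sum(xd), length(xd) - sum(xd)),
                      c(sum(xv), length(xv) - sum(xv)))
      p <- if (any(colSums(counts) == 0)) {
        # degenerate margin (all zeros or all ones in both samples)
        if (mean(xd) == mean(xv)) 1 else NA_real_
      } else {
        suppressWarnings(stats::chisq.test(counts, correct = FALSE)$p.value)
      }
      data.frame(
        variable = v, kind = "binary",
        derivation = sprintf("%d (%.1f%%)", sum(xd), 100 * mean(xd)),
        validation = sprintf("%d (%.1f%%)", sum(xv), 100 * mean(xv)),
        mean_derivation = mean(xd), sd_derivation = NA_real_,
        mean_validation = mean(xv), sd_validation = NA_real_,
        p_value = p, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read a covariate table as CSV with a provenance sidecar
#'
#' The table itself is written as a plain headered CSV; provenance (cohort id,
#' sample role, seed, column kinds) goes to `<path>.json` so a table read back
#' with [read_covariate_table()] round-trips its metadata.
#'
#' @param table a covariate table (optionally with an outcome column).
#' @param path CSV file path.
#' @return `write_covariate_table` returns `path` invisibly;
#'   `read_covariate_table` returns the table.
#' @export
write_covariate_table <- function(table, path) {
  out <- as.data.frame(table)
  # 17 significant digits make the double -> text -> double trip lossless
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  meta <- list(cohort_id = attr(table, "cohort_id"),
               role = attr(table, "role"),
               seed = attr(table, "seed"),
               kinds = as.list(variable_kinds(table)))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_covariate_table
#' @export
read_covariate_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    kinds <- unlist(meta$kinds)
    as_covariate_table(df, kinds = kinds[names(df)],
                       cohort_id = meta$cohort_id %||% NA_character_,
                       role = meta$role %||% NA_character_,
                       seed = meta$seed %||% NA_integer_)
  } else {
    as_covariate_table(df, kinds = variable_kinds(df))
  }
}
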