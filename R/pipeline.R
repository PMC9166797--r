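#' Configure a benchmarking study
#'
#' Resolves everything an end-to-end run needs: the cohort, the
#' signal fraction of the synthetic reference truth, the methods to compare
#' with their (fixed) hyperparameters, the number of Monte Carlo replicates,
#' the validation expansion size, and the master seed from which every stage
#' derives its substream.
#'
#' @param cohort `"ami"`, `"chf"`, a config file path, or a
#'   [cohort_config()] object.
#' @param signal_fraction variance proportion carried by the synthetic
#'   truth's linear predictor (default 0.2).
#' @param methods methods to include (default: all six).
#' @param hyperparameters named list of [learner_spec()] objects; defaults to
#'   [default_hyperparameters()] for the packaged cohorts (must be supplied
#'   for user cohorts).
#' @param replicates Monte Carlo replicates per generating process
#'   (default 1000).
#' @param expand_to validation bootstrap-expansion size (default 100000).
#' @param n_derivation,n_validation overrides of the configured sample sizes
#'   (used by the desk preset).
#' @param seed master seed.
#' @param preset `"full"` (defaults as above) or `"desk"`, a scaled-down
#'   preset fixing `replicates = 50`, `n_derivation = 1000`,
#'   `expand_to = 5000` for fast interactive runs.
#' @return An object of class `study_config`.
#' @export
study_config <- function(cohort = "ami", signal_fraction = 0.2,
                         methods = c("ols_rcs", "lasso", "ridge",
                                     "boosted_trees", "random_forest",
                                     "nnet1"),
                         hyperparameters = NULL,
                         replicates = 1000, expand_to = 100000,
                         n_derivation = NULL, n_validation = NULL,
                         seed = 1, preset = c("full", "desk")) {
  preset <- match.arg(preset)
  cfg <- if (inherits(cohort, "cohort_config")) cohort else
    load_cohort_config(cohort)
  if (is.null(hyperparameters)) {
    if (!cfg$cohort_id %in% c("ami", "chf")) {
      stop("hyperparameters must be supplied for non-packaged cohorts",
           call. = FALSE)
    }
    hyperparameters <- default_hyperparameters(cfg$cohort_id)
  }
  missing_specs <- setdiff(methods, names(hyperparameters))
  if (length(missing_specs)) {
    stop("no learner_spec for method(s): ",
         paste(missing_specs, collapse = ", "), call. = FALSE)
  }
  for (m in methods) {
    if (!inherits(hyperparameters[[m]], "learner_spec")) {
      stop("hyperparameters[['", m, "']] is not a learner_spec", call. = FALSE)
    }
  }
  if (preset == "desk") {
    replicates <- 50L
    n_derivation <- 1000L
    expand_to <- 5000L
  }
  structure(
    list(cohort = cfg, signal_fraction = signal_fraction, methods = methods,
         hyperparameters = hyperparameters[methods],
         replicates = as.integer(replicates),
         expand_to = as.integer(expand_to),
         n_derivation = as.integer(n_derivation %||% cfg$n_derivation),
         n_validation = as.integer(n_validation %||% cfg$n_validation),
         seed = seed, preset = preset),
    class = "study_config"
  )
}

#' @export
print.study_config <- function(x, ...) {
  cat("Study configuration (", x$preset, " preset)\n",
      "  cohort: ", x$cohort$cohort_id, " (", x$n_derivation,
      " derivation / ", x$n_validation, " validation)\n",
      "  methods: ", paste(x$methods, collapse = ", "), "\n",
      "  signal fraction ", x$signal_fraction, "; replicates ",
      x$replicates, "; expand_to ", x$expand_to, "; seed ", x$seed, "\n",
      sep = "")
  invisible(x)
}

# synthesize the base cohort data a study runs on: covariates for both
# sample roles plus a calibrated reference outcome shared by both
synthesize_base_data <- function(sc) {
  cfg <- sc$cohort
  x_deriv <- simulate_covariates(cfg, "derivation", sc$n_derivation,
                                 seed = seed_substream(sc$seed, "covariates_derivation"))
  x_valid <- simulate_covariates(cfg, "validation", sc$n_validation,
                                 seed = seed_substream(sc$seed, "covariates_validation"))
  model <- calibrate_outcome_model(cfg, x_deriv, sc$signal_fraction,
                                   seed = seed_substream(sc$seed, "calibration"))
  list(x_derivation = x_deriv,
       y_derivation = generate_outcome(model, x_deriv,
                                       seed = seed_substream(sc$seed, "outcome_derivation")),
       x_validation = x_valid,
       y_validation = generate_outcome(model, x_valid,
                                       seed = seed_substream(sc$seed, "outcome_validation")),
       outcome_model = model)
}

#' Run the empirical comparison
#'
#' Fits every configured method once on the derivation sample and evaluates
#' its predictions on the validation sample with the three metrics — the
#' single-dataset comparison that motivates the simulation study. By default
#' the samples are synthesized from the study configuration; user data can be
#' supplied as data.frames or CSV paths whose columns are the predictors plus
#' an outcome column named as in the cohort configuration.
#'
#' @param config a [study_config()].
#' @param derivation,validation optional user data (data.frame or CSV path).
#' @return data.frame with one row per method: `method`, `r2`, `mse`, `mae`.
#' @export
run_empirical <- function(config, derivation = NULL, validation = NULL) {
  stopifnot(inherits(config, "study_config"))
  outcome_name <- config$cohort$outcome$name
  predictor_names <- cohort_variable_names(config$cohort)
  load_user <- function(d, label) {
    if (is.character(d)) d <- utils::read.csv(d, check.names = FALSE)
    if (!outcome_name %in% names(d)) {
      stop(label, " data must contain the outcome column '", outcome_name,
           "'", call. = FALSE)
    }
    if (!all(predictor_names %in% names(d))) {
      stop(label, " data is missing predictor column(s): ",
           paste(setdiff(predictor_names, names(d)), collapse = ", "),
           call. = FALSE)
    }
    list(x = d[, predictor_names, drop = FALSE], y = d[[outcome_name]])
  }
  if (is.null(derivation) != is.null(validation)) {
    stop("supply both derivation and validation data, or neither",
         call. = FALSE)
  }
  if (is.null(derivation)) {
    base <- synthesize_base_data(config)
    deriv <- list(x = base$x_derivation, y = base$y_derivation)
    valid <- list(x = base$x_validation, y = base$y_validation)
  } else {
    deriv <- load_user(derivation, "derivation")
    valid <- load_user(validation, "validation")
  }
  rows <- lapply(config$methods, function(m) {
    fit <- fit_learner(config$hyperparameters[[m]], deriv$x, deriv$y,
                       seed = seed_substream(config$seed, paste0("fit_", m)))
    pred <- predict(fit, valid$x)
    data.frame(method = m,
               r2 = r2_pearson(valid$y, pred),
               mse = mse(valid$y, pred),
               mae = mae(valid$y, pred),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the factorial simulation study
#'
#' The full design: for each anchor method, a data-generating process is
#' built from the base data ([build_dgp()]), `replicates` replicate pairs are
#' drawn, every included method is fit on each simulated derivation sample
#' and evaluated on the corresponding simulated validation sample, and the
#' per-replicate records are aggregated to mean +/- SD summaries.
#'
#' @param config a [study_config()].
#' @param anchors methods to use as data-generating anchors (default: the
#'   configured methods).
#' @param verbose print per-anchor progress.
#' @return An object of class `simulation_result`: `records` (long
#'   data.frame, one row per anchor x method x replicate), `summary` (from
#'   [summarize_performance()]), `signal_proportions` (per-anchor oracle
#'   ceilings), and `manifest` (resolved configuration, per-stage seeds and
#'   timings).
#' @export
run_simulation <- function(config, anchors = config$methods, verbose = FALSE) {
  stopifnot(inherits(config, "study_config"))
  bad <- setdiff(anchors, names(config$hyperparameters))
  if (length(bad)) {
    stop("no learner_spec for anchor(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  t_start <- Sys.time()
  base <- synthesize_base_data(config)
  specs <- config$hyperparameters
  records <- list()
  signal <- numeric(0)
  timings <- list()
  for (anchor in anchors) {
    t0 <- Sys.time()
    if (verbose) message("anchor: ", anchor)
    gp <- build_dgp(specs[[anchor]], base$x_derivation, base$y_derivation,
                    base$x_validation, expand_to = config$expand_to,
                    seed = seed_substream(config$seed, paste0("dgp_", anchor)))
    signal[anchor] <- dgp_signal_proportion(gp)
    rep_seed <- seed_substream(config$seed, paste0("replicates_", anchor))
    recs <- generate_replicates(
      gp, config$replicates, base_seed = rep_seed,
      FUN = function(pair, r) {
        evaluate_replicate(pair, specs, seed = seed_substream(pair$seed, "eval"),
                           dgp_id = anchor, replicate = r)
      })
    records[[anchor]] <- do.call(rbind, recs)
    timings[[anchor]] <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  }
  records <- do.call(rbind, records)
  rownames(records) <- NULL
  manifest <- list(
    cohort_id = config$cohort$cohort_id,
    preset = config$preset,
    signal_fraction = config$signal_fraction,
    n_derivation = config$n_derivation,
    n_validation = config$n_validation,
    expand_to = config$expand_to,
    replicates = config$replicates,
    seed = config$seed,
    hyperparameters = lapply(specs, function(s) {
      c(list(method = s$method), s$hyperparameters)
    }),
    anchors = anchors,
    package_version = as.character(utils::packageVersion("sbpbench")),
    timings_sec = timings,
    total_sec = as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  )
  structure(
    list(records = records, summary = summarize_performance(records),
         signal_proportions = signal, manifest = manifest),
    class = "simulation_result"
  )
}

#' @export
print.simulation_result <- function(x, ...) {
  m <- x$manifest
  cat("Simulation study: cohort '", m$cohort_id, "', ",
      length(m$anchors), " generating processes x ",
      length(m$hyperparameters), " methods x ", m$replicates,
      " replicates\n", sep = "")
  cat("Mean validation R-squared by (anchor, method):\n")
  r2 <- x$summary[x$summary$metric == "r2", ]
  wide <- stats::reshape(r2[, c("dgp_id", "method", "mean")],
                         idvar = "dgp_id", timevar = "method",
                         direction = "wide")
  names(wide) <- sub("^mean\\.", "", names(wide))
  print(wide, row.names = FALSE, digits = 3)
  invisible(x)
}
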