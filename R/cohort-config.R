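#' Per-variable marginal specification
#'
#' Describes one predictor (or the outcome) of a cohort by its marginal
#' summaries in the derivation and validation samples: mean and standard
#' deviation for continuous variables, prevalence (a proportion) for binary
#' indicators.
#'
#' @param name variable name (unique within a cohort).
#' @param kind `"continuous"` or `"binary"`.
#' @param derivation,validation named lists: `list(mean =, sd =)` for
#'   continuous variables, `list(prevalence =)` for binary ones. A binary
#'   role may carry `imputed = TRUE` to flag a value that was not observed
#'   but filled in (e.g. a suppressed small cell).
#' @return An object of class `variable_spec`.
#' @export
#' @examples
#' variable_spec("age", "continuous",
#'               derivation = list(mean = 66.5, sd = 13.6),
#'               validation = list(mean = 69.1, sd = 14.3))
variable_spec <- function(name, kind = c("continuous", "binary"),
                          derivation, validation = derivation) {
  kind <- match.arg(kind)
  check_role <- function(role, label) {
    if (!is.list(role)) {
      stop("variable '", name, "': ", label, " marginal must be a list",
           call. = FALSE)
    }
    if (kind == "continuous") {
      for (f in c("mean", "sd")) {
        if (is.null(role[[f]]) || !is.numeric(role[[f]])) {
          stop("variable '", name, "': missing or non-numeric field '", f,
               "' in ", label, " marginal", call. = FALSE)
        }
      }
      if (role$sd < 0) {
        stop("variable '", name, "': field 'sd' must be >= 0 (", label, ")",
             call. = FALSE)
      }
    } else {
      pv <- role$prevalence
      if (is.null(pv) || !is.numeric(pv)) {
        stop("variable '", name, "': missing or non-numeric field ",
             "'prevalence' in ", label, " marginal", call. = FALSE)
      }
      if (pv < 0 || pv > 1) {
        stop("variable '", name, "': field 'prevalence' must lie in [0, 1], ",
             "got ", pv, " (", label, ")", call. = FALSE)
      }
    }
    role
  }
  structure(
    list(name = as.character(name), kind = kind,
         derivation = check_role(derivation, "derivation"),
         validation = check_role(validation, "validation")),
    class = "variable_spec"
  )
}

#' Cohort configuration
#'
#' Bundles everything needed to synthesise a disease cohort: the ordered
#' predictor marginals, the outcome marginal (discharge systolic blood
#' pressure), derivation/validation sample sizes, and the latent correlation
#' structure used by the Gaussian copula.
#'
#' @param cohort_id short label (e.g. `"ami"`, `"chf"`, or a user label).
#' @param variables list of [variable_spec()] objects (predictors only).
#' @param outcome a continuous [variable_spec()] for the outcome.
#' @param n_derivation,n_validation positive sample sizes.
#' @param correlation list describing the latent correlation:
#'   `list(mode = "independent")`, `list(mode = "exchangeable", rho =)`, or
#'   `list(mode = "matrix", matrix =)` with a p x p positive-semidefinite
#'   correlation matrix.
#' @return An object of class `cohort_config`.
#' @seealso [load_cohort_config()] for the packaged AMI/CHF configurations.
#' @export
cohort_config <- function(cohort_id, variables, outcome,
                          n_derivation, n_validation,
                          correlation = list(mode = "exchangeable", rho = 0.2)) {
  stopifnot(is.list(variables), length(variables) >= 1L)
  variables <- lapply(variables, function(v) {
    if (!inherits(v, "variable_spec")) {
      v <- variable_spec(v$name, v$kind, v$derivation, v$validation)
    }
    v
  })
  nms <- vapply(variables, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    stop("duplicate variable names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  }
  if (!inherits(outcome, "variable_spec")) {
    outcome <- variable_spec(outcome$name, outcome$kind,
                             outcome$derivation, outcome$validation)
  }
  if (outcome$kind != "continuous") {
    stop("field 'outcome' must be a continuous variable_spec", call. = FALSE)
  }
  n_derivation <- as.integer(n_derivation)
  n_validation <- as.integer(n_validation)
  if (is.na(n_derivation) || n_derivation < 1L) {
    stop("field 'n_derivation' must be a positive integer", call. = FALSE)
  }
  if (is.na(n_validation) || n_validation < 1L) {
    stop("field 'n_validation' must be a positive integer", call. = FALSE)
  }
  cfg <- structure(
    list(cohort_id = as.character(cohort_id), variables = variables,
         outcome = outcome, n_derivation = n_derivation,
         n_validation = n_validation,
         correlation = validate_correlation(correlation, length(variables))),
    class = "cohort_config"
  )
  cfg
}

validate_correlation <- function(correlation, p) {
  if (is.null(correlation$mode)) {
    stop("field 'correlation$mode' is required", call. = FALSE)
  }
  mode <- match.arg(correlation$mode, c("independent", "exchangeable", "matrix"))
  out <- list(mode = mode)
  if (mode == "exchangeable") {
    rho <- correlation$rho
    if (is.null(rho) || !is.numeric(rho)) {
      stop("field 'correlation$rho' is required for exchangeable mode",
           call. = FALSE)
    }
    if (p > 1 && (rho <= -1 / (p - 1) || rho >= 1)) {
      stop("field 'correlation$rho' must lie in (-1/(p-1), 1) = (",
           round(-1 / (p - 1), 4), ", 1)", call. = FALSE)
    }
    out$rho <- rho
  } else if (mode == "matrix") {
    m <- as.matrix(correlation$matrix)
    if (nrow(m) != p || ncol(m) != p) {
      stop("field 'correlation$matrix' must be ", p, " x ", p, call. = FALSE)
    }
    if (max(abs(m - t(m))) > 1e-8 || any(abs(diag(m) - 1) > 1e-8)) {
      stop("field 'correlation$matrix' must be symmetric with unit diagonal",
           call. = FALSE)
    }
    ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) {
      stop("field 'correlation$matrix' is not positive semidefinite ",
           "(smallest eigenvalue ", signif(min(ev), 3), ")", call. = FALSE)
    }
    out$matrix <- m
  }
  out
}

# latent correlation matrix implied by the config
correlation_matrix <- function(config) {
  p <- length(config$variables)
  cr <- config$correlation
  switch(cr$mode,
         independent = diag(p),
         exchangeable = {
           m <- matrix(cr$rho, p, p)
           diag(m) <- 1
           m
         },
         matrix = cr$matrix)
}

#' Load a cohort configuration
#'
#' Loads one of the packaged cohort configurations (`"ami"`: 33 predictors,
#' 8145 derivation / 4444 validation subjects; `"chf"`: 28 predictors, 7156 /
#' 6818 subjects) or a user YAML file following the same schema: top-level
#' keys `cohort_id`, `n_derivation`, `n_validation`, `correlation`
#' (`mode`/`rho`/`matrix`), `outcome`, and `variables`, where each variable
#' has `name`, `kind` (`continuous`/`binary`) and per-role marginals
#' `derivation`/`validation` holding `mean` + `sd` or `prevalence`.
#'
#' In the packaged AMI configuration the validation prevalence of cardiogenic
#' shock was suppressed at source; it is imputed at 0.005 and flagged with
#' `imputed: TRUE` on that marginal.
#'
#' @param source `"ami"`, `"chf"`, or the path of a YAML configuration file.
#' @return A validated [cohort_config()] object.
#' @export
#' @examples
#' cfg <- load_cohort_config("ami")
#' cfg
load_cohort_config <- function(source) {
  stopifnot(is.character(source), length(source) == 1L)
  path <- if (source %in% c("ami", "chf")) {
    system.file("extdata", paste0("cohort_", source, ".yaml"),
                package = "sbpbench", mustWork = TRUE)
  } else if (file.exists(source)) {
    source
  } else {
    stop("unknown cohort configuration '", source,
         "': expected \"ami\", \"chf\", or the path of a config file",
         call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  for (f in c("cohort_id", "n_derivation", "n_validation", "variables",
              "outcome")) {
    if (is.null(raw[[f]])) {
      stop("cohort config '", source, "': missing field '", f, "'",
           call. = FALSE)
    }
  }
  vars <- lapply(raw$variables, function(v) {
    variable_spec(v$name, v$kind, v$derivation, v$validation)
  })
  outc <- variable_spec(raw$outcome$name, raw$outcome$kind,
                        raw$outcome$derivation, raw$outcome$validation)
  cohort_config(raw$cohort_id, vars, outc,
                raw$n_derivation, raw$n_validation,
                raw$correlation %||% list(mode = "exchangeable", rho = 0.2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cohort_config <- function(x, ...) {
  kinds <- vapply(x$variables, `[[`, character(1), "kind")
  cat("Cohort configuration '", x$cohort_id, "'\n", sep = "")
  cat("  predictors:  ", length(x$variables), " (",
      sum(kinds == "continuous"), " continuous, ",
      sum(kinds == "binary"), " binary)\n", sep = "")
  cat("  outcome:     ", x$outcome$name, " (derivation mean ",
      x$outcome$derivation$mean, ", sd ", x$outcome$derivation$sd, ")\n",
      sep = "")
  cat("  sample size: ", x$n_derivation, " derivation / ",
      x$n_validation, " validation\n", sep = "")
  cat("  correlation: ", x$correlation$mode,
      if (x$correlation$mode == "exchangeable") {
        paste0(" (rho = ", x$correlation$rho, ")")
      } else "",
      "\n", sep = "")
  invisible(x)
}

# marginal summary for one sample role as a data.frame
role_marginals <- function(config, role = c("derivation", "validation")) {
  role <- match.arg(role)
  do.call(rbind, lapply(config$variables, function(v) {
    m <- v[[role]]
    data.frame(name = v$name, kind = v$kind,
               mean = if (v$kind == "continuous") m$mean else NA_real_,
               sd = if (v$kind == "continuous") m$sd else NA_real_,
               prevalence = if (v$kind == "binary") m$prevalence else NA_real_,
               stringsAsFactors = FALSE)
  }))
}

#' Predictor names of a cohort configuration
#' @param config a [cohort_config()].
#' @return Character vector of predictor names, in configuration order.
#' @export
cohort_variable_names <- function(config) {
  vapply(config$variables, `[[`, character(1), "name")
}
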