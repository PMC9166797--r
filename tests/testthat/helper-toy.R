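# Small programmatic cohort used where the packaged 33-predictor cohorts
# would be needlessly slow. 3 continuous + 2 binary predictors, outcome
# marginal loosely blood-pressure-like.
toy_config <- function(rho = 0.2, n_derivation = 400, n_validation = 300) {
  vars <- list(
    variable_spec("age", "continuous",
                  derivation = list(mean = 70, sd = 12),
                  validation = list(mean = 72, sd = 12)),
    variable_spec("sbp0", "continuous",
                  derivation = list(mean = 150, sd = 30),
                  validation = list(mean = 147, sd = 31)),
    variable_spec("creat", "continuous",
                  derivation = list(mean = 110, sd = 60),
                  validation = list(mean = 115, sd = 70)),
    variable_spec("female", "binary",
                  derivation = list(prevalence = 0.4),
                  validation = list(prevalence = 0.45)),
    variable_spec("diabetes", "binary",
                  derivation = list(prevalence = 0.3),
                  validation = list(prevalence = 0.33))
  )
  outcome <- variable_spec("discharge_sbp", "continuous",
                           derivation = list(mean = 122, sd = 20),
                           validation = list(mean = 124, sd = 21))
  cohort_config("toy", vars, outcome, n_derivation, n_validation,
                correlation = list(mode = "exchangeable", rho = rho))
}

# toy derivation data with a calibrated outcome; returns x, y and the model
toy_data <- function(n = 400, signal_fraction = 0.5, seed = 1,
                     config = toy_config()) {
  x <- simulate_covariates(config, "derivation", n, seed = seed)
  model <- calibrate_outcome_model(config, x, signal_fraction,
                                   seed = seed_substream(seed, "calib"))
  y <- generate_outcome(model, x, seed = seed_substream(seed, "outcome"))
  list(x = x, y = y, model = model, config = config)
}

# exact noiseless linear truth on a single continuous predictor
linear_truth <- function(n = 200, a = 2, b = 3, seed = 1) {
  x <- withr::with_seed(seed, data.frame(x = runif(n, 0, 10)))
  attr(x, "kinds") <- c(x = "continuous")
  list(x = x, y = a + b * x$x)
}
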