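test_that("covariate synthesis is deterministic in the seed", {
  cfg <- toy_config()
  a <- simulate_covariates(cfg, "derivation", 200, seed = 7)
  b <- simulate_covariates(cfg, "derivation", 200, seed = 7)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c2 <- simulate_covariates(cfg, "derivation", 200, seed = 8)
  expect_true(any(as.matrix(a) != as.matrix(c2)))
})

test_that("degenerate marginals behave as their limits", {
  vars <- list(
    variable_spec("never", "binary", derivation = list(prevalence = 0)),
    variable_spec("always", "binary", derivation = list(prevalence = 1)),
    variable_spec("const", "continuous", derivation = list(mean = 5, sd = 0)),
    variable_spec("norm", "continuous", derivation = list(mean = 0, sd = 1))
  )
  cfg <- cohort_config("degen", vars, toy_config()$outcome, 50, 50,
                       correlation = list(mode = "independent"))
  x <- simulate_covariates(cfg, "derivation", 500, seed = 1)
  expect_true(all(x$never == 0))
  expect_true(all(x$always == 1))
  expect_true(all(x$const == 5))
  expect_gt(sd(x$norm), 0)
})

test_that("simulated samples recover the configured marginals", {
  # one large AMI derivation draw reused by the calibration checks below
  cfg <- load_cohort_config("ami")
  n <- 50000
  x <- simulate_covariates(cfg, "derivation", n, seed = 42)
  for (v in cfg$variables) {
    col <- x[[v$name]]
    if (v$kind == "continuous") {
      se_mean <- v$derivation$sd / sqrt(n)
      expect_lt(abs(mean(col) - v$derivation$mean), 4 * se_mean + 1e-12)
      # SE of the SD for a normal sample: sd / sqrt(2(n-1))
      expect_lt(abs(sd(col) - v$derivation$sd),
                4 * v$derivation$sd / sqrt(2 * (n - 1)) + 1e-12)
    } else {
      pv <- v$derivation$prevalence
      expect_lt(abs(mean(col) - pv), 4 * sqrt(pv * (1 - pv) / n) + 1e-12)
    }
  }

  # validation-role marginals are the validation column of the config
  xv <- simulate_covariates(cfg, "validation", 20000, seed = 43)
  fem <- cfg$variables[[which(cohort_variable_names(cfg) == "female")]]
  expect_lt(abs(mean(xv$female) - fem$validation$prevalence),
            4 * sqrt(0.385 * 0.615 / 20000))
})

test_that("latent correlation propagates monotonically to the observed scale", {
  n <- 50000
  avg_cor <- function(rho) {
    cfg <- toy_config(rho = rho)
    x <- simulate_covariates(cfg, "derivation", n, seed = 5)
    cc <- cor(as.matrix(x[, c("age", "sbp0", "creat")]))
    mean(cc[upper.tri(cc)])
  }
  r1 <- avg_cor(0.1)
  r2 <- avg_cor(0.5)
  expect_gt(r2, r1)
  # continuous-continuous pairs inherit the latent correlation exactly
  expect_lt(abs(r2 - 0.5), 0.02)
})

test_that("outcome calibration hits the target mean, variance and signal split", {
  cfg <- load_cohort_config("ami")
  n <- 50000
  x <- simulate_covariates(cfg, "derivation", n, seed = 42)

  for (sf in c(0, 0.2, 0.5)) {
    model <- calibrate_outcome_model(cfg, x, signal_fraction = sf, seed = 9)
    expect_equal(model$noise_sd, 19.69 * sqrt(1 - sf))
    y <- generate_outcome(model, x, seed = 10)
    # calibration identity: outcome variance within 5% of target_sd^2
    expect_lt(abs(var(y) / 19.69^2 - 1), 0.05)
    expect_lt(abs(mean(y) - 120.40), 4 * 19.69 / sqrt(n))
    if (sf > 0) {
      Xs <- sweep(sweep(as.matrix(x), 2, model$center, "-"),
                  2, model$scale, "/")
      lp <- model$intercept + drop(Xs %*% model$coefficients)
      expect_lt(abs(var(lp) / var(y) - sf), 0.01)
    }
  }

  m0 <- calibrate_outcome_model(cfg, x, signal_fraction = 0)
  expect_true(all(m0$coefficients == 0))
  expect_equal(m0$intercept, 120.40)
  expect_equal(m0$noise_sd, 19.69)

  expect_error(calibrate_outcome_model(cfg, x, signal_fraction = 1),
               "signal_fraction")
  xc <- x
  for (j in seq_along(xc)) xc[[j]] <- rep(xc[[j]][1], nrow(xc))
  expect_error(calibrate_outcome_model(cfg, xc, signal_fraction = 0.2),
               "constant linear predictor")
})

test_that("outcome generation is the linear predictor plus seeded noise", {
  td <- toy_data(n = 300, signal_fraction = 0.5, seed = 2)
  model <- td$model
  # noiseless: force noise_sd to 0 and compare against the linear predictor
  m0 <- model
  m0$noise_sd <- 0
  y0 <- generate_outcome(m0, td$x, seed = 1)
  Xs <- sweep(sweep(as.matrix(td$x), 2, model$center, "-"), 2, model$scale, "/")
  expect_equal(y0, model$intercept + drop(Xs %*% model$coefficients),
               tolerance = 1e-12)
  # linearity: doubling every coefficient doubles (outcome - intercept)
  m2 <- m0
  m2$coefficients <- 2 * m0$coefficients
  expect_equal(generate_outcome(m2, td$x, seed = 1) - m2$intercept,
               2 * (y0 - m0$intercept), tolerance = 1e-10)
  # determinism and schema checking
  expect_identical(generate_outcome(model, td$x, seed = 3),
                   generate_outcome(model, td$x, seed = 3))
  expect_error(generate_outcome(model, td$x[, -1]), "do not match")
})

test_that("bootstrap expansion resamples source rows with replacement", {
  td <- toy_data(n = 120, seed = 3)
  tab <- td$x
  tab$discharge_sbp <- td$y
  big <- bootstrap_expand(tab, 1000, seed = 1)
  expect_identical(nrow(big), 1000L)
  key <- do.call(paste, c(tab, sep = "\r"))
  expect_true(all(do.call(paste, c(big, sep = "\r")) %in% key))

  empty <- bootstrap_expand(tab, 0)
  expect_identical(nrow(empty), 0L)
  expect_identical(names(empty), names(tab))

  one <- bootstrap_expand(tab[1, , drop = FALSE], 25, seed = 2)
  expect_true(all(duplicated(one)[-1]))

  expect_error(bootstrap_expand(tab[0, ], 5), "empty")
  expect_identical(bootstrap_expand(tab, 50, seed = 4),
                   bootstrap_expand(tab, 50, seed = 4))
})

test_that("baseline tables summarise and test derivation/validation differences", {
  td <- toy_data(n = 500, seed = 4)
  x <- td$x

  same <- baseline_table(x, x)
  expect_identical(nrow(same), ncol(x))
  expect_true(all(same$p_value[same$kind == "binary"] > 0.99))
  expect_true(all(same$p_value[same$kind == "continuous"] > 0.99))
  expect_equal(same$mean_derivation, same$mean_validation)

  # shift one continuous column by 5 standard errors of the difference
  x2 <- x
  se_diff <- sd(x$age) * sqrt(2 / nrow(x))
  x2$age <- x2$age + 5 * se_diff
  shifted <- baseline_table(x, x2)
  expect_lt(shifted$p_value[shifted$variable == "age"], 0.01)
  # untouched columns keep equal means
  expect_equal(shifted$mean_derivation[shifted$variable == "sbp0"],
               shifted$mean_validation[shifted$variable == "sbp0"])

  expect_error(baseline_table(x, x[, -1]), "share the same columns")
})

test_that("covariate tables round-trip through CSV with provenance sidecar", {
  cfg <- toy_config()
  x <- simulate_covariates(cfg, "derivation", 60, seed = 11)
  path <- tempfile(fileext = ".csv")
  write_covariate_table(x, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- read_covariate_table(path)
  expect_equal(as.data.frame(back), as.data.frame(x), tolerance = 1e-12)
  expect_identical(attr(back, "role"), "derivation")
  expect_identical(variable_kinds(back), variable_kinds(x))
})
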