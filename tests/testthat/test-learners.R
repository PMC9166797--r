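test_that("learner specs validate their hyperparameters", {
  expect_error(learner_spec("ols_rcs"), "required")
  expect_error(learner_spec("ols_rcs", knots = 9), "3..7")
  expect_error(learner_spec("lasso", lambda = -1), ">= 0")
  expect_error(learner_spec("boosted_trees", interaction_depth = 0,
                            learning_rate = 0.1), ">= 1")
  expect_identical(
    learner_spec("boosted_trees", interaction_depth = 4,
                 learning_rate = 0.065)$hyperparameters$n_trees, 100L)
  expect_identical(
    learner_spec("random_forest", mtry = 6,
                 min_node_size = 20)$hyperparameters$n_trees, 500L)
})

test_that("packaged tuned hyperparameters match the shipped defaults", {
  ami <- default_hyperparameters("ami")
  expect_identical(ami$ols_rcs$hyperparameters$knots, 3L)
  expect_equal(ami$lasso$hyperparameters$lambda, 0.08596)
  expect_equal(ami$ridge$hyperparameters$lambda, 0.56553)
  expect_identical(ami$boosted_trees$hyperparameters$interaction_depth, 4L)
  expect_equal(ami$boosted_trees$hyperparameters$learning_rate, 0.065)
  expect_identical(ami$random_forest$hyperparameters$mtry, 6L)
  chf <- default_hyperparameters("chf")
  expect_identical(chf$ols_rcs$hyperparameters$knots, 5L)
  expect_identical(chf$nnet1$hyperparameters$hidden_units, 6L)
  expect_equal(chf$nnet1$hyperparameters$weight_decay, 0)
  expect_identical(chf$random_forest$hyperparameters$mtry, 8L)
})

test_that("ols_rcs reproduces a noiseless linear truth exactly", {
  lt <- linear_truth(n = 200)
  fit <- fit_learner(learner_spec("ols_rcs", knots = 3), lt$x, lt$y)
  expect_lt(max(abs(predict(fit, lt$x) - lt$y)), 1e-8)
  expect_lt(fit$residual_sd, 1e-8)
})

test_that("ols_rcs reports rank failures rather than regularizing", {
  lt <- linear_truth(n = 200)
  expect_error(fit_learner(learner_spec("ols_rcs", knots = 3),
                           lt$x[1:3, , drop = FALSE], lt$y[1:3]),
               "rank failure")
  # a duplicated predictor makes the design singular
  x2 <- lt$x
  x2$x2 <- x2$x
  attr(x2, "kinds") <- c(x = "continuous", x2 = "continuous")
  expect_error(fit_learner(learner_spec("ols_rcs", knots = 3), x2, lt$y),
               "rank")
})

test_that("full shrinkage collapses penalized fits to the outcome mean", {
  td <- toy_data(n = 300, seed = 5)
  lasso_inf <- fit_learner(learner_spec("lasso", lambda = 1e6), td$x, td$y)
  expect_lt(max(abs(predict(lasso_inf, td$x) - mean(td$y))), 1e-6)

  boost0 <- fit_learner(learner_spec("boosted_trees", interaction_depth = 3,
                                     learning_rate = 0, n_trees = 20),
                        td$x, td$y)
  expect_lt(max(abs(predict(boost0, td$x) - mean(td$y))), 1e-5)
})

test_that("ridge at lambda = 0 matches the normal-equations OLS oracle", {
  # tiny fixed design; oracle is the closed-form solve of X'X beta = X'y
  X <- data.frame(a = c(1, 2, 3, 4, 5),
                  b = c(0.3, -1.2, 0.5, 2.0, -0.7),
                  c = c(2, 2, 3, 1, 4))
  y <- c(1.0, 0.4, 2.2, 3.1, 1.7)
  D <- cbind(1, as.matrix(X))
  beta_ols <- solve(t(D) %*% D, t(D) %*% y)
  oracle <- drop(D %*% beta_ols)

  fit <- fit_learner(learner_spec("ridge", lambda = 0), X, y)
  expect_lt(max(abs(predict(fit, X) - oracle)), 1e-6)
})

test_that("ridge coefficient norms shrink monotonically in lambda", {
  td <- toy_data(n = 400, seed = 6)
  norms <- sapply(c(0.01, 0.1, 1, 10, 100), function(l) {
    fit <- fit_learner(learner_spec("ridge", lambda = l), td$x, td$y)
    cf <- glmnet::coef.glmnet(fit$glmnet, s = l)
    sqrt(sum(as.numeric(cf)[-1]^2))
  })
  expect_true(all(diff(norms) < 0))
})

test_that("penalized-linear predictions respond to a shifted predictor only through its coefficient", {
  td <- toy_data(n = 300, seed = 7)
  for (method in c("lasso", "ridge")) {
    fit <- fit_learner(learner_spec(method, lambda = 0.5), td$x, td$y)
    cf <- as.numeric(glmnet::coef.glmnet(fit$glmnet, s = 0.5))
    p0 <- predict(fit, td$x)
    shifted <- td$x
    shifted$age <- shifted$age + 2
    p1 <- predict(fit, shifted)
    j <- which(names(td$x) == "age") + 1  # +1 for the intercept row
    expect_equal(p1 - p0, rep(2 * cf[j], nrow(td$x)), tolerance = 1e-8)
  }
})

test_that("stochastic learners are deterministic given the seed", {
  td <- toy_data(n = 300, seed = 8)
  specs <- list(
    learner_spec("random_forest", mtry = 2, min_node_size = 10,
                 n_trees = 100),
    learner_spec("boosted_trees", interaction_depth = 3,
                 learning_rate = 0.1, n_trees = 50),
    learner_spec("nnet1", hidden_units = 3, weight_decay = 0.05)
  )
  for (spec in specs) {
    p1 <- predict(fit_learner(spec, td$x, td$y, seed = 21), td$x)
    p2 <- predict(fit_learner(spec, td$x, td$y, seed = 21), td$x)
    expect_identical(p1, p2)
  }
  # and the forest genuinely uses its random stream
  f1 <- predict(fit_learner(specs[[1]], td$x, td$y, seed = 1), td$x)
  f2 <- predict(fit_learner(specs[[1]], td$x, td$y, seed = 2), td$x)
  expect_false(identical(f1, f2))
})

test_that("forest predictions are a rowwise map (row-order invariant)", {
  td <- toy_data(n = 200, seed = 9)
  fit <- fit_learner(learner_spec("random_forest", mtry = 2,
                                  min_node_size = 10, n_trees = 100),
                     td$x, td$y, seed = 3)
  idx <- rev(seq_len(nrow(td$x)))
  shuffled <- td$x[idx, , drop = FALSE]
  expect_equal(predict(fit, shuffled), predict(fit, td$x)[idx],
               tolerance = 1e-12)
})

test_that("every learner beats the intercept-only baseline on a strong signal", {
  for (s in 1:3) {
    td <- toy_data(n = 2000, signal_fraction = 0.5, seed = 100 + s)
    xv <- simulate_covariates(td$config, "validation", 2000,
                              seed = 200 + s)
    yv <- generate_outcome(td$model, xv, seed = 300 + s)
    base_mse <- mse(yv, rep(mean(td$y), length(yv)))
    specs <- list(
      learner_spec("ols_rcs", knots = 3),
      learner_spec("lasso", lambda = 0.1),
      learner_spec("ridge", lambda = 0.5),
      learner_spec("boosted_trees", interaction_depth = 3,
                   learning_rate = 0.065),
      learner_spec("random_forest", mtry = 2, min_node_size = 20),
      learner_spec("nnet1", hidden_units = 4, weight_decay = 0.05)
    )
    for (spec in specs) {
      fit <- fit_learner(spec, td$x, td$y, seed = s)
      expect_lt(mse(yv, predict(fit, xv)), base_mse)
    }
  }
})

test_that("prediction enforces the training schema", {
  td <- toy_data(n = 100, seed = 10)
  fit <- fit_learner(learner_spec("ols_rcs", knots = 3), td$x, td$y)
  expect_error(predict(fit, td$x[, -2]), "schema")
  renamed <- td$x
  names(renamed)[1] <- "other"
  expect_error(predict(fit, renamed), "schema")
})

test_that("fitted learners round-trip through serialization", {
  td <- toy_data(n = 200, seed = 11)
  specs <- list(
    learner_spec("ols_rcs", knots = 3),
    learner_spec("ridge", lambda = 0.3),
    learner_spec("boosted_trees", interaction_depth = 2,
                 learning_rate = 0.1, n_trees = 25),
    learner_spec("random_forest", mtry = 2, min_node_size = 10, n_trees = 50),
    learner_spec("nnet1", hidden_units = 2, weight_decay = 0.1)
  )
  for (spec in specs) {
    fit <- fit_learner(spec, td$x, td$y, seed = 4)
    path <- tempfile(fileext = ".sbpl")
    write_learner(fit, path)
    back <- read_learner(path)
    expect_identical(back$spec, fit$spec)
    expect_equal(predict(back, td$x), predict(fit, td$x), tolerance = 1e-12)
  }
})
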