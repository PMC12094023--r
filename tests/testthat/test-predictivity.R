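test_that("evaluate_r2 is the squared Pearson correlation with its conventions", {
  obs <- c(1, 2, 3, 4)
  pred <- c(1.1, 1.9, 3.2, 3.8)
  # independent route: R^2 of the linear regression of observed on predicted
  expect_equal(evaluate_r2(obs, pred),
               summary(lm(obs ~ pred))$r.squared, tolerance = 1e-12)
  expect_equal(evaluate_r2(obs, obs), 1.0)
  expect_equal(evaluate_r2(obs, rep(2, 4)), 0.0)
  expect_error(evaluate_r2(rep(1, 4), pred), "constant observed")
  expect_error(evaluate_r2(obs, pred[1:3]), "length mismatch")

  # invariance to positive affine transforms of the predictions
  expect_equal(evaluate_r2(obs, 3 * pred + 10), evaluate_r2(obs, pred))
})

test_that("loo_predictions enforces its preconditions", {
  x <- matrix(rnorm(6), 2, 3)
  expect_error(loo_predictions(x, c(1, 2)), "at least 3")
  x2 <- matrix(rnorm(30), 10, 3)
  expect_warning(loo_predictions(x2, rep(1, 10), fast_config(20)), "constant outcome")
  expect_error(loo_predictions(x2, c(NA, rnorm(9))), "missing values")
})

test_that("an outcome copying one feature is predicted accurately", {
  set.seed(5)
  n <- 50
  x <- matrix(runif(n * 10), n, 10)
  y <- x[, 4]
  # all features tried per split: with p = 10 the forest should isolate the
  # copied feature almost perfectly
  preds <- loo_predictions(x, y, model_config(mtry_fraction = 1), seed = 2)
  expect_gte(evaluate_r2(y, preds), 0.9)
})

test_that("prediction i does not depend on outcome i (no leakage)", {
  set.seed(8)
  n <- 30
  x <- matrix(runif(n * 8), n, 8)
  y <- x[, 1] + rnorm(n, 0, 0.1)
  p1 <- loo_predictions(x, y, fast_config(50), seed = 3)
  y2 <- y
  y2[7] <- 99
  p2 <- loo_predictions(x, y2, fast_config(50), seed = 3)
  expect_identical(p1[7], p2[7])
})

test_that("a pure-noise outcome yields near-zero LOO R^2", {
  for (s in 1:5) {
    sim <- simulate_survival_data(n_samples = 60, n_features = 40, n_signal = 0,
                                  noise_sd = 0.1, seed = s)
    y <- sim$table$metadata$survival_rate
    preds <- loo_predictions(sim$table, y, fast_config(100), seed = s)
    expect_lt(evaluate_r2(y, preds), 0.15)
  }
})

test_that("seeded evaluations are bit-identical on repeat", {
  sim <- simulate_survival_data(n_samples = 30, n_features = 20, seed = 4)
  y <- sim$table$metadata$survival_rate
  cfg <- fast_config(50)
  expect_identical(loo_predictions(sim$table, y, cfg, seed = 6),
                   loo_predictions(sim$table, y, cfg, seed = 6))
  pn1 <- permutation_null(sim$table, y, n_perm = 5, cfg, seed = 6)
  pn2 <- permutation_null(sim$table, y, n_perm = 5, cfg, seed = 6)
  expect_identical(pn1$null, pn2$null)
  lc1 <- learning_curve(sim$table, y, sizes = c(10, 20), reps = 2, cfg, seed = 6)
  lc2 <- learning_curve(sim$table, y, sizes = c(10, 20), reps = 2, cfg, seed = 6)
  expect_identical(lc1$r2, lc2$r2)
  expect_identical(lc1$slope_per_10, lc2$slope_per_10)
})

test_that("a strong planted signal beats every outcome permutation", {
  sim <- simulate_survival_data(n_samples = 60, n_features = 40, noise_sd = 0.02,
                                seed = 12)
  y <- sim$table$metadata$survival_rate
  pn <- permutation_null(sim$table, y, n_perm = 19, fast_config(100), seed = 1)
  expect_equal(pn$p_value, 1 / 20)
  expect_true(all(pn$null < pn$observed_r2))
  expect_error(permutation_null(sim$table, y, n_perm = 0), "at least 1")
})

test_that("learning_curve validates sizes and summarises a slope", {
  sim <- simulate_survival_data(n_samples = 50, n_features = 30, seed = 3)
  y <- sim$table$metadata$survival_rate
  expect_error(
    learning_curve(sim$table, y, sizes = c(40, 200), reps = 2),
    "200"
  )
  lc <- learning_curve(sim$table, y, sizes = c(15, 25, 35), reps = 3,
                       fast_config(80), seed = 2)
  expect_equal(dim(lc$r2), c(3, 3))
  expect_equal(lc$summary$mean_r2, unname(colMeans(lc$r2)))
  fit <- lm(mean_r2 ~ size, data = lc$summary)
  expect_equal(lc$slope_per_10, unname(coef(fit)[2]) * 10, tolerance = 1e-12)
})

test_that("feature importances are normalised and find the signal features", {
  # outcome driven by two designated features only
  set.seed(6)
  n <- 80
  x <- matrix(runif(n * 60), n, 60, dimnames = list(NULL, sprintf("f%02d", 1:60)))
  y <- x[, 3] / (x[, 3] + 0.3) + x[, 7] / (x[, 7] + 0.3) + rnorm(n, 0, 0.02)
  imp <- rank_features(x, y, model_config(n_trees = 300), seed = 2)
  expect_equal(sum(imp$importance), 1, tolerance = 1e-9)
  expect_true(all(diff(imp$importance) <= 0))
  expect_true(all(c("f03", "f07") %in% imp$feature[1:5]))
})

test_that("a constant feature carries zero importance", {
  set.seed(2)
  x <- cbind(matrix(runif(40 * 5), 40, 5), const = 1)
  colnames(x) <- c(paste0("v", 1:5), "const")
  y <- x[, 1] + rnorm(40, 0, 0.05)
  imp <- rank_features(x, y, fast_config(200), seed = 3)
  expect_equal(imp$importance[imp$feature == "const"], 0, tolerance = 1e-9)
})

test_that("alternative engines run behind the same evaluation contract", {
  sim <- simulate_survival_data(n_samples = 30, n_features = 15, noise_sd = 0.02,
                                seed = 7)
  y <- sim$table$metadata$survival_rate
  for (eng in c("glmnet", "xgboost")) {
    cfg <- model_config(eng, n_trees = 50)
    preds <- loo_predictions(sim$table, y, cfg, seed = 4)
    expect_length(preds, 30)
    expect_true(all(is.finite(preds)))
    expect_identical(preds, loo_predictions(sim$table, y, cfg, seed = 4))
  }
})

test_that("tree ensembles beat the lasso on the nonlinear planted signal", {
  sim <- simulate_survival_data(n_samples = 70, n_features = 40, noise_sd = 0.03,
                                seed = 30)
  y <- sim$table$metadata$survival_rate
  r2_rf <- evaluate_r2(y, loo_predictions(sim$table, y, fast_config(150), seed = 1))
  r2_lasso <- evaluate_r2(y, loo_predictions(sim$table, y,
                                             model_config("glmnet"), seed = 1))
  expect_gt(r2_rf, r2_lasso)
})
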