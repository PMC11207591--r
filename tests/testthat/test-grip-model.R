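# Grip-force model layer: splitting, the tuning fitness, metrics, training
# and persistence.

test_that("the 70/30 split partitions rows deterministically", {
  feats <- tibble::tibble(f = rnorm(200), percent_mvc = rep(c(40, 80), 100))
  sp <- split_dataset(feats, 0.7, seed = 1)
  expect_identical(nrow(sp$train), 140L)
  expect_identical(nrow(sp$test), 60L)
  sp2 <- split_dataset(feats, 0.7, seed = 1)
  expect_identical(sp$train, sp2$train)
  # disjoint union of all rows
  feats$row <- seq_len(200)
  sp3 <- split_dataset(feats, 0.7, seed = 5)
  expect_setequal(c(sp3$train$row, sp3$test$row), 1:200)
  expect_length(intersect(sp3$train$row, sp3$test$row), 0L)
  expect_error(split_dataset(feats[1:5, ], 0.7), "at least 10")
  expect_error(split_dataset(feats, 1.2), "in \\(0, 1\\)")
})

test_that("a grouped split keeps whole groups on one side", {
  feats <- tibble::tibble(f = rnorm(100), percent_mvc = rnorm(100),
                          session = rep(1:10, each = 10))
  sp <- split_dataset(feats, 0.7, seed = 2, stratify_by = "session")
  expect_length(intersect(unique(sp$train$session),
                          unique(sp$test$session)), 0L)
  expect_identical(nrow(sp$train) + nrow(sp$test), 100L)
})

test_that("metrics match the direct-formula oracle to 1e-12", {
  withr::with_seed(12, {
    for (rep in 1:20) {
      f <- runif(50, 0, 100)
      p <- f + rnorm(50, sd = 5)
      got <- regression_metrics(f, p)
      want <- metrics_oracle(f, p)
      expect_equal(got$mae, want$mae, tolerance = 1e-12)
      expect_equal(got$mse, want$mse, tolerance = 1e-12)
      expect_equal(got$r2, want$r2, tolerance = 1e-12)
    }
  })
})

test_that("metrics honor the closed-form special cases", {
  f <- c(40, 60, 80, 100)
  perfect <- regression_metrics(f, f)
  expect_identical(perfect$mae, 0)
  expect_identical(perfect$mse, 0)
  expect_identical(perfect$r2, 1)
  off <- regression_metrics(f, f + 3)
  expect_equal(off$mae, 3)
  expect_equal(off$mse, 9)
  at_mean <- regression_metrics(f, rep(mean(f), 4))
  expect_equal(at_mean$r2, 0)
  expect_error(regression_metrics(c(5, 5, 5), c(4, 5, 6)), "undefined")
  expect_error(regression_metrics(1:3, 1:4), "same length")
  # tidy-eval wrapper reads columns
  d <- tibble::tibble(truth = f, est = f + 1)
  expect_equal(grip_metrics(d, truth, est)$mae, 1)
})

test_that("rf_fitness is deterministic, non-negative, near zero when noiseless", {
  withr::with_seed(30, {
    x <- runif(120)
    d <- tibble::tibble(x1 = x, x2 = rnorm(120), percent_mvc = 10 * x)
  })
  sp <- split_dataset(d, 0.7, seed = 3)
  f1 <- rf_fitness(200, 1, sp$train, sp$test, seed = 4)
  f2 <- rf_fitness(200, 1, sp$train, sp$test, seed = 4)
  expect_identical(f1$fitness, f2$fitness)
  expect_gte(f1$fitness, 0)
  expect_identical(f1$fitness, f1$mse_train + f1$mse_test)
  # labels perfectly determined by one feature, deep trees: fitness ~ 0
  # relative to a unit-variance label scale
  scale2 <- stats::var(d$percent_mvc)
  expect_lt(f1$fitness / scale2, 1e-2 * 10)
  # fractional parameters are rounded at evaluation
  f3 <- rf_fitness(200.4, 1.2, sp$train, sp$test, seed = 4)
  expect_identical(f3$n_estimators, 200L)
  expect_identical(f3$min_samples_leaf, 1L)
  expect_identical(f3$fitness, f1$fitness)
})

test_that("the cross-validated fitness variant stays on the training set", {
  withr::with_seed(31, d <- tibble::tibble(x1 = runif(60),
                                           percent_mvc = runif(60, 0, 100)))
  sp <- split_dataset(d, 0.7, seed = 1)
  f <- rf_fitness(50, 2, sp$train, sp$test, seed = 1, cv_folds = 3)
  expect_true(is.na(f$mse_test))
  expect_gte(f$fitness, 0)
})

test_that("BES tuning returns in-space parameters with a monotone history", {
  feats <- quick_feature_dataset(seed = 101)
  sp <- split_dataset(feats, 0.7, seed = 1)
  tuned <- tune_grip_rf(sp$train, sp$test,
                        n_estimators_range = c(10, 100),
                        min_samples_leaf_range = c(1, 10),
                        pop_size = 4L, max_iter = 4L, seed = 1)
  expect_gte(tuned$best$n_estimators, 10L)
  expect_lte(tuned$best$n_estimators, 100L)
  expect_gte(tuned$best$min_samples_leaf, 1L)
  expect_lte(tuned$best$min_samples_leaf, 10L)
  expect_true(all(diff(tuned$bes$history$best_fitness) <= 0))
  expect_identical(tuned$best$fitness, tuned$bes$best_fitness)
  # evaluations are distinct integer pairs sorted by fitness
  expect_false(any(duplicated(
    tuned$evaluations[c("n_estimators", "min_samples_leaf")])))
  expect_true(all(diff(tuned$evaluations$fitness) >= 0))
})

test_that("a trained model predicts finitely, persists, and reloads identically", {
  feats <- quick_feature_dataset(seed = 202)
  sp <- split_dataset(feats, 0.7, seed = 2)
  model <- train_grip_rf(sp$train, n_estimators = 150, min_samples_leaf = 2,
                         seed = 7)
  preds <- predict(model, sp$test)
  expect_true(all(is.finite(preds$.pred)))
  expect_identical(nrow(preds), nrow(sp$test))
  path <- withr::local_tempfile(fileext = ".rds")
  write_grip_rf(model, path)
  reloaded <- read_grip_rf(path)
  expect_identical(predict(reloaded, sp$test)$.pred, preds$.pred)
  # broom-style accessors
  td <- tidy(model)
  expect_true(all(c("feature", "importance") %in% names(td)))
  expect_identical(glance(model)$n_estimators, 150L)
})

test_that("noiseless monotone synthetic data is recovered with high R^2", {
  withr::with_seed(40, {
    lvl <- sample(c(40, 60, 80, 100), 200, replace = TRUE)
    d <- tibble::tibble(x1 = (lvl / 100)^1.5 + rnorm(200, sd = 1e-3),
                        x2 = rnorm(200), percent_mvc = lvl)
  })
  sp <- split_dataset(d, 0.7, seed = 4)
  model <- train_grip_rf(sp$train, 300, 1, seed = 4)
  rep <- grip_metrics(predict(model, sp$test), percent_mvc, .pred)
  expect_gte(rep$r2, 0.95)
})
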