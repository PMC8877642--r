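test_that("a single-leaf model attributes nothing and exposes its constant", {
  df <- toy_regression(n = 80, p = 3, seed = 2)
  # a minimum-leaf-size above n forbids any split: one leaf per round
  fit <- fit_surrogate("lgbm", list(n_estimators = 3, learning_rate = 0.5,
                                    max_depth = 3, min_child_samples = 1e6),
                       df)
  rep <- compute_shap(fit, df[1:10, ])
  expect_true(all(abs(rep$attributions) < 1e-12))
  expect_equal(rep$base_value, mean(df$final_score), tolerance = 1e-6)
  expect_equal(rep$prediction, rep(rep$base_value, 10))
  # all-zero attributions rank alphabetically by the tie rule
  expect_identical(feature_importance(rep)$feature, sort(fit$features))
})

test_that("a stump attributes only to its split feature, by the closed form", {
  df <- toy_regression(n = 200, p = 4, seed = 6,
                       fun = function(X) 3 * (X[, 2] > 2))
  fit <- fit_surrogate("xgb", list(learning_rate = 1, n_estimators = 1,
                                   min_child_weight = 1, max_depth = 1), df)
  rep <- compute_shap(fit, df[1:20, ])
  expect_true(all(abs(rep$attributions[, c("x1", "x3", "x4")]) < 1e-12))
  # for a stump the split feature takes the full gap to the expectation
  expect_equal(rep$attributions[, "x2"], rep$prediction - rep$base_value,
               tolerance = 1e-9)
  expect_identical(feature_importance(rep)$feature[1], "x2")
})

test_that("attributions equal brute-force Shapley enumeration (p <= 4)", {
  df <- toy_regression(n = 120, p = 4, seed = 8,
                       fun = function(X) X[, 1] * X[, 2] + X[, 3])
  fit <- fit_surrogate("lgbm", list(n_estimators = 5, learning_rate = 0.4,
                                    max_depth = 3, min_child_samples = 5), df)
  rep <- compute_shap(fit, df[1:6, ])
  for (i in 1:6) {
    oracle <- brute_shap(fit, unlist(df[i, fit$features]))
    expect_equal(unname(rep$attributions[i, ]), oracle$phi, tolerance = 1e-9)
    expect_equal(rep$base_value, oracle$base, tolerance = 1e-9)
  }
})

test_that("duplicated feature columns share attribution consistently", {
  set.seed(12)
  x1 <- sample(0:5, 150, replace = TRUE)
  df <- data.frame(x1 = x1, x2 = x1, final_score = 2 * x1)
  fit <- fit_surrogate("gbm", list(n_estimators = 4, learning_rate = 0.5), df)
  rep <- compute_shap(fit, df[1:8, ])
  for (i in 1:8) {
    oracle <- brute_shap(fit, unlist(df[i, fit$features]))
    expect_equal(unname(rep$attributions[i, ]), oracle$phi, tolerance = 1e-9)
  }
  # the duplicates carry the whole effect between them
  expect_equal(rowSums(rep$attributions), rep$prediction - rep$base_value,
               tolerance = 1e-9)
})

test_that("local accuracy holds in double precision, matching the booster", {
  df <- toy_regression(n = 300, p = 3, seed = 14,
                       fun = function(X) X[, 1] - X[, 2] * X[, 3])
  fit <- fit_surrogate("lgbm", list(n_estimators = 60, learning_rate = 0.1,
                                    max_depth = 7, min_child_samples = 5), df)
  rep <- compute_shap(fit, df)
  expect_lt(max(abs(rep$base_value + rowSums(rep$attributions) -
                      rep$prediction)), 1e-9)
  # double-precision re-evaluation agrees with the float32 booster
  expect_lt(max(abs(rep$prediction - predict(fit, df))), 1e-4)
  # and with xgboost's own float32 TreeSHAP
  ref <- predict(fit$model, as.matrix(df[fit$features]), predcontrib = TRUE)
  expect_lt(max(abs(rep$attributions - ref[, fit$features])), 1e-4)
})

test_that("direction trends recover monotone effects and skip constants", {
  set.seed(20)
  n <- 250
  df <- data.frame(up = sample(0:5, n, TRUE), down = sample(0:5, n, TRUE),
                   flat = rep(2, n))
  df$final_score <- df$up - 2 * df$down
  fit <- fit_surrogate("lgbm", list(n_estimators = 40, learning_rate = 0.2,
                                    max_depth = 3, min_child_samples = 5), df)
  rep <- compute_shap(fit, df[1:100, ])
  dirs <- direction_summary(rep)
  expect_identical(dirs$trend[dirs$feature == "up"], "positive")
  expect_identical(dirs$trend[dirs$feature == "down"], "negative")
  expect_true(is.na(dirs$trend[dirs$feature == "flat"]))
})

test_that("only boosted surrogates can be explained", {
  df <- toy_regression(n = 100, p = 3, seed = 1)
  dt <- fit_surrogate("dt", list(min_samples_split = 2, min_samples_leaf = 2,
                                 max_depth = 5), df)
  expect_error(compute_shap(dt, df), "boosted")
  rf <- fit_surrogate("rf", list(n_estimators = 10, max_depth = 5,
                                 min_samples_leaf = 2), df)
  expect_error(compute_shap(rf, df), "boosted")
  gb <- fit_surrogate("gbm", list(n_estimators = 5, learning_rate = 0.3), df)
  expect_error(compute_shap(gb, df[0, ]), "no instances")
})
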