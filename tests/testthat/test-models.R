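test_that("the shuffle split is disjoint, exhaustive and reproducible", {
  ds <- data.frame(x = seq_len(2304), final_score = rnorm(2304))
  sp <- split_dataset(ds, 0.2, seed = 42)
  expect_equal(nrow(sp$train), 1843L)
  expect_equal(nrow(sp$test), 461L)
  expect_length(intersect(sp$train$x, sp$test$x), 0L)
  expect_setequal(c(sp$train$x, sp$test$x), ds$x)
  sp2 <- split_dataset(ds, 0.2, seed = 42)
  expect_identical(sp$train$x, sp2$train$x)

  four <- split_dataset(data.frame(x = 1:4, final_score = 1:4), 0.5, seed = 1)
  expect_equal(nrow(four$train), 2L)
  expect_equal(nrow(four$test), 2L)
  expect_error(split_dataset(ds, 0), "test_fraction")
  expect_error(split_dataset(ds[0, ], 0.2), "empty")
})

test_that("rmse and R^2 match hand computations and brute force", {
  expect_equal(rmse(c(1, 2), c(1, 2)), 0)
  expect_equal(rmse(c(1, 2), c(3, 4)), 2)
  expect_equal(rmse(0, 3), 3)
  expect_error(rmse(1:3, 1:2), "length")

  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(r_squared(rep(2, 3), c(1, 2, 3)), 0)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 4)), 1 - 1 / (14 / 3))
  expect_error(r_squared(c(1, 2), c(5, 5)), "variance")

  set.seed(77)
  for (i in 1:25) {
    n <- sample(2:50, 1)
    p <- rnorm(n); a <- rnorm(n)
    brute_mse <- sum((p - a)^2) / n
    expect_equal(rmse(p, a), sqrt(brute_mse), tolerance = 1e-12)
    expect_equal(r_squared(p, a),
                 1 - sum((p - a)^2) / sum((a - mean(a))^2),
                 tolerance = 1e-12)
  }
})

test_that("grid search picks the single or dominant configuration", {
  # y is a depth-2 checkerboard in x1: a depth-1 tree cannot represent it
  df <- toy_regression(n = 240, p = 2, seed = 9,
                       fun = function(X) as.numeric(X[, 1] %% 2 == 0))
  single <- tune_model("dt", df, folds = 3, seed = 1,
                       grid = data.frame(min_samples_split = 2,
                                         min_samples_leaf = 1,
                                         max_depth = 4))
  expect_equal(single$best_params$max_depth, 4)

  two <- tune_model("dt", df, folds = 3, seed = 1,
                    grid = data.frame(min_samples_split = 2,
                                      min_samples_leaf = 1,
                                      max_depth = c(1, 5)))
  expect_equal(two$best_params$max_depth, 5)
  expect_lt(min(two$cv_results$cv_rmse), max(two$cv_results$cv_rmse))

  again <- tune_model("dt", df, folds = 3, seed = 1,
                      grid = data.frame(min_samples_split = 2,
                                        min_samples_leaf = 1,
                                        max_depth = c(1, 5)))
  expect_identical(two$best_params, again$best_params)
  expect_identical(two$cv_results$cv_rmse, again$cv_results$cv_rmse)
})

test_that("decision-tree training error is non-increasing in depth", {
  ds <- build_dataset(sizes = c(100, 500), seed = 13)
  prev <- Inf
  for (d in c(4, 8, 10, 11, 12, 15)) {
    fit <- fit_surrogate("dt", list(min_samples_split = 2,
                                    min_samples_leaf = 2, max_depth = d), ds)
    err <- rmse(predict(fit, ds), ds$final_score)
    expect_lte(err, prev + 1e-9)
    prev <- err
  }
})

test_that("truncated boosting predictions equal separately trained models", {
  df <- toy_regression(n = 150, p = 3, seed = 21)
  params10 <- list(n_estimators = 10, learning_rate = 0.1)
  params4 <- list(n_estimators = 4, learning_rate = 0.1)
  long <- fit_surrogate("gbm", params10, df, seed = 3)
  short <- fit_surrogate("gbm", params4, df, seed = 3)
  X <- as.matrix(df[long$features])
  expect_identical(
    as.numeric(predict(long$model, X, iterationrange = c(1, 4))),
    as.numeric(predict(short$model, X)))
})

test_that("boosting CV over round counts matches naive per-config refits", {
  df <- toy_regression(n = 90, p = 3, seed = 33)
  grid <- expand.grid(n_estimators = c(3L, 8L), learning_rate = 0.3)
  folds <- 3L
  fold_id <- with_seed_test(5, sample(rep_len(seq_len(folds), nrow(df))))
  fast <- deidverify:::cv_boosting("gbm", grid, df, fold_id, folds, seed = 5)
  naive <- vapply(seq_len(nrow(grid)), function(i) {
    mean(vapply(seq_len(folds), function(f) {
      fit <- fit_surrogate("gbm", as.list(grid[i, ]),
                           df[fold_id != f, ], seed = 5)
      rmse(predict(fit, df[fold_id == f, ]), df$final_score[fold_id == f])
    }, numeric(1)))
  }, numeric(1))
  expect_equal(fast, naive, tolerance = 1e-12)
})

test_that("every method's grid matches its documented shape", {
  expect_equal(nrow(tuning_grid("dt")), 2 * 2 * 6)
  expect_equal(nrow(tuning_grid("rf")), 7 * 2)
  expect_equal(nrow(tuning_grid("gbm")), 10 * 2)
  expect_equal(nrow(tuning_grid("xgb")), 3 * 6 * 5)
  expect_equal(nrow(tuning_grid("lgbm")), 10 * 2 * 3)
})

test_that("model comparison reports all methods and picks the lowest RMSE", {
  ds <- build_dataset(sizes = c(100, 500), seed = 19)
  grids <- list(
    dt = data.frame(min_samples_split = 2, min_samples_leaf = 2,
                    max_depth = c(8, 12)),
    gbm = expand.grid(n_estimators = c(50L, 150L), learning_rate = 0.1))
  cmp <- compare_models(ds, methods = c("dt", "gbm"), folds = 3, seed = 4,
                        grids = grids)
  expect_equal(nrow(cmp$table), 2L)
  expect_identical(cmp$best, cmp$table$method[which.min(cmp$table$rmse)])
  expect_true(all(cmp$table$rmse >= 0))
  expect_true(all(cmp$table$r2 <= 1))
  f <- tempfile(fileext = ".csv")
  write_comparison(cmp, f)
  expect_identical(utils::read.csv(f)$method, cmp$table$method)
})
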