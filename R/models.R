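#' Train/test split of the regression dataset
#'
#' Reproducible shuffle split: the training set takes
#' `floor(n * (1 - test_fraction))` rows of a seeded permutation, the
#' test set the remainder; together they are disjoint and exhaustive.
#'
#' @param dataset A data.frame from [build_dataset()].
#' @param test_fraction Fraction of rows held out (default 0.2).
#' @param seed Integer seed for the permutation.
#' @return A list with elements `train` and `test`.
#' @export
split_dataset <- function(dataset, test_fraction = 0.2, seed = 42L) {
  n <- nrow(dataset)
  if (is.null(n) || n == 0L) stop("dataset is empty", call. = FALSE)
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction must lie in (0, 1)", call. = FALSE)
  }
  n_train <- floor(n * (1 - test_fraction))
  perm <- with_seed(seed, sample.int(n))
  list(train = dataset[perm[seq_len(n_train)], , drop = FALSE],
       test = dataset[perm[-seq_len(n_train)], , drop = FALSE])
}

#' Root mean square error
#'
#' `sqrt(mean((predicted - actual)^2))`.
#'
#' @param predicted,actual Equal-length numeric vectors.
#' @return Non-negative scalar.
#' @export
rmse <- function(predicted, actual) {
  if (length(predicted) != length(actual)) {
    stop("predicted and actual differ in length", call. = FALSE)
  }
  if (length(actual) == 0L) stop("empty vectors", call. = FALSE)
  sqrt(mean((predicted - actual)^2))
}

#' Coefficient of determination
#'
#' `1 - SSE/SST`, with SST taken around the mean of `actual`.
#'
#' @param predicted,actual Equal-length numeric vectors; `actual` must
#'   have nonzero variance.
#' @return Scalar in `(-Inf, 1]`.
#' @export
r_squared <- function(predicted, actual) {
  if (length(predicted) != length(actual)) {
    stop("predicted and actual differ in length", call. = FALSE)
  }
  sst <- sum((actual - mean(actual))^2)
  if (sst == 0) {
    stop("actual values have zero variance; R^2 undefined", call. = FALSE)
  }
  1 - sum((predicted - actual)^2) / sst
}

#' Hyperparameter grid for a surrogate method
#'
#' Returns the full search grid for one of the five tree-based methods,
#' as a data.frame whose row order is the canonical tie-breaking order of
#' the grid search.
#'
#' @param method One of `"dt"` (decision tree), `"rf"` (random forest),
#'   `"gbm"` (depth-wise gradient boosting), `"xgb"` (extreme gradient
#'   boosting), `"lgbm"` (leaf-wise histogram gradient boosting).
#' @return A data.frame of candidate hyperparameter combinations.
#' @export
tuning_grid <- function(method = c("dt", "rf", "gbm", "xgb", "lgbm")) {
  method <- match.arg(method)
  switch(method,
    dt = expand.grid(min_samples_split = c(2L, 7L),
                     min_samples_leaf = c(2L, 7L),
                     max_depth = c(4L, 8L, 10L, 11L, 12L, 15L)),
    rf = expand.grid(n_estimators = c(10L, 20L, 30L, 100L, 200L, 300L, 400L),
                     max_depth = c(3L, 15L),
                     min_samples_leaf = 10L),
    gbm = expand.grid(n_estimators = c(10L, 20L, 30L, 100L, 200L, 300L,
                                       400L, 500L, 600L, 700L),
                      learning_rate = c(0.02, 0.1)),
    xgb = expand.grid(learning_rate = c(0.01, 0.05, 0.1),
                      n_estimators = c(20L, 100L, 200L, 300L, 400L, 500L),
                      min_child_weight = 5L,
                      max_depth = c(3L, 5L, 6L, 7L, 10L)),
    lgbm = expand.grid(n_estimators = c(20L, 100L, 200L, 400L, 600L, 700L,
                                        800L, 900L, 1000L, 1100L),
                       learning_rate = c(0.01, 0.05),
                       max_depth = c(3L, 7L, 15L),
                       min_child_samples = 5L))
}

surrogate_methods <- function() c("dt", "rf", "gbm", "xgb", "lgbm")

method_label <- function(method) {
  c(dt = "Decision tree",
    rf = "Random forest",
    gbm = "Gradient boosting (depth-wise)",
    xgb = "Extreme gradient boosting",
    lgbm = "Gradient boosting (leaf-wise histogram)")[[method]]
}

feature_columns <- function(data) setdiff(names(data), "final_score")

xgb_params <- function(method, params) {
  base <- list(objective = "reg:squarederror", nthread = 1, verbosity = 0)
  extra <- switch(method,
    # classic stochastic-gradient-boosting configuration: shallow
    # depth-wise trees, exact splits, no L2 shrinkage on leaf weights
    gbm = list(eta = params$learning_rate, max_depth = 3,
               min_child_weight = 1, lambda = 0, alpha = 0,
               tree_method = "exact"),
    xgb = list(eta = params$learning_rate, max_depth = params$max_depth,
               min_child_weight = params$min_child_weight,
               tree_method = "exact"),
    # leaf-wise growth on feature histograms; for squared loss the
    # hessian is 1 per row, so min_child_weight equals the minimum
    # number of samples in a leaf
    lgbm = list(eta = params$learning_rate, max_depth = params$max_depth,
                min_child_weight = params$min_child_samples,
                lambda = 0, alpha = 0, tree_method = "hist",
                grow_policy = "lossguide", max_leaves = 31,
                max_bin = 255))
  c(base, extra)
}

#' Fit one surrogate model at fixed hyperparameters
#'
#' Backends: `"dt"` via [rpart::rpart()] (complexity pruning disabled so
#' the depth/leaf-size parameters govern growth), `"rf"` via
#' [ranger::ranger()], and the three boosting variants via
#' [xgboost::xgb.train()] (depth-wise exact splits for `"gbm"`/`"xgb"`,
#' leaf-wise histogram growth for `"lgbm"`).
#'
#' @param method Method name, see [tuning_grid()].
#' @param params Named list (one row of the method's grid).
#' @param data Training data.frame with a `final_score` column.
#' @param seed Integer seed for the stochastic backends.
#' @return An object of class `deid_surrogate`.
#' @export
fit_surrogate <- function(method, params, data, seed = 42L) {
  method <- match.arg(method, surrogate_methods())
  params <- as.list(params)
  feats <- feature_columns(data)
  fit <- switch(method,
    dt = rpart::rpart(
      final_score ~ ., data = data, method = "anova",
      control = rpart::rpart.control(
        minsplit = params$min_samples_split,
        minbucket = params$min_samples_leaf,
        maxdepth = params$max_depth, cp = 0, xval = 0)),
    rf = ranger::ranger(
      final_score ~ ., data = data,
      num.trees = params$n_estimators, max.depth = params$max_depth,
      min.node.size = params$min_samples_leaf,
      num.threads = 1, seed = seed),
    {
      dtrain <- xgboost::xgb.DMatrix(
        as.matrix(data[, feats, drop = FALSE]),
        label = data$final_score, nthread = 1)
      xgboost::xgb.train(params = c(xgb_params(method, params),
                                    list(seed = seed)),
                         data = dtrain, nrounds = params$n_estimators,
                         verbose = 0)
    })
  structure(list(method = method, params = params,
                 backend = switch(method, dt = "rpart", rf = "ranger",
                                  "xgboost"),
                 features = feats, model = fit),
            class = "deid_surrogate")
}

#' @export
predict.deid_surrogate <- function(object, newdata, ...) {
  switch(object$backend,
    rpart = unname(stats::predict(object$model, newdata)),
    ranger = stats::predict(object$model, data = newdata,
                            num.threads = 1)$predictions,
    xgboost = stats::predict(
      object$model,
      as.matrix(newdata[, object$features, drop = FALSE])))
}

#' @export
print.deid_surrogate <- function(x, ...) {
  cat(method_label(x$method), "surrogate (", x$backend, " backend)\n",
      sep = "")
  cat("  ", paste(names(x$params), unlist(x$params), sep = " = ",
                  collapse = ", "), "\n")
  invisible(x)
}

# Mean CV RMSE per grid row for a boosting method: within each group of
# non-n_estimators parameters, one model is trained per fold at the
# largest round count and candidate counts are evaluated by truncated
# prediction (boosting is sequential and deterministic here, so the
# truncated model is identical to one trained with fewer rounds).
cv_boosting <- function(method, grid, data, fold_id, folds, seed) {
  feats <- feature_columns(data)
  X <- as.matrix(data[, feats, drop = FALSE])
  y <- data$final_score
  other <- setdiff(names(grid), "n_estimators")
  group_key <- do.call(paste, c(grid[other], sep = "|"))
  cv_rmse <- matrix(NA_real_, nrow(grid), folds)
  for (g in unique(group_key)) {
    rows <- which(group_key == g)
    rounds <- grid$n_estimators[rows]
    pars <- xgb_params(method, as.list(grid[rows[1], , drop = FALSE]))
    for (f in seq_len(folds)) {
      hold <- fold_id == f
      dtrain <- xgboost::xgb.DMatrix(X[!hold, , drop = FALSE],
                                     label = y[!hold], nthread = 1)
      fit <- xgboost::xgb.train(params = c(pars, list(seed = seed)),
                                data = dtrain, nrounds = max(rounds),
                                verbose = 0)
      for (j in seq_along(rows)) {
        pred <- stats::predict(fit, X[hold, , drop = FALSE],
                               iterationrange = c(1, rounds[j]))
        cv_rmse[rows[j], f] <- rmse(pred, y[hold])
      }
    }
  }
  rowMeans(cv_rmse)
}

#' Tune a surrogate method by cross-validated grid search
#'
#' Exhaustive search over the method's hyperparameter grid, scored by
#' mean RMSE over `folds`-fold cross-validation on the training set;
#' ties are broken by canonical grid order. The winning configuration is
#' refit on the full training set.
#'
#' @param method Method name, see [tuning_grid()].
#' @param data Training data.frame with a `final_score` column.
#' @param folds Number of CV folds (default 5).
#' @param seed Integer seed governing fold assignment and model fits.
#' @param grid Search grid; defaults to [tuning_grid()] for the method.
#' @return An object of class `deid_tuned`: list with the refit `model`
#'   (a `deid_surrogate`), `best_params`, and `cv_results` (the grid
#'   with its mean CV RMSE).
#' @export
tune_model <- function(method, data, folds = 5L, seed = 42L,
                       grid = tuning_grid(method)) {
  method <- match.arg(method, surrogate_methods())
  if (nrow(grid) == 0L) stop("empty tuning grid", call. = FALSE)
  if (folds < 2L) stop("folds must be >= 2", call. = FALSE)
  n <- nrow(data)
  fold_id <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  if (method %in% c("gbm", "xgb", "lgbm")) {
    mean_rmse <- cv_boosting(method, grid, data, fold_id, folds, seed)
  } else {
    mean_rmse <- vapply(seq_len(nrow(grid)), function(i) {
      params <- as.list(grid[i, , drop = FALSE])
      fold_rmse <- vapply(seq_len(folds), function(f) {
        hold <- fold_id == f
        fit <- fit_surrogate(method, params, data[!hold, , drop = FALSE],
                             seed = seed)
        rmse(predict(fit, data[hold, , drop = FALSE]),
             data$final_score[hold])
      }, numeric(1))
      mean(fold_rmse)
    }, numeric(1))
  }
  best <- which.min(mean_rmse)  # first minimum = canonical grid order
  best_params <- as.list(grid[best, , drop = FALSE])
  structure(
    list(method = method,
         best_params = best_params,
         cv_results = cbind(grid, cv_rmse = mean_rmse),
         model = fit_surrogate(method, best_params, data, seed = seed)),
    class = "deid_tuned")
}

#' @export
print.deid_tuned <- function(x, ...) {
  cat("Tuned ", method_label(x$method), ": ",
      paste(names(x$best_params), unlist(x$best_params), sep = " = ",
            collapse = ", "),
      " (CV RMSE ", sprintf("%.4f", min(x$cv_results$cv_rmse)), ")\n",
      sep = "")
  invisible(x)
}

#' Tune, evaluate and compare the surrogate methods
#'
#' Splits the dataset, tunes each requested method by cross-validated
#' grid search on the training set, and evaluates test-set RMSE and R^2.
#' The best model is the one with the lowest test RMSE.
#'
#' @param dataset A data.frame from [build_dataset()].
#' @param methods Character vector of method names (default all five).
#' @param test_fraction Held-out fraction (default 0.2).
#' @param folds CV folds for tuning (default 5).
#' @param seed Integer seed for split, folds and fits.
#' @param grids Optional named list of grid overrides per method.
#' @return An object of class `deid_comparison`: list with `table` (one
#'   row per method: chosen hyperparameters, test RMSE, test R^2, fit
#'   time in seconds), `models` (named list of `deid_tuned`), `best`
#'   (name of the lowest-RMSE method) and `split`.
#' @export
compare_models <- function(dataset, methods = surrogate_methods(),
                           test_fraction = 0.2, folds = 5L, seed = 42L,
                           grids = list()) {
  methods <- match.arg(methods, surrogate_methods(), several.ok = TRUE)
  split <- split_dataset(dataset, test_fraction, seed)
  models <- list()
  rows <- list()
  for (m in methods) {
    grid <- if (!is.null(grids[[m]])) grids[[m]] else tuning_grid(m)
    elapsed <- system.time(
      tuned <- tune_model(m, split$train, folds = folds, seed = seed,
                          grid = grid))[["elapsed"]]
    pred <- predict(tuned$model, split$test)
    models[[m]] <- tuned
    rows[[m]] <- data.frame(
      method = m,
      hyperparameters = paste(names(tuned$best_params),
                              unlist(tuned$best_params),
                              sep = "=", collapse = ", "),
      rmse = rmse(pred, split$test$final_score),
      r2 = r_squared(pred, split$test$final_score),
      fit_time_s = unname(elapsed),
      stringsAsFactors = FALSE)
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  structure(list(table = table, models = models,
                 best = table$method[which.min(table$rmse)],
                 split = split),
            class = "deid_comparison")
}

#' @export
print.deid_comparison <- function(x, ...) {
  cat("Surrogate model comparison (best by test RMSE: ",
      method_label(x$best), ")\n", sep = "")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Write the model comparison table as CSV
#'
#' @param comparison A `deid_comparison` object.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(comparison, path) {
  utils::write.csv(comparison$table, path, row.names = FALSE)
  invisible(path)
}
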