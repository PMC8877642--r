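# Flatten a fitted xgboost booster into parallel node arrays (absolute
# 0-based child indices, -1 marking leaves) for the C++ TreeSHAP kernel.
xgb_tree_arrays <- function(booster, features) {
  tr <- as.data.frame(xgboost::xgb.model.dt.tree(model = booster))
  tr <- tr[order(tr$Tree, tr$Node), ]
  offset <- c(0L, cumsum(tapply(tr$Node, tr$Tree, length)))
  idx <- stats::setNames(seq_len(nrow(tr)) - 1L, tr$ID)
  is_leaf <- tr$Feature == "Leaf"
  feat <- ifelse(is_leaf, -1L, match(tr$Feature, features) - 1L)
  if (anyNA(feat)) {
    # models trained without column names report features as f0, f1, ...
    fallback <- as.integer(sub("^f", "", tr$Feature[!is_leaf]))
    feat[!is_leaf] <- ifelse(is.na(feat[!is_leaf]), fallback, feat[!is_leaf])
  }
  if (anyNA(feat)) stop("unrecognized feature in tree dump", call. = FALSE)
  list(
    roots = as.integer(offset[seq_len(length(offset) - 1L)]),
    left = as.integer(ifelse(is_leaf, -1L, idx[tr$Yes])),
    right = as.integer(ifelse(is_leaf, -1L, idx[tr$No])),
    feat = as.integer(feat),
    thr = as.numeric(ifelse(is_leaf, 0, tr$Split)),
    val = as.numeric(ifelse(is_leaf, tr$Gain, 0)),
    cover = as.numeric(tr$Cover),
    base_score = as.numeric(
      xgboost::xgb.config(booster)$learner$learner_model_param$base_score)
  )
}

#' Tree-SHAP attributions for a boosted surrogate
#'
#' Computes exact TreeSHAP attributions (the Shapley values of the
#' cover-weighted conditional-expectation value function for trees) in
#' double precision for every instance, together with the model's base
#' value (its expected output) and per-instance predictions. Local
#' accuracy — `base_value + sum(attributions) = prediction` — holds to
#' double-precision rounding on every instance.
#'
#' Only the gradient-boosted surrogates (`gbm`, `xgb`, `lgbm` backends)
#' are supported; decision-tree and random-forest surrogates raise an
#' error.
#'
#' @param model A `deid_surrogate` or `deid_tuned` object with an
#'   xgboost backend.
#' @param instances Data.frame of instances (must contain the model's
#'   feature columns, e.g. the test rows of the regression dataset).
#' @return An object of class `deid_shap`: list with `attributions`
#'   (instances x features matrix), `base_value`, `prediction`,
#'   `data` (the feature values), `mean_abs` (per-feature mean absolute
#'   attribution) and `ranking` (features by descending `mean_abs`,
#'   ties alphabetical).
#' @export
#' @examples
#' \donttest{
#' ds <- build_dataset(sizes = 100, seed = 7)
#' fit <- fit_surrogate("lgbm", list(n_estimators = 200, learning_rate = 0.05,
#'                                   max_depth = 7, min_child_samples = 5), ds)
#' sh <- compute_shap(fit, ds[1:50, ])
#' feature_importance(sh)
#' }
compute_shap <- function(model, instances) {
  if (inherits(model, "deid_tuned")) model <- model$model
  stopifnot(inherits(model, "deid_surrogate"))
  if (!identical(model$backend, "xgboost")) {
    stop("tree SHAP is implemented for the boosted (xgboost-backend) ",
         "surrogates; got a ", model$backend, " model", call. = FALSE)
  }
  if (is.null(nrow(instances)) || nrow(instances) == 0L) {
    stop("no instances to explain", call. = FALSE)
  }
  X <- as.matrix(instances[, model$features, drop = FALSE])
  arr <- xgb_tree_arrays(model$model, model$features)
  phi <- cpp_tree_shap(arr$roots, arr$left, arr$right, arr$feat, arr$thr,
                       arr$val, arr$cover, X)
  colnames(phi) <- model$features
  base <- arr$base_score +
    cpp_tree_expected(arr$roots, arr$left, arr$right, arr$feat, arr$thr,
                      arr$val, arr$cover)
  pred <- arr$base_score +
    cpp_tree_predict(arr$roots, arr$left, arr$right, arr$feat, arr$thr,
                     arr$val, arr$cover, X)
  mean_abs <- colMeans(abs(phi))
  ranking <- names(mean_abs)[order(-mean_abs, names(mean_abs))]
  structure(list(attributions = phi, base_value = base, prediction = pred,
                 data = as.data.frame(X), mean_abs = mean_abs,
                 ranking = ranking),
            class = "deid_shap")
}

#' @export
print.deid_shap <- function(x, ...) {
  cat("Tree-SHAP report:", nrow(x$attributions), "instances,",
      ncol(x$attributions), "features; base value",
      sprintf("%.4f", x$base_value), "\n")
  cat("ranking:", paste(x$ranking, collapse = " > "), "\n")
  invisible(x)
}

#' Feature-importance ranking from a SHAP report
#'
#' Features ordered by mean absolute attribution (descending); ties are
#' broken alphabetically.
#'
#' @param report A `deid_shap` object.
#' @return Data.frame with columns `feature` and `mean_abs_shap`.
#' @export
feature_importance <- function(report) {
  stopifnot(inherits(report, "deid_shap"))
  data.frame(feature = report$ranking,
             mean_abs_shap = unname(report$mean_abs[report$ranking]),
             stringsAsFactors = FALSE)
}

#' Direction-of-effect summary per feature
#'
#' For each feature, the Spearman rank correlation between the feature's
#' values and its attributions over the evaluated instances, and the
#' resulting sign trend: `"positive"` (higher feature value pushes the
#' predicted score up), `"negative"`, or `NA` when the feature or its
#' attributions are constant. This is the tabular counterpart of a SHAP
#' beeswarm summary plot.
#'
#' @param report A `deid_shap` object.
#' @return Data.frame with columns `feature`, `rho` and `trend`, in
#'   ranking order.
#' @export
direction_summary <- function(report) {
  stopifnot(inherits(report, "deid_shap"))
  rows <- lapply(report$ranking, function(f) {
    x <- report$data[[f]]
    phi <- report$attributions[, f]
    if (stats::sd(x) == 0 || stats::sd(phi) == 0) {
      return(data.frame(feature = f, rho = NA_real_,
                        trend = NA_character_, stringsAsFactors = FALSE))
    }
    rho <- stats::cor(x, phi, method = "spearman")
    data.frame(feature = f, rho = rho,
               trend = if (is.na(rho) || rho == 0) NA_character_
                       else if (rho > 0) "positive" else "negative",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write SHAP artifacts as CSV
#'
#' Writes the attribution matrix (one row per instance, one column per
#' feature, plus the base value and prediction) and the importance
#' ranking with direction trends.
#'
#' @param report A `deid_shap` object.
#' @param attributions_path,ranking_path Output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_shap <- function(report, attributions_path, ranking_path) {
  att <- data.frame(report$attributions,
                    base_value = report$base_value,
                    prediction = report$prediction)
  utils::write.csv(att, attributions_path, row.names = FALSE)
  rk <- merge(feature_importance(report), direction_summary(report),
              by = "feature", sort = FALSE)
  rk <- rk[order(-rk$mean_abs_shap, rk$feature), ]
  utils::write.csv(rk, ranking_path, row.names = FALSE)
  invisible(c(attributions_path, ranking_path))
}
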