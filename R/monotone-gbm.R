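## PC-GBM: gradient boosted regression trees with per-feature monotonicity
## enforced during split search (see src/gbm.cpp), gain importances, and a
## grid-sweep violation auditor.

#' PC-GBM hyperparameter configuration
#'
#' Defaults sit inside the published optimal ranges (depth 5-7, learning rate
#' 0.03-0.06, 250-400 estimators, subsample 0.7-0.9, L1 0.1-0.3, L2 0.5-1.0).
#'
#' @param max_depth maximum tree depth.
#' @param learning_rate shrinkage per tree.
#' @param n_estimators number of boosting rounds.
#' @param subsample row-subsampling fraction per round.
#' @param l1,l2 leaf-value regularization strengths.
#' @param min_leaf minimum samples per leaf.
#' @param constraints named integer vector of monotone directions per feature
#'   (`+1`, `-1`, `0`); missing features default to 0.
#' @param seed integer seed for row subsampling.
#' @return object of class `gbm_config`.
#' @export
gbm_config <- function(max_depth = 6, learning_rate = 0.05,
                       n_estimators = 300, subsample = 0.8, l1 = 0.2,
                       l2 = 0.75, min_leaf = 5,
                       constraints = constraint_map(), seed = 1L) {
  stopifnot(max_depth >= 1, learning_rate > 0, n_estimators >= 1,
            subsample > 0, subsample <= 1, l1 >= 0, l2 >= 0, min_leaf >= 1)
  structure(list(max_depth = as.integer(max_depth),
                 learning_rate = learning_rate,
                 n_estimators = as.integer(n_estimators),
                 subsample = subsample, l1 = l1, l2 = l2,
                 min_leaf = as.integer(min_leaf),
                 constraints = constraints, seed = as.integer(seed)),
            class = "gbm_config")
}

#' Fit a monotonicity-constrained gradient boosted tree ensemble
#'
#' Squared-error boosting with exact greedy split search.  For a feature
#' constrained `+1`, any split on it must produce an ordered pair of child
#' values (left <= right), and descendant leaf values are clipped to intervals
#' propagated from the split mid-point, so the fitted function is globally
#' non-decreasing in that feature (mirrored for `-1`).
#'
#' @param X numeric matrix (named columns) or [compound_table()].
#' @param y response vector (taken from the table when omitted).
#' @param config a [gbm_config()].
#' @return object of class `gbm_model`.
#' @export
fit_pcgbm <- function(X, y = NULL, config = gbm_config()) {
  if (inherits(X, "compound_table")) {
    if (is.null(y)) y <- X$y
    X <- X$X
  }
  X <- as.matrix(X)
  if (is.null(y)) stop_tox("no response supplied")
  if (nrow(X) < 10) stop_tox("fit_pcgbm requires n >= 10")
  cons <- integer(ncol(X))
  names(cons) <- colnames(X)
  if (length(config$constraints)) {
    unknown <- setdiff(names(config$constraints), colnames(X))
    if (length(unknown))
      stop_tox("constraint on unknown column(s): %s",
               paste(unknown, collapse = ", "))
    cons[names(config$constraints)] <- as.integer(config$constraints)
  }
  fit <- gbm_fit_cpp(X, as.numeric(y), config$n_estimators,
                     config$learning_rate, config$max_depth, config$subsample,
                     config$l1, config$l2, config$min_leaf, unname(cons),
                     config$seed)
  gain <- as.numeric(fit$gain)
  names(gain) <- colnames(X)
  structure(list(trees = fit$trees, base_score = fit$base_score,
                 gain = gain, constraints = cons, config = config,
                 feature_names = colnames(X),
                 train_pred = as.numeric(fit$train_pred)),
            class = "gbm_model")
}

#' @export
print.gbm_model <- function(x, ...) {
  cat(sprintf("<gbm_model> %d trees, depth <= %d, %d features (%d constrained)\n",
              length(x$trees), x$config$max_depth, length(x$feature_names),
              sum(x$constraints != 0)))
  invisible(x)
}

#' Predict from a fitted PC-GBM
#'
#' @param object a `gbm_model`.
#' @param newdata matrix or [compound_table()] with the training columns.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.gbm_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "compound_table")) newdata$X else
    as.matrix(newdata)
  if (!identical(colnames(X), object$feature_names))
    stop_tox("newdata columns do not match the training layout")
  as.numeric(gbm_predict_cpp(object$trees, object$base_score, X))
}

#' Gain-based feature importance shares
#'
#' Total split gain per feature, normalized to sum to one.
#'
#' @param model a fitted `gbm_model`.
#' @return named numeric vector summing to 1.
#' @export
gbm_importance <- function(model) {
  if (!inherits(model, "gbm_model")) stop_tox("not a fitted gbm_model")
  g <- model$gain
  if (sum(g) == 0) return(g)
  g / sum(g)
}

#' Cross-fold importance averaging
#'
#' Refits the model per fold (training rows only) and averages normalized
#' importance shares, for fold-stability displays.
#'
#' @param X matrix or [compound_table()]; `y` taken from the table if absent.
#' @param y response.
#' @param folds a [kfold_plan()].
#' @param config a [gbm_config()].
#' @return list with `mean` (named vector) and `per_fold` (matrix).
#' @export
gbm_importance_cv <- function(X, y = NULL, folds, config = gbm_config()) {
  if (inherits(X, "compound_table")) { if (is.null(y)) y <- X$y; X <- X$X }
  k <- folds$k
  per <- matrix(NA_real_, k, ncol(X), dimnames = list(NULL, colnames(X)))
  for (f in seq_len(k)) {
    tr <- folds$fold_assignments != f
    m <- fit_pcgbm(X[tr, , drop = FALSE], y[tr], config)
    per[f, ] <- gbm_importance(m)
  }
  list(mean = colMeans(per), per_fold = per)
}

#' Audit monotonicity of a fitted model by grid sweeps
#'
#' For each anchor row the feature is swept over an equally spaced grid
#' spanning its observed range with all other coordinates fixed; adjacent-pair
#' violations of the declared direction beyond `tol` are counted.
#'
#' @param model a fitted `gbm_model` (or any object with a `predict` method
#'   over matrices) carrying `constraints`.
#' @param anchors matrix of anchor rows (training column layout).
#' @param feature name of a constrained feature.
#' @param grid_size number of grid points (>= 1).
#' @param tol numeric tolerance.
#' @return integer violation count.
#' @export
check_monotonic <- function(model, anchors, feature, grid_size = 21,
                            tol = 1e-9) {
  anchors <- if (inherits(anchors, "compound_table")) anchors$X else
    as.matrix(anchors)
  dir <- model$constraints[[feature]]
  if (is.null(dir) || dir == 0)
    stop_tox("feature '%s' is not constrained; use the sensitivity module",
             feature)
  if (grid_size < 2) return(0L)
  grid <- seq(min(anchors[, feature]), max(anchors[, feature]),
              length.out = grid_size)
  violations <- 0L
  for (a in seq_len(nrow(anchors))) {
    sweep_X <- anchors[rep(a, grid_size), , drop = FALSE]
    sweep_X[, feature] <- grid
    pr <- predict(model, sweep_X)
    d <- diff(pr) * dir
    violations <- violations + sum(d < -tol)
  }
  violations
}

#' Serialize a PC-GBM to a JSON-compatible list
#'
#' @param model a fitted `gbm_model`.
#' @return plain list (trees as row-wise node records).
#' @export
gbm_serialize <- function(model) {
  list(base_score = model$base_score,
       feature_names = model$feature_names,
       constraints = as.list(model$constraints),
       trees = lapply(model$trees, function(m) as.data.frame(m)))
}
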