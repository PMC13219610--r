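## Descriptor screening chain: variance filter -> pairwise-correlation filter
## -> supervised top-k ranking, plus leakage-safe z-scoring.  All fitting
## statistics come from training rows only; test rows are only ever
## transformed.

#' Drop near-constant descriptor columns
#'
#' @param table a [compound_table()].
#' @param tau variance threshold; columns with sample variance `<= tau` are
#'   removed.  The default removes only numerically constant columns.
#' @return list with elements `table` (survivors, original order) and
#'   `dropped` (character vector).
#' @export
filter_low_variance <- function(table, tau = 1e-8) {
  stopifnot(inherits(table, "compound_table"), tau >= 0)
  v <- apply(table$X, 2, var)
  drop <- names(v)[v <= tau]
  keep <- setdiff(colnames(table$X), drop)
  if (!length(keep)) stop_tox("variance filter would drop every column")
  out <- compound_table(table$ids, table$X[, keep, drop = FALSE], table$y,
                        table$specs[keep])
  list(table = out, dropped = drop)
}

#' Drop one member of each highly correlated descriptor pair
#'
#' Greedy scan in column order: whenever a surviving pair has absolute
#' Pearson correlation above `r_max`, the later-indexed column is dropped.
#' Deterministic given the column order.
#'
#' @param table a [compound_table()] with at least 3 rows.
#' @param r_max absolute-correlation threshold (default 0.9).
#' @return list with `table` (survivors), `pairs` (data.frame kept/dropped/r)
#'   and `dropped`.
#' @export
filter_correlated <- function(table, r_max = 0.9) {
  stopifnot(inherits(table, "compound_table"))
  if (nrow(table$X) < 3) stop_tox("correlation filter requires n >= 3")
  nms <- colnames(table$X)
  cm <- suppressWarnings(cor(table$X))
  cm[is.na(cm)] <- 0
  alive <- rep(TRUE, length(nms))
  kept <- dropped <- character(0); rvals <- numeric(0)
  for (i in seq_along(nms)) {
    if (!alive[i]) next
    for (j in seq_along(nms)) {
      if (j <= i || !alive[j]) next
      if (abs(cm[i, j]) > r_max) {
        alive[j] <- FALSE
        kept <- c(kept, nms[i]); dropped <- c(dropped, nms[j])
        rvals <- c(rvals, cm[i, j])
      }
    }
  }
  keep <- nms[alive]
  out <- compound_table(table$ids, table$X[, keep, drop = FALSE], table$y,
                        table$specs[keep])
  list(table = out,
       pairs = data.frame(kept = kept, dropped = dropped, r = rvals,
                          stringsAsFactors = FALSE),
       dropped = dropped)
}

#' Supervised top-k descriptor ranking
#'
#' Scores each descriptor by its absolute Pearson correlation with the target
#' inside each cross-validation training fold, averages the per-fold scores,
#' and keeps the top `k` (ties broken by column order).  Per-fold scores are
#' retained for stability displays.
#'
#' @param table a [compound_table()] carrying a target.
#' @param k number of descriptors to keep.
#' @param folds a [kfold_plan()] over the rows of `table`.
#' @return list with `selected` (ordered names), `scores` (named mean scores),
#'   and `fold_scores` (folds x descriptors matrix).
#' @export
rank_select <- function(table, k = 8, folds) {
  stopifnot(inherits(table, "compound_table"))
  if (is.null(table$y)) stop_tox("rank_select requires a target column")
  p <- ncol(table$X)
  if (k > p) stop_tox("k (%d) exceeds descriptor count (%d)", k, p)
  kf <- max(folds$fold_assignments)
  fs <- matrix(NA_real_, kf, p, dimnames = list(NULL, colnames(table$X)))
  for (f in seq_len(kf)) {
    tr <- folds$fold_assignments != f
    fs[f, ] <- abs(suppressWarnings(
      cor(table$X[tr, , drop = FALSE], table$y[tr])))[, 1]
  }
  fs[is.na(fs)] <- 0
  mean_scores <- colMeans(fs)
  ord <- order(-mean_scores, seq_len(p))
  sel <- colnames(table$X)[ord[seq_len(k)]]
  list(selected = sel, scores = mean_scores, fold_scores = fs)
}

#' Fit a z-scoring scaler on training rows
#'
#' @param table training [compound_table()]; every column must have sd > 0.
#' @return object of class `tox_scaler` (per-column center and scale).
#' @export
fit_scaler <- function(table) {
  stopifnot(inherits(table, "compound_table"))
  ctr <- colMeans(table$X)
  scl <- apply(table$X, 2, sd)
  if (any(scl == 0))
    stop_tox("zero-sd column(s) %s: run filter_low_variance() first",
             paste(names(scl)[scl == 0], collapse = ", "))
  structure(list(center = ctr, scale = scl), class = "tox_scaler")
}

#' Apply a fitted scaler
#'
#' @param scaler a [fit_scaler()] result.
#' @param table a [compound_table()] or matrix with matching columns.
#' @return object of the same type, z-scored with the training parameters.
#'   Values outside the training range extrapolate freely (no clipping).
#' @export
apply_scaler <- function(scaler, table) {
  stopifnot(inherits(scaler, "tox_scaler"))
  X <- if (inherits(table, "compound_table")) table$X else as.matrix(table)
  if (!identical(colnames(X), names(scaler$center)))
    stop_tox("scaler/table column mismatch")
  Z <- sweep(sweep(X, 2, scaler$center), 2, scaler$scale, "/")
  if (inherits(table, "compound_table")) {
    out <- table
    out$X <- Z
    ## z-scored columns are continuous regardless of original kind
    out$specs <- lapply(seq_along(out$specs), function(j) {
      sp <- out$specs[[j]]
      descriptor_spec(sp$name, "continuous", min(Z[, j]), max(Z[, j]),
                      median(Z[, j]), mean(Z[, j]), sd(Z[, j]),
                      monotone_direction = sp$monotone_direction)
    })
    names(out$specs) <- colnames(Z)
    out
  } else Z
}

#' Standardize apply-rows using statistics fitted on training rows only
#'
#' @param fit_rows training [compound_table()].
#' @param apply_rows rows to transform (defaults to `fit_rows`).
#' @return list with `table` (transformed `apply_rows`) and `scaler`.
#' @export
standardize <- function(fit_rows, apply_rows = fit_rows) {
  sc <- fit_scaler(fit_rows)
  list(table = apply_scaler(sc, apply_rows), scaler = sc)
}

#' Run the full descriptor screening chain
#'
#' Variance filter, correlation filter and (when a target and fold plan are
#' supplied) supervised top-k selection, returning both the reduced table and
#' a serializable report.
#'
#' @param table a [compound_table()].
#' @param tau variance threshold.
#' @param r_max correlation threshold.
#' @param k number of descriptors to keep in supervised ranking (`NULL` skips
#'   ranking).
#' @param folds fold plan for the ranking step.
#' @return list with `table` and `report` (class `preprocess_report`).
#' @export
preprocess_chain <- function(table, tau = 1e-8, r_max = 0.9, k = NULL,
                             folds = NULL) {
  lv <- filter_low_variance(table, tau)
  fc <- filter_correlated(lv$table, r_max)
  tab <- fc$table
  sel <- NULL
  if (!is.null(k) && !is.null(folds) && !is.null(tab$y)) {
    rs <- rank_select(tab, k = min(k, ncol(tab$X)), folds = folds)
    tab <- compound_table(tab$ids, tab$X[, rs$selected, drop = FALSE], tab$y,
                          tab$specs[rs$selected])
    sel <- rs
  }
  report <- structure(list(
    dropped_low_variance = lv$dropped,
    dropped_correlated = fc$pairs,
    selected = if (is.null(sel)) colnames(tab$X) else sel$selected,
    scores = if (is.null(sel)) NULL else sel$scores,
    fold_scores = if (is.null(sel)) NULL else sel$fold_scores
  ), class = "preprocess_report")
  list(table = tab, report = report)
}
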