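## Robustness diagnostics: Y-scrambling (label-permutation null), distance-
## based applicability-domain assessment, and uncertainty/distance/error
## association analysis.

#' Y-scrambling diagnostic
#'
#' Refits the supplied training routine on permuted labels (identical
#' protocol, fixed hyperparameters) and compares held-out R^2 of the original
#' model against the scrambled distribution.  R^2 is evaluated on a held-out
#' fifth of the rows (the same split for every permutation) because the
#' expected collapse of scrambled performance into the negative region is an
#' out-of-sample phenomenon.
#'
#' @param model_factory function `(X, y) -> model` where the model has a
#'   `predict(model, X)` method (or is itself a function of `X`).
#' @param X descriptor matrix.
#' @param y labels.
#' @param n_perm number of permutations (>= 10).
#' @param seed integer seed.
#' @return list of class `yscramble_report`: `original_r2`, `scrambled_r2`,
#'   `scrambled_mean`, `scrambled_sd`, `scrambled_max`, `z`, `passed`.
#' @export
yscrambling <- function(model_factory, X, y, n_perm = 50, seed = 1L) {
  if (n_perm < 10) stop_tox("n_perm must be >= 10")
  X <- if (inherits(X, "compound_table")) X$X else as.matrix(X)
  n <- nrow(X)
  hold <- with_seed(derive_seed(seed, 1L), sample(n, round(n / 5)))
  tr <- setdiff(seq_len(n), hold)
  r2_of <- function(yy) {
    model <- model_factory(X[tr, , drop = FALSE], yy[tr])
    pred <- if (is.function(model)) model(X[hold, , drop = FALSE]) else
      predict(model, X[hold, , drop = FALSE])
    1 - sum((yy[hold] - pred)^2) / sum((yy[hold] - mean(yy[hold]))^2)
  }
  original <- r2_of(y)
  perms <- yscramble_labels(y, n_perm, derive_seed(seed, 2L))
  scrambled <- vapply(seq_along(perms), function(i) {
    tryCatch(r2_of(perms[[i]]),
             error = function(e)
               stop_tox("model factory failed on permutation %d: %s", i,
                        conditionMessage(e)))
  }, 0)
  m <- mean(scrambled); s <- sd(scrambled)
  structure(list(original_r2 = original, scrambled_r2 = scrambled,
                 scrambled_mean = m, scrambled_sd = s,
                 scrambled_max = max(scrambled),
                 z = (original - m) / s,
                 passed = original > m + 2 * s && original > max(scrambled),
                 n_perm = n_perm, seed = seed),
            class = "yscramble_report")
}

#' Applicability-domain assessment by centroid distance
#'
#' Distances are Euclidean in the standardized descriptor space (scaler fitted
#' on the training rows); the training centroid is the origin of that space.
#' Default threshold rule: mean + 2 SD of the training self-distances;
#' alternatively the 97.5th percentile.
#'
#' @param train training [compound_table()].
#' @param query query [compound_table()] (columns must match).
#' @param scaler optional pre-fitted [fit_scaler()]; fitted on `train` when
#'   omitted.
#' @param threshold_rule `"mean_2sd"` or `"percentile"`.
#' @param widths optional per-query interval widths for the distance/width
#'   correlation.
#' @return list of class `ad_report`: distances, threshold, flags, in-domain
#'   fraction, and (when widths given) Pearson r plus Q4/Q1 width ratio.
#' @export
ad_assess <- function(train, query, scaler = NULL,
                      threshold_rule = c("mean_2sd", "percentile"),
                      widths = NULL) {
  threshold_rule <- match.arg(threshold_rule)
  if (!identical(colnames(train$X), colnames(query$X)))
    stop_tox("train/query descriptor columns differ")
  if (is.null(scaler)) scaler <- fit_scaler(train)
  if (!identical(names(scaler$center), colnames(train$X)))
    stop_tox("scaler does not match the training columns")
  Ztr <- apply_scaler(scaler, train$X)
  Zq <- apply_scaler(scaler, query$X)
  centroid <- colMeans(Ztr)
  dtr <- sqrt(rowSums(sweep(Ztr, 2, centroid)^2))
  dq <- sqrt(rowSums(sweep(Zq, 2, centroid)^2))
  threshold <- switch(threshold_rule,
                      mean_2sd = mean(dtr) + 2 * sd(dtr),
                      percentile = quantile(dtr, 0.975, names = FALSE))
  flags <- dq <= threshold
  r <- ratio <- NA_real_
  if (!is.null(widths)) {
    assoc <- uncertainty_associations(dq, widths,
                                      abs_errors = NULL, min_n = 4L)
    r <- assoc$r_distance_width
    ratio <- assoc$q4_q1_width_ratio
  }
  structure(list(distances = dq, train_distances = dtr,
                 threshold = threshold, threshold_rule = threshold_rule,
                 in_domain = flags, in_domain_fraction = mean(flags),
                 r_distance_width = r, q4_q1_width_ratio = ratio),
            class = "ad_report")
}

#' Uncertainty / domain-distance / error associations
#'
#' Pearson correlation of distance with interval width, the Q4/Q1 mean-width
#' ratio across distance quartiles, and (when errors are supplied) the Q4/Q1
#' mean-error ratio across width quartiles.
#'
#' @param distances per-sample centroid distances.
#' @param widths per-sample interval widths.
#' @param abs_errors optional per-sample absolute errors.
#' @param min_n minimum aligned length (default 20).
#' @return list with `r_distance_width`, `q4_q1_width_ratio`,
#'   `q4_q1_error_ratio`.
#' @export
uncertainty_associations <- function(distances, widths, abs_errors = NULL,
                                     min_n = 20L) {
  n <- length(distances)
  if (length(widths) != n) stop_tox("distances/widths length mismatch")
  if (n < min_n) stop_tox("need N >= %d aligned samples", min_n)
  if (sd(distances) == 0 || sd(widths) == 0)
    stop_tox("zero variance in distances or widths")
  quart_ratio <- function(by, val) {
    qs <- quantile(by, c(0.25, 0.75), names = FALSE)
    mean(val[by >= qs[2]]) / mean(val[by <= qs[1]])
  }
  err_ratio <- NA_real_
  if (!is.null(abs_errors)) {
    if (length(abs_errors) != n) stop_tox("abs_errors length mismatch")
    if (sd(abs_errors) == 0) stop_tox("zero variance in abs_errors")
    err_ratio <- quart_ratio(widths, abs_errors)
  }
  list(r_distance_width = cor(distances, widths),
       q4_q1_width_ratio = quart_ratio(distances, widths),
       q4_q1_error_ratio = err_ratio)
}
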