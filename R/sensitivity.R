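## Intervention-inspired one-at-a-time perturbation analysis: per-descriptor
## directional effects under controlled sweeps with all other descriptors
## fixed, classification into positive/negative/neutral, and the
## monotonic-consistency percentage over descriptors with declared
## directionality.

model_predict <- function(model, X) {
  if (is.function(model)) model(X) else predict(model, X)
}

#' Sweep one descriptor with all others fixed
#'
#' @param model a fitted model with a `predict` method over matrices, or a
#'   plain function `X -> predictions`.
#' @param x a single anchor row (named vector or 1-row matrix).
#' @param feature descriptor to sweep.
#' @param grid_size number of equally spaced grid points (>= 2).
#' @param range `c(lo, hi)` sweep range with `lo < hi`.
#' @return list with `grid` and `pred`.
#' @export
perturb_feature <- function(model, x, feature, grid_size = 21, range) {
  if (is.null(dim(x))) x <- matrix(x, 1, dimnames = list(NULL, names(x)))
  if (!feature %in% colnames(x)) stop_tox("unknown feature '%s'", feature)
  if (grid_size < 2) stop_tox("grid_size must be >= 2")
  if (range[1] >= range[2]) stop_tox("need lo < hi in the sweep range")
  grid <- seq(range[1], range[2], length.out = grid_size)
  sweep_X <- x[rep(1, grid_size), , drop = FALSE]
  sweep_X[, feature] <- grid
  list(grid = grid, pred = model_predict(model, sweep_X))
}

#' One-at-a-time directional sensitivity analysis
#'
#' For `n_anchors` representative compounds (sampled without replacement,
#' seeded) every descriptor is swept over its observed range in the table with
#' all other descriptors fixed.  Per descriptor: the mean net effect
#' (prediction at the high end minus at the low end), the modal-sign
#' consistency across anchors, the relative magnitude (mean |effect|
#' normalized by the maximum across descriptors), and a
#' positive/negative/neutral class (neutral when the mean |effect| is below
#' `neutral_eps` times the SD of predictions over the table).  The monotonic
#' consistency percentage is the share of (anchor x directional-descriptor)
#' sweeps whose net effect matches the declared direction (a zero net effect
#' is consistent with a weak monotone constraint and counts as aligned).
#'
#' @param model predictor (object with `predict` method, or function).
#' @param table a [compound_table()] supplying anchors and observed ranges.
#' @param n_anchors number of anchors (default 200, capped at n).
#' @param grid_size sweep resolution (default 21).
#' @param neutral_eps neutral-class threshold (default 0.05).
#' @param expected_directions named vector of expected signs for the
#'   consistency statistic; defaults to the nonzero monotone directions in
#'   the table's specs.
#' @param seed integer seed.
#' @return list of class `sensitivity_report`.
#' @export
directional_analysis <- function(model, table, n_anchors = 200,
                                 grid_size = 21, neutral_eps = 0.05,
                                 expected_directions = NULL, seed = 1L) {
  stopifnot(inherits(table, "compound_table"))
  n <- nrow(table$X)
  if (n_anchors > n) stop_tox("n_anchors (%d) exceeds n (%d)", n_anchors, n)
  features <- colnames(table$X)
  if (is.null(expected_directions)) {
    dirs <- constraint_map(table$specs)
    expected_directions <- dirs[dirs != 0]
  }
  anchors <- with_seed(seed, sample(n, n_anchors))
  # neutral-band normalizer: the observed response SD when the table carries
  # one (a scale the model cannot deflate by underfitting), else the SD of
  # the model's own predictions
  pred_sd <- if (!is.null(table$y)) sd(table$y) else
    sd(model_predict(model, table$X))

  effects <- matrix(NA_real_, n_anchors, length(features),
                    dimnames = list(NULL, features))
  step_viol <- setNames(numeric(length(features)), features)
  for (f in features) {
    rng <- range(table$X[, f])
    if (rng[1] == rng[2]) { effects[, f] <- 0; next }
    for (a in seq_len(n_anchors)) {
      pf <- perturb_feature(model, table$X[anchors[a], , drop = FALSE], f,
                            grid_size, rng)
      effects[a, f] <- pf$pred[grid_size] - pf$pred[1]
      d <- expected_directions[f]
      if (!is.na(d) && length(d) && !is.null(d))
        step_viol[f] <- step_viol[f] + sum(diff(pf$pred) * d < -1e-9)
    }
  }

  mean_eff <- colMeans(effects)
  abs_eff <- colMeans(abs(effects))
  rel_mag <- if (max(abs_eff) > 0) abs_eff / max(abs_eff) else abs_eff
  sign_consistency <- apply(effects, 2, function(e) {
    s <- sign(e)
    max(tabulate(factor(s, levels = c(-1, 0, 1)))) / length(e)
  })
  class <- ifelse(abs_eff < neutral_eps * pred_sd, "neutral",
                  ifelse(mean_eff > 0, "positive", "negative"))

  exp_f <- intersect(names(expected_directions), features)
  aligned <- total <- 0L
  for (f in exp_f) {
    d <- expected_directions[[f]]
    aligned <- aligned + sum(effects[, f] * d >= 0)
    total <- total + n_anchors
  }
  consistency_pct <- if (total > 0) 100 * aligned / total else NA_real_

  per <- data.frame(feature = features, mean_effect = mean_eff,
                    sign_consistency = sign_consistency,
                    relative_magnitude = rel_mag, class = class,
                    step_violations = step_viol[features],
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(
    per_descriptor = per,
    summary = list(
      total_features = length(features),
      positive = sum(class == "positive"),
      negative = sum(class == "negative"),
      neutral = sum(class == "neutral"),
      most_positive = features[which.max(mean_eff)],
      most_negative = features[which.min(mean_eff)],
      highest_abs_effect = features[which.max(abs_eff)],
      monotonic_consistency_pct = consistency_pct,
      samples_used = n_anchors),
    n_anchors = n_anchors, grid_size = grid_size,
    neutral_eps = neutral_eps, seed = seed),
    class = "sensitivity_report")
}
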