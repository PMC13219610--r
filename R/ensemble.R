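## CV-performance-weighted aggregation of member predictive distributions.
## Members are treated as a Gaussian mixture: the ensemble mean is the
## weighted member mean and the ensemble variance the full mixture variance,
## so member disagreement widens the intervals.

#' Inverse-RMSE ensemble weights
#'
#' `w_m` proportional to `1 / RMSE_m` (default) or `softmax(-RMSE)`;
#' normalized to sum to one.  Invariant to rescaling all RMSEs by a common
#' factor under the inverse rule.
#'
#' @param cv_rmse named positive numeric vector of per-member CV RMSEs.
#' @param scheme `"inverse"` or `"softmax"`.
#' @return named weights summing to 1.
#' @export
ensemble_weights <- function(cv_rmse, scheme = c("inverse", "softmax")) {
  scheme <- match.arg(scheme)
  if (any(cv_rmse <= 0)) stop_tox("all member RMSEs must be > 0")
  w <- switch(scheme, inverse = 1 / cv_rmse,
              softmax = exp(-cv_rmse - max(-cv_rmse)))
  w / sum(w)
}

#' Mixture-aggregate member predictions
#'
#' Given aligned member [prediction_set()]s carrying means and predictive SDs,
#' computes the mixture mean `mu = sum(w_m mu_m)` and mixture variance
#' `sigma^2 = sum(w_m (sigma_m^2 + mu_m^2)) - mu^2` (law of total variance),
#' then Gaussian central intervals at `level`.
#'
#' @param members list of [prediction_set()]s with `sigma` present.
#' @param weights weights from [ensemble_weights()] (recycled equal weights
#'   when omitted).
#' @param level interval level (default 0.95).
#' @return a [prediction_set()].
#' @export
ensemble_predict <- function(members, weights = NULL, level = 0.95) {
  stopifnot(length(members) >= 1)
  n <- length(members[[1]]$y)
  for (m in members) {
    if (length(m$y) != n || any(abs(m$y - members[[1]]$y) > 1e-9))
      stop_tox("member prediction sets are not row-aligned")
    if (is.null(m$sigma)) stop_tox("every member must supply sigma")
  }
  if (is.null(weights)) weights <- rep(1 / length(members), length(members))
  if (abs(sum(weights) - 1) > 1e-9) stop_tox("weights must sum to 1")
  mus <- vapply(members, `[[`, numeric(n), "y_hat")
  sds <- vapply(members, `[[`, numeric(n), "sigma")
  if (n == 1) { mus <- matrix(mus, 1); sds <- matrix(sds, 1) }
  mu <- drop(mus %*% weights)
  second_moment <- drop((sds^2 + mus^2) %*% weights)
  sig <- sqrt(pmax(second_moment - mu^2, 0))
  z <- z_mult(level)
  prediction_set(members[[1]]$y, mu, lower = mu - z * sig,
                 upper = mu + z * sig, sigma = sig)
}
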