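## Scalar evaluators: RMSE / R^2 / MARE / MAE, Theil inequality coefficient,
## interval-calibration metrics (PI, coverage, calibration error, sharpness,
## NLL), folded standardized-residual diagnostics, and regression-through-
## origin external-validation statistics (k, k', R0^2).

#' Point-prediction metrics
#'
#' RMSE, coefficient of determination (against the observed mean), mean
#' absolute relative error and mean absolute error.  MARE is undefined when
#' any observation is exactly zero; it is then reported as `NA` with a
#' warning while the other metrics are computed.
#'
#' @param ps a [prediction_set()] with N >= 2.
#' @return list of class `point_metrics`: `rmse`, `r2`, `mare`, `mae`.
#' @export
point_metrics <- function(ps) {
  stopifnot(inherits(ps, "prediction_set"))
  y <- ps$y; yh <- ps$y_hat
  n <- length(y)
  if (n < 2) stop_tox("point_metrics requires N >= 2")
  rmse <- sqrt(mean((y - yh)^2))
  r2 <- 1 - sum((y - yh)^2) / sum((y - mean(y))^2)
  mae <- mean(abs(y - yh))
  mare <- if (any(y == 0)) {
    warning("MARE undefined: some observed values are exactly zero")
    NA_real_
  } else mean(abs((y - yh) / y))
  structure(list(rmse = rmse, r2 = r2, mare = mare, mae = mae),
            class = "point_metrics")
}

#' Theil inequality coefficient
#'
#' `TIC = RMSE / (sqrt(mean(y^2)) + sqrt(mean(y_hat^2)))`; bounded in
#' `[0, 1]`, 0 for perfect agreement.
#'
#' @param ps a [prediction_set()].
#' @return numeric scalar.
#' @export
tic <- function(ps) {
  stopifnot(inherits(ps, "prediction_set"))
  y <- ps$y; yh <- ps$y_hat
  denom <- sqrt(mean(y^2)) + sqrt(mean(yh^2))
  if (denom == 0) stop_tox("TIC undefined: y and y_hat are both all-zero")
  sqrt(mean((y - yh)^2)) / denom
}

#' Interval calibration metrics
#'
#' PI is the mean interval width; coverage the fraction of observations inside
#' their interval; calibration error the signed gap `nominal - coverage`;
#' sharpness the mean predictive SD (for Gaussian central intervals this
#' equals width / (2 z)); NLL the mean Gaussian negative log-likelihood.
#'
#' @param ps a [prediction_set()] with `lower`/`upper` (and `sigma` for
#'   sharpness/NLL).
#' @param nominal nominal coverage level (default 0.95).
#' @return list of class `interval_metrics`.
#' @export
interval_metrics <- function(ps, nominal = 0.95) {
  stopifnot(inherits(ps, "prediction_set"))
  missing <- c("lower", "upper")[c(is.null(ps$lower), is.null(ps$upper))]
  if (length(missing))
    stop_tox("interval_metrics requires fields: %s",
             paste(missing, collapse = ", "))
  pi_width <- mean(ps$upper - ps$lower)
  coverage <- mean(ps$y >= ps$lower & ps$y <= ps$upper)
  sharp <- nll <- NA_real_
  if (!is.null(ps$sigma)) {
    sharp <- mean(ps$sigma)
    if (all(ps$sigma > 0))
      nll <- mean(0.5 * log(2 * pi * ps$sigma^2) +
                    (ps$y - ps$y_hat)^2 / (2 * ps$sigma^2))
  }
  structure(list(pi = pi_width, coverage = coverage,
                 calibration_error = nominal - coverage,
                 sharpness = sharp, nll = nll, nominal = nominal),
            class = "interval_metrics")
}

#' Folded standardized-residual diagnostics
#'
#' Computes `z_i = |y_i - y_hat_i| / sigma_i` (the folded convention keeps all
#' location statistics positive), with mean, SD, median, skewness, kurtosis
#' and a moment-based omnibus normality test on the sign-restored residuals.
#' Kurtosis here is raw (normal -> 3) by default so the folded-normal
#' reference stays interpretable; set `excess_kurtosis = TRUE` to change.
#'
#' @param ps a [prediction_set()] with strictly positive `sigma`.
#' @param excess_kurtosis use Fisher excess instead of raw kurtosis.
#' @return list of class `residual_diagnostics`.
#' @export
residual_diagnostics <- function(ps, excess_kurtosis = FALSE) {
  stopifnot(inherits(ps, "prediction_set"))
  if (is.null(ps$sigma)) stop_tox("residual diagnostics require sigma")
  if (any(ps$sigma <= 0)) stop_tox("all sigma must be > 0")
  signed <- (ps$y - ps$y_hat) / ps$sigma
  z <- abs(signed)
  nt <- if (length(z) >= 20) dagostino_k2(signed) else
    list(statistic = NA_real_, p_value = NA_real_)
  structure(list(mean = mean(z), sd = sd(z), median = median(z),
                 skewness = sample_skewness(z, corrected = FALSE),
                 kurtosis = sample_kurtosis(z, excess = excess_kurtosis,
                                            corrected = FALSE),
                 normality_p = nt$p_value),
            class = "residual_diagnostics")
}

#' Regression-through-origin external-validation statistics
#'
#' `k = sum(y * y_hat) / sum(y_hat^2)` (observed on predicted through the
#' origin), `k'` the reverse slope, `R0^2` the origin-constrained
#' determination coefficient of observed vs `k * y_hat` (one of several
#' literature conventions; documented choice), and the relative gap
#' `|R^2 - R0^2| / R^2`.
#'
#' @param ps a [prediction_set()] with N >= 3.
#' @return list of class `rto_validation`: `k`, `k_prime`, `r2`, `r0_sq`,
#'   `rel_gap`.
#' @export
rto_validation <- function(ps) {
  stopifnot(inherits(ps, "prediction_set"))
  y <- ps$y; yh <- ps$y_hat
  if (length(y) < 3) stop_tox("rto_validation requires N >= 3")
  if (sum(yh^2) == 0 || sum(y^2) == 0)
    stop_tox("degenerate sums: all-zero y or y_hat")
  k <- sum(y * yh) / sum(yh^2)
  k_prime <- sum(y * yh) / sum(y^2)
  r2 <- 1 - sum((y - yh)^2) / sum((y - mean(y))^2)
  r0_sq <- 1 - sum((y - k * yh)^2) / sum((y - mean(y))^2)
  rel_gap <- if (r2 == 0) NA_real_ else abs(r2 - r0_sq) / abs(r2)
  structure(list(k = k, k_prime = k_prime, r2 = r2, r0_sq = r0_sq,
                 rel_gap = rel_gap),
            class = "rto_validation")
}

#' Conformal prediction intervals from held-out absolute residuals
#'
#' For point models without native uncertainty (PC-GBM, SR) intervals are
#' formed as `y_hat +/- q`, where `q` is the conformal quantile (order
#' statistic `ceiling((m + 1) * level)` of `m` calibration residuals, capped
#' at the maximum).  The implied Gaussian-equivalent SD `q / z(level)` is
#' stored as `sigma`.
#'
#' @param y observed responses of the evaluation rows.
#' @param y_hat point predictions for the evaluation rows.
#' @param calib_abs_resid absolute residuals from held-out calibration rows
#'   (e.g. out-of-fold CV residuals).
#' @param level interval level (default 0.95).
#' @return a [prediction_set()].
#' @export
conformal_intervals <- function(y, y_hat, calib_abs_resid, level = 0.95) {
  m <- length(calib_abs_resid)
  if (m < 5) stop_tox("need >= 5 calibration residuals")
  r <- sort(calib_abs_resid)
  q <- r[min(ceiling((m + 1) * level), m)]
  prediction_set(y, y_hat, lower = y_hat - q, upper = y_hat + q,
                 sigma = rep(q / z_mult(level), length(y_hat)))
}

#' Flat JSON-ready metric report
#'
#' @param point a [point_metrics()] result (optional).
#' @param interval an [interval_metrics()] result (optional).
#' @param ps optional [prediction_set()] for TIC.
#' @return named list keyed `rmse`, `r2`, `mare`, `mae`, `pi`, `tic`,
#'   `coverage`, `calibration_error`, `sharpness`, `nll`.
#' @export
metric_report <- function(point = NULL, interval = NULL, ps = NULL) {
  out <- list(rmse = NA_real_, r2 = NA_real_, mare = NA_real_, mae = NA_real_,
              pi = NA_real_, tic = NA_real_, coverage = NA_real_,
              calibration_error = NA_real_, sharpness = NA_real_,
              nll = NA_real_)
  if (!is.null(point)) out[c("rmse", "r2", "mare", "mae")] <-
      point[c("rmse", "r2", "mare", "mae")]
  if (!is.null(interval)) out[c("pi", "coverage", "calibration_error",
                                "sharpness", "nll")] <-
      interval[c("pi", "coverage", "calibration_error", "sharpness", "nll")]
  if (!is.null(ps)) out$tic <- tic(ps)
  out
}
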