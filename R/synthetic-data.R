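## Calibrated synthetic compound generator.  Marginals reproduce the published
## per-descriptor summaries (bounds, mean, SD; mode for the discrete counts);
## the response surface embeds the symbolic-regression-consistent linear form
## pIGC50 = 0.42*LogP + 0.015*MW - 0.31*GATS1p (+ small monotone nDB/nROH
## terms) + C + Gaussian noise, clipped to the observed target range.

## ---- truncated-distribution moment helpers -------------------------------

trunc_norm_moments <- function(mu, sigma, a, b) {
  al <- (a - mu) / sigma; be <- (b - mu) / sigma
  z <- pnorm(be) - pnorm(al)
  m <- mu + sigma * (dnorm(al) - dnorm(be)) / z
  v <- sigma^2 * (1 + (al * dnorm(al) - be * dnorm(be)) / z -
                    ((dnorm(al) - dnorm(be)) / z)^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

trunc_lnorm_moments <- function(ml, sl, a, b) {
  d <- function(x, shift = 0) {
    if (x <= 0) -Inf else (log(x) - ml) / sl - shift
  }
  z <- pnorm(d(b)) - pnorm(d(a))
  e1 <- exp(ml + sl^2 / 2) * (pnorm(d(b, sl)) - pnorm(d(a, sl))) / z
  e2 <- exp(2 * ml + 2 * sl^2) * (pnorm(d(b, 2 * sl)) - pnorm(d(a, 2 * sl))) / z
  c(mean = e1, sd = sqrt(max(e2 - e1^2, 0)))
}

## solve parent parameters so that post-truncation mean/sd hit the spec
solve_marginal <- function(spec) {
  target <- c(spec$mean, spec$sd)
  lognormal <- spec$name %in% c("A", "B")  # right-skewed, lower bound 0
  obj <- function(par) {
    mom <- if (lognormal)
      trunc_lnorm_moments(par[1], exp(par[2]), spec$lower, spec$upper)
    else trunc_norm_moments(par[1], exp(par[2]), spec$lower, spec$upper)
    if (any(!is.finite(mom))) return(1e6)
    sum(((mom - target) / pmax(abs(target), 0.1))^2)
  }
  init <- if (lognormal) {
    cv2 <- (spec$sd / spec$mean)^2
    sl <- sqrt(log(1 + cv2))
    c(log(spec$mean) - sl^2 / 2, log(sl))
  } else c(spec$mean, log(spec$sd))
  fit <- optim(init, obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  list(family = if (lognormal) "lognormal" else "normal",
       p1 = fit$par[1], p2 = exp(fit$par[2]), objective = fit$value)
}

## clipped (censored) normal moments, closed form
clip_norm_moments <- function(mu, sigma, a, b) {
  al <- (a - mu) / sigma; be <- (b - mu) / sigma
  z <- pnorm(be) - pnorm(al)
  e1 <- a * pnorm(al) + b * (1 - pnorm(be)) +
    mu * z + sigma * (dnorm(al) - dnorm(be))
  e2 <- a^2 * pnorm(al) + b^2 * (1 - pnorm(be)) +
    (mu^2 + sigma^2) * z + sigma^2 * (al * dnorm(al) - be * dnorm(be)) +
    2 * mu * sigma * (dnorm(al) - dnorm(be))
  c(mean = e1, sd = sqrt(max(e2 - e1^2, 0)))
}

## ---- configuration --------------------------------------------------------

#' Create a synthetic-generator configuration
#'
#' Default coefficients follow the published symbolic-regression form
#' (0.42 LogP + 0.015 MW - 0.31 GATS1p) plus small monotone terms for the
#' double-bond count (+0.05) and hydroxyl count (-0.05) so constraint-recovery
#' experiments have signal.  Intercept and noise SD are solved by
#' [calibrate_generator()].
#'
#' @param specs descriptor specs ([descriptor_specs()] defaults).
#' @param target_spec spec of the pIGC50 target (bounds, mean, SD).
#' @param coeffs named linear coefficients; signs must respect the monotone
#'   directions declared in `specs`.
#' @param intercept,noise_sd usually left `NA` and solved by calibration.
#' @param seed default generation seed.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(specs = descriptor_specs(),
                             target_spec = descriptor_specs(TRUE)$pIGC50,
                             coeffs = c(LogP = 0.42, MW = 0.015,
                                        GATS1p = -0.31, nDB = 0.05,
                                        nROH = -0.05),
                             intercept = NA_real_, noise_sd = NA_real_,
                             seed = 1L) {
  stopifnot(length(names(coeffs)) == length(coeffs))
  missing <- setdiff(names(coeffs), names(specs))
  if (length(missing))
    stop_tox("coefficients reference unknown descriptors: %s",
             paste(missing, collapse = ", "))
  for (nm in names(coeffs)) {
    dir <- specs[[nm]]$monotone_direction
    if (dir != 0 && coeffs[[nm]] != 0 && sign(coeffs[[nm]]) != dir)
      stop_tox("coefficient sign for %s conflicts with its monotone direction",
               nm)
  }
  if (!is.na(noise_sd) && noise_sd < 0) stop_tox("noise_sd must be >= 0")
  structure(list(specs = specs, target_spec = target_spec, coeffs = coeffs,
                 intercept = intercept, noise_sd = noise_sd,
                 marginals = NULL, calibrated = FALSE, seed = as.integer(seed)),
            class = "generator_config")
}

#' Calibrate the generator's intercept and noise SD by moment matching
#'
#' Solves each continuous descriptor's parent distribution so truncated
#' moments match its spec, then solves `(C, noise_sd)` so the clipped target
#' reproduces the target spec's mean and SD (normal approximation of the
#' pre-clip response; descriptors treated as independent).  A closed-form
#' solution ignoring clipping initializes the 2-parameter numeric solve.
#'
#' @param config a [generator_config()].
#' @return the calibrated config (intercept, noise_sd, marginals filled in).
#' @export
calibrate_generator <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  specs <- config$specs
  marg <- lapply(specs, function(sp) {
    if (sp$kind == "discrete") {
      p <- (sp$mean - sp$lower) / (sp$upper - sp$lower)
      list(family = "binomial", size = sp$upper - sp$lower, prob = p,
           shift = sp$lower)
    } else solve_marginal(sp)
  })
  b <- config$coeffs
  mu_sys <- sum(vapply(names(b), function(nm) b[[nm]] * specs[[nm]]$mean, 0))
  var_sys <- sum(vapply(names(b), function(nm) (b[[nm]] * specs[[nm]]$sd)^2, 0))
  tg <- config$target_spec
  noise_var0 <- tg$sd^2 - var_sys
  if (noise_var0 < 0)
    stop_tox(paste0("infeasible noise variance (%.4f): systematic variance ",
                    "exceeds the target variance; rescale coefficients"),
             noise_var0)
  c0 <- tg$mean - mu_sys
  ns0 <- sqrt(noise_var0)
  # refine for the (small) effect of clipping y to the target bounds
  obj <- function(par) {
    mom <- clip_norm_moments(mu_sys + par[1], sqrt(var_sys + exp(2 * par[2])),
                             tg$lower, tg$upper)
    sum(((mom - c(tg$mean, tg$sd)) / c(tg$mean, tg$sd))^2)
  }
  fit <- optim(c(c0, log(ns0)), obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-14))
  config$intercept <- fit$par[1]
  config$noise_sd <- exp(fit$par[2])
  config$marginals <- marg
  config$calibrated <- TRUE
  config
}

#' Generate a synthetic compound table
#'
#' Continuous descriptors are drawn by inverse-CDF sampling from their
#' truncated parent distributions; discrete counts from bounded binomial
#' distributions peaked at the published mode; the target is the linear
#' response plus Gaussian noise, clipped to the target bounds.  Fully
#' reproducible per seed.
#'
#' @param config a calibrated [generator_config()].
#' @param n number of compounds (> 0).
#' @param seed integer seed (defaults to the config's).
#' @return a [compound_table()] with target.
#' @export
generate_compounds <- function(config, n, seed = config$seed) {
  stopifnot(inherits(config, "generator_config"))
  if (!isTRUE(config$calibrated))
    stop_tox("config must be calibrated first (calibrate_generator)")
  if (n <= 0) stop_tox("n must be positive")
  specs <- config$specs
  with_seed(seed, {
    X <- matrix(NA_real_, n, length(specs),
                dimnames = list(NULL, names(specs)))
    for (nm in names(specs)) {
      sp <- specs[[nm]]; mg <- config$marginals[[nm]]
      X[, nm] <- switch(
        mg$family,
        binomial = rbinom(n, mg$size, mg$prob) + mg$shift,
        normal = {
          lo <- pnorm(sp$lower, mg$p1, mg$p2)
          hi <- pnorm(sp$upper, mg$p1, mg$p2)
          qnorm(runif(n, lo, hi), mg$p1, mg$p2)
        },
        lognormal = {
          lo <- plnorm(sp$lower, mg$p1, mg$p2)
          hi <- plnorm(sp$upper, mg$p1, mg$p2)
          qlnorm(runif(n, lo, hi), mg$p1, mg$p2)
        })
    }
    y <- true_response(X, config) + rnorm(n, 0, config$noise_sd)
    y <- pmin(pmax(y, config$target_spec$lower), config$target_spec$upper)
    compound_table(sprintf("CMP%06d", seq_len(n)), X, y, specs)
  })
}

#' Noiseless ground-truth response of the generator
#'
#' Linear in the configured coefficients; monotone non-decreasing in LogP, MW
#' and nDB and non-increasing in nROH by construction (no clipping, so slopes
#' are exact everywhere).
#'
#' @param x named numeric vector or matrix with descriptor columns.
#' @param config a calibrated [generator_config()].
#' @return numeric response value(s).
#' @export
true_response <- function(x, config) {
  if (!isTRUE(config$calibrated))
    stop_tox("config must be calibrated first (calibrate_generator)")
  if (is.null(dim(x))) x <- matrix(x, 1, dimnames = list(NULL, names(x)))
  b <- config$coeffs
  miss <- setdiff(names(b), colnames(x))
  if (length(miss))
    stop_tox("input lacks descriptor(s): %s", paste(miss, collapse = ", "))
  drop(x[, names(b), drop = FALSE] %*% as.numeric(b)) + config$intercept
}
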