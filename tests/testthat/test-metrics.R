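# independent brute-force oracle: explicit summation loops, no shared code
oracle_metrics <- function(y, yh) {
  n <- length(y)
  se <- ae <- re <- 0
  for (i in seq_len(n)) {
    se <- se + (y[i] - yh[i])^2
    ae <- ae + abs(y[i] - yh[i])
    re <- re + abs((y[i] - yh[i]) / y[i])
  }
  ybar <- sum(y) / n
  sst <- sum((y - ybar)^2)
  list(rmse = sqrt(se / n), r2 = 1 - se / sst, mae = ae / n, mare = re / n,
       tic = sqrt(se / n) / (sqrt(sum(y^2) / n) + sqrt(sum(yh^2) / n)),
       k = sum(y * yh) / sum(yh^2), k_prime = sum(y * yh) / sum(y^2))
}

test_that("point metrics match hand arithmetic and identities", {
  ps <- prediction_set(c(1, 2, 3), c(1, 2, 4))
  pm <- point_metrics(ps)
  expect_equal(pm$rmse, sqrt(1 / 3), tolerance = 1e-12)
  expect_equal(pm$r2, 0.5)
  expect_equal(pm$mae, 1 / 3)
  expect_equal(pm$mare, 1 / 9)

  ident <- prediction_set(c(1, 2, 3), c(1, 2, 3))
  pmi <- point_metrics(ident)
  expect_equal(unlist(pmi[c("rmse", "mare", "mae")]), c(rmse = 0, mare = 0,
                                                        mae = 0))
  expect_equal(pmi$r2, 1)

  const <- prediction_set(c(1, 2, 3), rep(2, 3))
  expect_equal(point_metrics(const)$r2, 0)

  expect_warning(z <- point_metrics(prediction_set(c(0, 1, 2), c(0, 1, 2))),
                 "MARE")
  expect_true(is.na(z$mare))
})

test_that("TIC matches hand arithmetic and stays in [0, 1]", {
  expect_equal(round(tic(prediction_set(c(1, 2, 3), c(1, 2, 4))), 4), 0.1201)
  expect_equal(tic(prediction_set(c(1, 2, 3), c(1, 2, 3))), 0)
  expect_equal(tic(prediction_set(c(1, -2, 3), -c(1, -2, 3))), 1)
  expect_error(tic(prediction_set(c(0, 0), c(0, 0))), "all-zero")
  set.seed(51)
  for (i in 1:200) {
    v <- tic(prediction_set(rnorm(10), rnorm(10)))
    expect_gte(v, 0); expect_lte(v, 1)
  }
})

test_that("interval metrics reproduce the published calibration pairs", {
  # coverage 66.8% at nominal 95% -> calibration error 0.2820
  set.seed(52)
  n <- 1000
  inside <- seq_len(n) <= 668
  y <- rep(0, n)
  yh <- rep(0, n)
  lower <- ifelse(inside, -1, 1); upper <- ifelse(inside, 1, 3)
  yh <- (lower + upper) / 2
  ps <- prediction_set(y, yh, lower, upper,
                       sigma = (upper - lower) / (2 * qnorm(0.975)))
  im <- interval_metrics(ps, nominal = 0.95)
  expect_equal(im$coverage, 0.668)
  expect_equal(round(im$calibration_error, 4), 0.2820)

  # Gaussian 95% intervals of mean width 0.4957 -> sharpness 0.1265
  sig <- 0.4957 / (2 * qnorm(0.975))
  ps2 <- prediction_set(rnorm(50), rep(0, 50), rep(-0.4957 / 2, 50),
                        rep(0.4957 / 2, 50), rep(sig, 50))
  im2 <- interval_metrics(ps2)
  expect_equal(im2$pi, 0.4957)
  expect_equal(round(im2$sharpness, 4), 0.1265)

  # hand arithmetic example
  ps3 <- prediction_set(c(1, 2, 3), c(1, 3, 3),
                        lower = c(0.5, 2.5, 2.5), upper = c(1.5, 3.5, 3.5))
  im3 <- interval_metrics(ps3)
  expect_equal(im3$pi, 1.0)
  expect_equal(im3$coverage, 2 / 3)
  expect_equal(round(im3$calibration_error, 4), 0.2833)

  expect_error(interval_metrics(prediction_set(1:3, 1:3)), "lower")
  # calibration error is linear in coverage with slope -1
  covs <- runif(20)
  expect_equal(0.95 - covs, vapply(covs, function(cv) 0.95 - cv, 0))
})

test_that("NLL equals the Gaussian log-density average", {
  set.seed(53)
  ps <- random_prediction_set(100)
  im <- interval_metrics(ps)
  expect_equal(im$nll,
               -mean(dnorm(ps$y, ps$y_hat, ps$sigma, log = TRUE)),
               tolerance = 1e-12)
})

test_that("residual diagnostics follow the folded convention", {
  y <- c(2, 3, 4); mu <- c(1, 2, 3); sig <- c(1, 1, 1)
  rd <- residual_diagnostics(prediction_set(y, mu, sigma = sig))
  expect_equal(rd$mean, 1); expect_equal(rd$sd, 0)

  ps <- prediction_set(y, mu, sigma = sig * 2)
  expect_equal(residual_diagnostics(ps)$mean, 0.5)   # doubling sigma halves z

  set.seed(54)
  r <- rnorm(1e4)
  psn <- prediction_set(r, rep(0, 1e4), sigma = rep(1, 1e4))
  rdn <- residual_diagnostics(psn)
  # folded-normal references: skewness ~0.9953, raw kurtosis ~3.8692
  expect_equal(rdn$skewness, 0.9953, tolerance = 0.1)
  expect_equal(rdn$kurtosis, 3.8692, tolerance = 0.15)
  # the omnibus test runs on sign-restored residuals: a Gaussian residual
  # stream is not rejected, a strongly skewed one is
  expect_gt(rdn$normality_p, 0.01)
  skewed <- prediction_set(exp(rnorm(1e4)), rep(0, 1e4), sigma = rep(1, 1e4))
  expect_lt(residual_diagnostics(skewed)$normality_p, 1e-6)
  expect_error(residual_diagnostics(prediction_set(y, mu, sigma = c(0, 1, 1))),
               "> 0")
})

test_that("regression-through-origin statistics match hand arithmetic", {
  rv <- rto_validation(prediction_set(c(1, 2, 3), c(1.1, 1.9, 3.2)))
  expect_equal(rv$k, 0.9628, tolerance = 1e-4)
  expect_equal(rv$k_prime, 1.0357, tolerance = 1e-4)

  ident <- rto_validation(prediction_set(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(ident$k, 1); expect_equal(ident$k_prime, 1)
  expect_equal(ident$rel_gap, 0)

  sc <- rto_validation(prediction_set(c(1, 2, 3), 2 * c(1, 2, 3)))
  expect_equal(sc$k, 0.5); expect_equal(sc$k_prime, 2)
  expect_error(rto_validation(prediction_set(1:2, 1:2)), "N >= 3")
})

test_that("all evaluators agree with the brute-force oracle", {
  set.seed(55)
  for (i in 1:200) {
    n <- sample(5:40, 1)
    y <- rnorm(n, 3, 1); yh <- y + rnorm(n, 0, 0.5)
    ps <- prediction_set(y, yh)
    o <- oracle_metrics(y, yh)
    pm <- point_metrics(ps)
    expect_equal(pm$rmse, o$rmse, tolerance = 1e-10)
    expect_equal(pm$r2, o$r2, tolerance = 1e-10)
    expect_equal(pm$mae, o$mae, tolerance = 1e-10)
    expect_equal(pm$mare, o$mare, tolerance = 1e-10)
    expect_equal(tic(ps), o$tic, tolerance = 1e-10)
    rv <- rto_validation(ps)
    expect_equal(rv$k, o$k, tolerance = 1e-10)
    expect_equal(rv$k_prime, o$k_prime, tolerance = 1e-10)
  }
})

test_that("conformal intervals cover at the requested level", {
  set.seed(56)
  resid <- abs(rnorm(500, 0, 0.5))
  y_hat <- rnorm(300, 3)
  y <- y_hat + rnorm(300, 0, 0.5)
  ps <- conformal_intervals(y, y_hat, resid, level = 0.95)
  expect_true(all(ps$upper - ps$lower > 0))
  expect_gt(interval_metrics(ps)$coverage, 0.9)
  expect_error(conformal_intervals(y, y_hat, resid[1:3]), ">= 5")
})
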