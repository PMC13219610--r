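gbm_factory <- function(seed = 1) {
  cfg <- gbm_config(n_estimators = 60, max_depth = 3,
                    constraints = constraint_map(), seed = seed)
  function(X, y) fit_pcgbm(X, y, cfg)
}

test_that("Y-scrambling collapses permuted performance and is deterministic", {
  tab <- gen_table(400, seed = 91)
  rep1 <- yscrambling(gbm_factory(), tab$X, tab$y, n_perm = 10, seed = 5)
  expect_length(rep1$scrambled_r2, 10)
  expect_lte(rep1$scrambled_mean, 0.1)
  expect_true(rep1$passed)
  expect_gt(rep1$original_r2, rep1$scrambled_max)

  rep2 <- yscrambling(gbm_factory(), tab$X, tab$y, n_perm = 10, seed = 5)
  expect_identical(rep1$scrambled_r2, rep2$scrambled_r2)
  expect_error(yscrambling(gbm_factory(), tab$X, tab$y, n_perm = 5), ">= 10")
})

test_that("a pure-noise target fails the scrambling criterion (negative control)", {
  tab <- gen_table(300, seed = 92)
  set.seed(920)
  noise <- rnorm(300)   # response unrelated to the descriptors
  rep <- yscrambling(gbm_factory(), tab$X, noise, n_perm = 12, seed = 6)
  expect_false(rep$passed)
})

test_that("z statistic is invariant to common positive affine rescaling", {
  r2s <- c(orig = 0.8, s = c(0.01, -0.1, 0.05, -0.02))
  z <- function(v) (v[1] - mean(v[-1])) / sd(v[-1])
  expect_equal(z(2.5 * r2s + 1), z(r2s))
})

test_that("applicability domain flags behave under the 2-SD rule", {
  tab <- gen_table(500, seed = 93)
  tr <- table_subset(tab, 1:400)
  te <- table_subset(tab, 401:500)
  ad <- ad_assess(tr, te)
  expect_true(all(ad$distances >= 0))
  expect_gte(ad$in_domain_fraction, 0)

  # query = training rows: nearly everything is in-domain
  self <- ad_assess(tr, tr)
  expect_gte(self$in_domain_fraction, 0.95)

  # query at the training centroid: distance ~0, in-domain
  sc <- fit_scaler(tr)
  ctr <- compound_table("ctr", matrix(sc$center, 1,
                                      dimnames = list(NULL, colnames(tr$X))))
  adc <- ad_assess(tr, ctr, sc)
  expect_lt(adc$distances, 1e-9)
  expect_true(adc$in_domain)

  # far extrapolation: nothing in-domain
  far <- compound_table(te$ids, te$X * 5 + 100)
  expect_equal(ad_assess(tr, far)$in_domain_fraction, 0)

  # threshold monotonicity: percentile rule is tighter here, never covers more
  p_rule <- ad_assess(tr, te, threshold_rule = "percentile")
  wide <- mean(te_d <- ad$distances <= max(ad$threshold, p_rule$threshold))
  narrow <- mean(ad$distances <= min(ad$threshold, p_rule$threshold))
  expect_gte(wide, narrow)
})

test_that("uncertainty associations detect signal and reject degenerate input", {
  set.seed(94)
  d <- runif(1000, 0, 3)
  expect_equal(uncertainty_associations(d, d)$r_distance_width, 1)
  noise <- runif(1000)
  a <- uncertainty_associations(d, noise)
  expect_lt(abs(a$r_distance_width), 0.1)
  expect_error(uncertainty_associations(d, rep(1, 1000)), "zero variance")
  expect_error(uncertainty_associations(d[1:5], noise[1:5]), "N >=")

  err <- noise * 2 + runif(1000, 0, 0.1)
  b <- uncertainty_associations(d, noise, err)
  expect_gt(b$q4_q1_error_ratio, 1)   # errors track widths by construction
})

test_that("BNN interval widths grow with centroid distance on generator data", {
  ok <- vapply(1:3, function(s) {
    tab <- gen_table(500, seed = 100 + s)
    tr <- table_subset(tab, 1:350)
    te <- table_subset(tab, 351:500)
    st <- standardize(tr, te)
    m <- fit_bnn(standardize(tr)$table$X, tr$y, small_bnn(seed = s))
    ps <- predict_dist(m, st$table$X, y = te$y, S = 50, seed = s)
    ad <- ad_assess(tr, te, st$scaler, widths = ps$upper - ps$lower)
    ad$r_distance_width > 0 && ad$q4_q1_width_ratio > 1
  }, TRUE)
  expect_gte(sum(ok), 2)
})
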