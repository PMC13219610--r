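# synthetic factory whose loss depends on the configuration through a known
# function: predictions are offset from truth by f(config), intervals fixed
synthetic_factory <- function(f) {
  function(cfg) {
    offset <- f(cfg)
    list(
      fit = function(X, y) list(mean = mean(y), offset = offset),
      predict_ps = function(model, X, y) {
        yh <- y + model$offset          # rmse == |offset| by construction
        prediction_set(y, yh, lower = yh - 5, upper = yh + 5,
                       sigma = rep(5 / 1.96, length(y)))
      })
  }
}

test_that("composite loss matches hand arithmetic and its reductions", {
  pm <- structure(list(rmse = 0.3, r2 = 0.9, mare = 0.1, mae = 0.2),
                  class = "point_metrics")
  im <- structure(list(pi = 0.4957, coverage = 0.668,
                       calibration_error = 0.282, sharpness = 0.13,
                       nll = 1, nominal = 0.95), class = "interval_metrics")
  expect_equal(composite_loss(pm, im, 1, 0.5), 0.3 + 0.282 + 0.24785)
  expect_equal(composite_loss(pm, im, 0, 0), 0.3)
  im$coverage <- 0.99   # over-coverage earns no hinge penalty
  expect_equal(composite_loss(pm, im, 1, 0), 0.3)
  expect_error(composite_loss(pm, im, -1, 0), ">= 0")
})

test_that("search histories are complete, bounded and deterministic", {
  set.seed(61)
  X <- matrix(rnorm(100), 50, 2, dimnames = list(NULL, c("a", "b")))
  y <- rnorm(50)
  folds <- kfold_plan(50, 5, seed = 1)
  space <- gbm_search_space()
  fac <- synthetic_factory(function(cfg)
    (cfg$learning_rate - 0.045)^2 * 100 + (cfg$subsample - 0.8)^2 * 10)

  tr <- tune_model(fac, space, X, y, folds, budget = 5, seed = 3)
  expect_equal(nrow(tr$history), 5)
  expect_equal(tr$best_loss, min(tr$history$loss))

  tr2 <- tune_model(fac, space, X, y, folds, budget = 12, seed = 3)
  expect_identical(tune_model(fac, space, X, y, folds, budget = 12,
                              seed = 3)$history, tr2$history)
  for (p in space) {
    expect_true(all(tr2$history[[p$name]] >= p$lower))
    expect_true(all(tr2$history[[p$name]] <= p$upper))
  }
  expect_true(all(diff(cummin(tr2$history$loss)) <= 0))  # best-so-far trace
  expect_error(tune_model(fac, space, X, y, folds, budget = 3), ">= 5")
})

test_that("a constant objective returns the first configuration", {
  X <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("a", "b")))
  y <- rnorm(30)
  folds <- kfold_plan(30, 3, seed = 1)
  fac <- synthetic_factory(function(cfg) 0.7)
  tr <- tune_model(fac, gbm_search_space(), X, y, folds, budget = 8, seed = 2)
  expect_identical(tr$best_config, tr$configs[[1]])
})

test_that("failing configurations score +Inf and the search continues", {
  X <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("a", "b")))
  y <- rnorm(30)
  folds <- kfold_plan(30, 3, seed = 1)
  fac <- function(cfg) {
    if (cfg$max_depth == 6) stop("boom")
    synthetic_factory(function(cfg) cfg$learning_rate)(cfg)
  }
  tr <- tune_model(fac, gbm_search_space(), X, y, folds, budget = 10, seed = 4)
  expect_equal(nrow(tr$history), 10)
  expect_true(is.finite(tr$best_loss))
})

test_that("the surrogate beats pure random search on a smooth objective", {
  X <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("a", "b")))
  y <- rnorm(30)
  folds <- kfold_plan(30, 3, seed = 1)
  f <- function(cfg) (cfg$learning_rate - 0.052)^2 * 2000 +
    (cfg$subsample - 0.74)^2 * 50 + (cfg$l2 - 0.8)^2 * 10
  fac <- synthetic_factory(f)
  wins <- vapply(1:3, function(s) {
    tuned <- tune_model(fac, gbm_search_space(), X, y, folds, budget = 30,
                        seed = s)$best_loss
    # pure random baseline from the same seed bank as the tuner's exploration
    rand <- min(vapply(1:30, function(i) {
      cfg <- with_seed(derive_seed(s, i), toxqsar:::space_sample(
        gbm_search_space()))
      f(cfg) + 0.5 * 10   # same additive interval terms as the factory path
    }, 0))
    tuned <= rand + 1e-9
  }, TRUE)
  expect_gte(sum(wins), 2)
})
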