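test_that("degenerate and deterministic behaviour of the booster", {
  set.seed(2)
  X <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, c("a", "b", "c", "d")))
  y_const <- rep(2.5, 50)
  m <- fit_pcgbm(X, y_const, small_gbm(constraints = c(a = 1L)))
  expect_equal(predict(m, X), rep(2.5, 50), tolerance = 1e-9)

  y <- X[, 1] - 0.5 * X[, 2] + rnorm(50, 0, 0.1)
  cfg <- small_gbm(constraints = c(a = 1L), seed = 7)
  m1 <- fit_pcgbm(X, y, cfg)
  m2 <- fit_pcgbm(X, y, cfg)
  expect_identical(predict(m1, X), predict(m2, X))   # bitwise refit identity

  perm <- sample(50)
  expect_identical(predict(m1, X[perm, ]), predict(m1, X)[perm])

  expect_error(fit_pcgbm(X[1:5, ], y[1:5], cfg), "n >= 10")
  expect_error(fit_pcgbm(X, y, small_gbm(constraints = c(zz = 1L))),
               "unknown column")
  expect_error(predict(m1, X[, 1:3]), "columns")
})

test_that("monotone constraints hold on grid sweeps; negative control violates", {
  tab <- gen_table(600, seed = 41)
  m <- fit_pcgbm(tab, config = small_gbm(seed = 3))
  anchors <- tab$X[1:50, ]
  for (f in c("LogP", "MW", "nDB", "nROH"))
    expect_equal(check_monotonic(m, anchors, f, grid_size = 21), 0)
  expect_equal(check_monotonic(m, anchors, "LogP", grid_size = 1), 0L)
  expect_error(check_monotonic(m, anchors, "GATS1p"), "not constrained")

  # negative control: unconstrained fit on steeply non-monotone data
  set.seed(4)
  Xs <- cbind(x = runif(300, 0, 4 * pi), z = rnorm(300))
  ys <- sin(Xs[, "x"]) + rnorm(300, 0, 0.05)
  un <- fit_pcgbm(Xs, ys, small_gbm(constraints = integer(0)))
  un$constraints[["x"]] <- 1L   # audit the declared +1 direction post hoc
  expect_gt(check_monotonic(un, Xs[1:40, ], "x", grid_size = 21), 0)
  # the same data fit *with* the constraint audits clean
  con <- fit_pcgbm(Xs, ys, small_gbm(constraints = c(x = 1L)))
  expect_equal(check_monotonic(con, Xs[1:40, ], "x", grid_size = 21), 0)
})

test_that("boosting descent: more trees never raise training RMSE", {
  set.seed(9)
  X <- matrix(rnorm(600), 150, 4, dimnames = list(NULL, c("a", "b", "c", "d")))
  y <- X[, 1]^2 - X[, 2] + rnorm(150, 0.2)
  rmses <- vapply(c(20, 60, 120, 200), function(nt) {
    m <- fit_pcgbm(X, y, gbm_config(n_estimators = nt, subsample = 1,
                                    learning_rate = 0.05, max_depth = 3,
                                    constraints = integer(0), seed = 1))
    sqrt(mean((y - m$train_pred)^2))
  }, 0)
  expect_true(all(diff(rmses) <= 1e-9))
})

test_that("zero constraints reduce to ordinary boosting", {
  set.seed(10)
  X <- matrix(rnorm(400), 100, 4, dimnames = list(NULL, c("a", "b", "c", "d")))
  y <- X %*% c(1, -1, 0.5, 0) + rnorm(100, 0, 0.2)
  m0 <- fit_pcgbm(X, y, small_gbm(constraints = integer(0), seed = 5))
  mz <- fit_pcgbm(X, y, small_gbm(constraints = c(a = 0L, b = 0L, c = 0L,
                                                  d = 0L), seed = 5))
  expect_identical(predict(m0, X), predict(mz, X))
})

test_that("gain importances are normalized and identify the signal", {
  set.seed(11)
  X <- matrix(rnorm(400), 100, 4, dimnames = list(NULL, c("a", "b", "c", "d")))
  y1 <- 2 * X[, "c"] + rnorm(100, 0, 0.01)
  m1 <- fit_pcgbm(X, y1, small_gbm(constraints = integer(0)))
  imp <- gbm_importance(m1)
  expect_equal(sum(imp), 1, tolerance = 1e-9)
  expect_gt(imp[["c"]], 0.98)

  # cross-fold averaging: LogP and MW dominate on generator data
  tab <- gen_table(800, seed = 51)
  folds <- kfold_plan(800, 10, seed = 2)
  cv <- gbm_importance_cv(tab, folds = folds, config = small_gbm(seed = 2))
  expect_equal(dim(cv$per_fold), c(10, 8))
  top2 <- names(sort(cv$mean, decreasing = TRUE))[1:2]
  expect_setequal(top2, c("LogP", "MW"))
})

test_that("serialized trees reproduce predictions", {
  set.seed(12)
  X <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, c("a", "b", "c", "d")))
  y <- X[, 1] + rnorm(50, 0, 0.1)
  m <- fit_pcgbm(X, y, small_gbm(constraints = c(a = 1L), n_estimators = 10))
  ser <- gbm_serialize(m)
  expect_length(ser$trees, 10)
  # walk the serialized first tree by hand for one row
  walk <- function(tree, x) {
    i <- 1
    while (tree$feature[i] >= 0) {
      j <- tree$feature[i] + 1
      i <- if (x[j] < tree$threshold[i]) tree$left[i] + 1 else tree$right[i] + 1
    }
    tree$value[i]
  }
  manual <- ser$base_score +
    sum(vapply(ser$trees, walk, 0, x = X[1, ]))
  expect_equal(manual, predict(m, X[1, , drop = FALSE]), tolerance = 1e-12)
})
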