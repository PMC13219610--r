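make_table <- function(X, y = NULL) {
  compound_table(sprintf("c%04d", seq_len(nrow(X))), X, y)
}

test_that("variance filter drops exactly the near-constant columns", {
  set.seed(7)
  X <- matrix(rnorm(200), 20, 10,
              dimnames = list(NULL, paste0("d", 1:10)))
  X[, 3] <- 5
  X[, 8] <- -1
  out <- filter_low_variance(make_table(X), tau = 0)
  expect_setequal(out$dropped, c("d3", "d8"))
  expect_equal(colnames(out$table$X), paste0("d", setdiff(1:10, c(3, 8))))

  half <- cbind(a = rnorm(30, sd = sqrt(0.5)), b = rnorm(30))
  kept <- filter_low_variance(make_table(half), tau = 0.1)
  expect_length(kept$dropped, 0)

  expect_error(filter_low_variance(make_table(cbind(k = rep(1, 5))), 0),
               "every column")
})

test_that("correlation filter drops the later column of each |r| > r_max pair", {
  set.seed(8)
  n <- 200
  base <- rnorm(n)
  X <- cbind(a = base,
             b = base,                                  # r = 1 with a
             c = 0.95 * base + sqrt(1 - 0.95^2) * rnorm(n),
             d = 0.5 * base + sqrt(0.75) * rnorm(n))
  tab <- make_table(X)
  expect_gt(abs(cor(X[, "a"], X[, "c"])), 0.9)
  expect_lt(abs(cor(X[, "a"], X[, "d"])), 0.9)
  out <- filter_correlated(tab, r_max = 0.9)
  expect_setequal(out$dropped, c("b", "c"))
  expect_true(all(out$pairs$kept == "a"))
  # audit: survivors contain no remaining pair above the threshold
  cs <- cor(out$table$X)
  diag(cs) <- 0
  expect_lt(max(abs(cs)), 0.9)

  expect_error(filter_correlated(make_table(X[1:2, ])), "n >= 3")
})

test_that("rank_select recovers the informative descriptors across folds", {
  tab <- gen_table(400, seed = 21)
  y_lin <- 0.42 * tab$X[, "LogP"] + 0.015 * tab$X[, "MW"] -
    0.31 * tab$X[, "GATS1p"] + rnorm(400, 0, 0.1)
  tab2 <- compound_table(tab$ids, tab$X, y_lin, tab$specs)
  folds <- kfold_plan(400, 10, seed = 3)
  rs <- rank_select(tab2, k = 8, folds = folds)
  expect_length(rs$selected, 8)
  expect_setequal(head(rs$selected, 3), c("LogP", "MW", "GATS1p"))
  expect_equal(dim(rs$fold_scores), c(10, 8))

  expect_error(rank_select(tab2, k = 9, folds = folds), "exceeds")
  no_y <- compound_table(tab$ids, tab$X)
  expect_error(rank_select(no_y, k = 2, folds = folds), "target")
})

test_that("standardization is leakage-safe and exact", {
  tab <- gen_table(100, seed = 5)
  st <- standardize(tab)
  expect_equal(unname(colMeans(st$table$X)), rep(0, 8), tolerance = 1e-9)
  expect_equal(unname(apply(st$table$X, 2, sd)), rep(1, 8), tolerance = 1e-9)

  # a row equal to the training mean maps to the zero vector
  mrow <- matrix(st$scaler$center, 1, dimnames = list(NULL, colnames(tab$X)))
  expect_equal(unname(drop(apply_scaler(st$scaler, mrow))), rep(0, 8))

  # rows outside the training range extrapolate without clipping
  far <- matrix(st$scaler$center + 10 * st$scaler$scale, 1,
                dimnames = list(NULL, colnames(tab$X)))
  expect_equal(unname(drop(apply_scaler(st$scaler, far))), rep(10, 8))

  # scaler parameters depend on training rows only
  other <- gen_table(50, seed = 99)
  st2 <- standardize(tab, other)
  expect_identical(st2$scaler, st$scaler)

  zero <- compound_table(c("a", "b"), cbind(k = c(1, 1)))
  expect_error(fit_scaler(zero), "filter_low_variance")
})

test_that("preprocess_chain composes filters and reports consistently", {
  set.seed(11)
  tab <- gen_table(300, seed = 31)
  X <- cbind(tab$X, dup_LogP = tab$X[, "LogP"], const = 7)
  big <- compound_table(tab$ids, X, tab$y)
  folds <- kfold_plan(300, 5, seed = 1)
  out <- preprocess_chain(big, k = 8, folds = folds)
  expect_true("const" %in% out$report$dropped_low_variance)
  expect_true("dup_LogP" %in% out$report$dropped_correlated$dropped)
  expect_length(out$report$selected, 8)
  expect_false(any(out$report$selected %in%
                     c(out$report$dropped_low_variance,
                       out$report$dropped_correlated$dropped)))
})
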