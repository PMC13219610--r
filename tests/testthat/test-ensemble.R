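test_that("inverse-RMSE weights match hand arithmetic and invariances", {
  expect_equal(unname(ensemble_weights(c(a = 0.3, b = 0.3))), c(0.5, 0.5))
  expect_equal(unname(ensemble_weights(c(a = 0.2, b = 0.4))), c(2, 1) / 3)
  expect_equal(unname(ensemble_weights(c(a = 0.4))), 1)
  expect_equal(ensemble_weights(c(a = 0.2, b = 0.4) * 10),
               ensemble_weights(c(a = 0.2, b = 0.4)))
  expect_error(ensemble_weights(c(a = 0, b = 1)), "> 0")
})

test_that("mixture aggregation is exact for identical members and inflates on disagreement", {
  set.seed(41)
  y <- rnorm(30, 3)
  mu <- y + rnorm(30, 0, 0.3)
  sig <- runif(30, 0.2, 0.5)
  mem <- prediction_set(y, mu, mu - 1.96 * sig, mu + 1.96 * sig, sig)
  ens <- ensemble_predict(list(mem, mem), c(0.5, 0.5))
  expect_equal(ens$y_hat, mem$y_hat)
  expect_equal(ens$sigma, mem$sigma, tolerance = 1e-12)

  mu2 <- mu + 0.5
  mem2 <- prediction_set(y, mu2, mu2 - 1.96 * sig, mu2 + 1.96 * sig, sig)
  ens2 <- ensemble_predict(list(mem, mem2), c(0.5, 0.5))
  expect_true(all(ens2$sigma > mem$sigma))   # law of total variance

  bad <- prediction_set(y + 1, mu, sigma = sig)
  expect_error(ensemble_predict(list(mem, bad)), "aligned")
  nos <- prediction_set(y, mu)
  expect_error(ensemble_predict(list(mem, nos)), "sigma")
})

test_that("mixture variance formula matches brute-force Monte Carlo", {
  set.seed(42)
  for (rep in 1:5) {
    k <- sample(2:4, 1)
    y <- rnorm(3, 3)
    mus <- lapply(1:k, function(i) y + rnorm(3, 0, 0.5))
    sigs <- lapply(1:k, function(i) runif(3, 0.3, 1))
    w <- ensemble_weights(setNames(runif(k, 0.2, 0.6), paste0("m", 1:k)))
    members <- lapply(1:k, function(i)
      prediction_set(y, mus[[i]], sigma = sigs[[i]],
                     lower = mus[[i]] - 3 * sigs[[i]],
                     upper = mus[[i]] + 3 * sigs[[i]]))
    ens <- ensemble_predict(members, w)
    # oracle: sample the mixture directly
    S <- 4e5
    comp <- sample.int(k, S, replace = TRUE, prob = w)
    for (row in 1:3) {
      draws <- rnorm(S, unlist(lapply(mus, `[`, row))[comp],
                     unlist(lapply(sigs, `[`, row))[comp])
      expect_equal(mean(draws), ens$y_hat[row], tolerance = 0.01)
      expect_equal(sd(draws), ens$sigma[row], tolerance = 0.01)
    }
  }
})

test_that("ensembling PC-GBM and BNN preserves coverage on generator data", {
  ok <- vapply(1:3, function(s) {
    tab <- gen_table(600, seed = 80 + s)
    tr <- 1:400; te <- 401:600
    st <- standardize(table_subset(tab, tr), table_subset(tab, te))
    gb <- fit_pcgbm(tab$X[tr, ], tab$y[tr], small_gbm(seed = s))
    folds <- kfold_plan(400, 5, seed = s)
    oof <- rep(NA_real_, 400)
    for (f in 1:5) {
      fi <- folds$fold_assignments == f
      mf <- fit_pcgbm(tab$X[tr, ][!fi, ], tab$y[tr][!fi], small_gbm(seed = s))
      oof[fi] <- predict(mf, tab$X[tr, ][fi, ])
    }
    ps_g <- conformal_intervals(tab$y[te], predict(gb, tab$X[te, ]),
                                abs(tab$y[tr] - oof))
    bn <- fit_bnn(standardize(table_subset(tab, tr))$table$X, tab$y[tr],
                  small_bnn(seed = s))
    ps_b <- predict_dist(bn, st$table$X, y = tab$y[te], S = 50, seed = s)
    w <- ensemble_weights(c(gbm = point_metrics(ps_g)$rmse,
                            bnn = point_metrics(ps_b)$rmse))
    ens <- ensemble_predict(list(ps_g, ps_b), w)
    cov_m <- vapply(list(ps_g, ps_b), function(p)
      interval_metrics(p)$coverage, 0)
    interval_metrics(ens)$coverage >= max(cov_m) - 0.02
  }, TRUE)
  expect_gte(sum(ok), 2)   # qualitative coverage-preservation, 3 seeds
})
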