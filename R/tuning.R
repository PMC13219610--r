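## Seeded sequential model-based hyperparameter optimization over the
## published search ranges, minimizing a composite accuracy/reliability loss
## (point error + under-coverage hinge + interval width) averaged across CV
## folds.  Surrogate: Gaussian-process regression with an RBF kernel and
## expected-improvement acquisition over random candidate draws.

#' Composite accuracy-reliability loss
#'
#' `L = RMSE + lambda1 * max(0, nominal - coverage) + lambda2 * PI`.
#' Under-coverage is penalized through a hinge (no reward for over-coverage);
#' interval width enters linearly so sharper calibrated models win.
#'
#' @param point a [point_metrics()] result.
#' @param interval an [interval_metrics()] result.
#' @param lambda1 under-coverage penalty weight (default 1.0).
#' @param lambda2 width penalty weight (default 0.5).
#' @param nominal nominal coverage (default 0.95).
#' @return numeric scalar.
#' @export
composite_loss <- function(point, interval, lambda1 = 1.0, lambda2 = 0.5,
                           nominal = 0.95) {
  if (lambda1 < 0 || lambda2 < 0) stop_tox("lambda weights must be >= 0")
  if (!is.finite(point$rmse) || !is.finite(interval$coverage) ||
      !is.finite(interval$pi))
    stop_tox("composite_loss requires finite metrics")
  point$rmse + lambda1 * max(0, nominal - interval$coverage) +
    lambda2 * interval$pi
}

#' Published PC-GBM search space
#'
#' @return list of parameter definitions (name, type, lower, upper).
#' @export
gbm_search_space <- function() {
  list(
    list(name = "max_depth", type = "int", lower = 5, upper = 7),
    list(name = "learning_rate", type = "real", lower = 0.03, upper = 0.06),
    list(name = "n_estimators", type = "int", lower = 250, upper = 400),
    list(name = "subsample", type = "real", lower = 0.7, upper = 0.9),
    list(name = "l1", type = "real", lower = 0.1, upper = 0.3),
    list(name = "l2", type = "real", lower = 0.5, upper = 1.0))
}

#' BNN search space (learning rate around 1e-3, patience, MC samples)
#'
#' @return list of parameter definitions.
#' @export
bnn_search_space <- function() {
  list(
    list(name = "learn_rate", type = "real", lower = 3e-4, upper = 3e-3),
    list(name = "patience", type = "int", lower = 10, upper = 40),
    list(name = "mc_samples", type = "int", lower = 50, upper = 200))
}

space_sample <- function(space) {
  cfg <- lapply(space, function(p) {
    if (p$type == "int") sample(seq(p$lower, p$upper), 1)
    else runif(1, p$lower, p$upper)
  })
  names(cfg) <- vapply(space, `[[`, "", "name")
  cfg
}

space_scale01 <- function(space, cfg) {
  vapply(space, function(p)
    (cfg[[p$name]] - p$lower) / (p$upper - p$lower), 0)
}

## minimal RBF-kernel GP posterior for EI
gp_ei <- function(Xo, z, Xc, ell = 0.3, nugget = 1e-6) {
  sqd <- function(A, B) {
    an <- rowSums(A^2); bn <- rowSums(B^2)
    pmax(outer(an, bn, "+") - 2 * tcrossprod(A, B), 0)
  }
  s2 <- max(var(z), 1e-12)
  K <- s2 * exp(-0.5 * sqd(Xo, Xo) / ell^2) + diag(nugget + 1e-10, nrow(Xo))
  Ks <- s2 * exp(-0.5 * sqd(Xc, Xo) / ell^2)
  L <- chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), z - mean(z)))
  mu <- mean(z) + Ks %*% alpha
  v <- backsolve(L, forwardsolve(t(L), t(Ks)), k = nrow(Xo))
  var_c <- pmax(s2 - colSums(v^2), 0)
  sd_c <- sqrt(var_c)
  best <- min(z)
  imp <- best - mu
  ei <- ifelse(sd_c > 0,
               imp * pnorm(imp / sd_c) + sd_c * dnorm(imp / sd_c),
               pmax(imp, 0))
  as.numeric(ei)
}

#' Sequential surrogate-guided hyperparameter optimization
#'
#' Scores each candidate configuration by the mean [composite_loss()] across
#' the supplied CV folds (a factory failure marks the configuration with
#' `+Inf` loss and the search continues).  The first third of the budget is
#' random exploration; remaining evaluations maximize expected improvement
#' under a GP surrogate over 500 random candidates.  Fully deterministic per
#' `(seed, budget, space)`.
#'
#' @param factory function `(config) -> list(fit = function(X, y) model,
#'   predict_ps = function(model, X, y) prediction_set)` producing interval
#'   predictions.
#' @param space search space (e.g. [gbm_search_space()]).
#' @param X,y training data.
#' @param folds a [kfold_plan()].
#' @param budget number of evaluations (>= 5).
#' @param seed integer seed.
#' @param lambda1,lambda2,nominal composite-loss parameters.
#' @return list of class `tune_result`: `best_config`, `best_loss`,
#'   `history` (data.frame with per-config loss), `configs`.
#' @export
tune_model <- function(factory, space, X, y, folds, budget = 30, seed = 1L,
                       lambda1 = 1.0, lambda2 = 0.5, nominal = 0.95) {
  if (budget < 5) stop_tox("budget must be >= 5")
  X <- if (inherits(X, "compound_table")) X$X else as.matrix(X)
  k <- folds$k

  score_config <- function(cfg) {
    member <- tryCatch(factory(cfg), error = function(e) NULL)
    if (is.null(member)) return(Inf)
    losses <- numeric(k)
    for (f in seq_len(k)) {
      tr <- folds$fold_assignments != f
      res <- tryCatch({
        model <- member$fit(X[tr, , drop = FALSE], y[tr])
        ps <- member$predict_ps(model, X[!tr, , drop = FALSE], y[!tr])
        composite_loss(point_metrics(ps), interval_metrics(ps, nominal),
                       lambda1, lambda2, nominal)
      }, error = function(e) Inf)
      losses[f] <- res
    }
    mean(losses)
  }

  n_init <- max(5L, budget %/% 3L)
  configs <- vector("list", budget)
  losses <- numeric(budget)
  for (i in seq_len(budget)) {
    cfg <- if (i <= n_init) {
      with_seed(derive_seed(seed, i), space_sample(space))
    } else {
      with_seed(derive_seed(seed, 1000L + i), {
        cand <- lapply(seq_len(500), function(j) space_sample(space))
        done <- is.finite(losses[seq_len(i - 1)])
        if (sum(done) >= 2) {
          Xo <- t(vapply(configs[seq_len(i - 1)][done], space_scale01,
                         numeric(length(space)), space = space))
          Xc <- t(vapply(cand, space_scale01, numeric(length(space)),
                         space = space))
          ei <- gp_ei(Xo, losses[seq_len(i - 1)][done], Xc)
          cand[[which.max(ei)]]
        } else cand[[1]]
      })
    }
    configs[[i]] <- cfg
    losses[i] <- score_config(cfg)
  }

  best <- which.min(losses)   # first minimum wins ties (evaluation order)
  history <- data.frame(eval = seq_len(budget), loss = losses)
  for (p in space)
    history[[p$name]] <- vapply(configs, function(cfg) cfg[[p$name]], 0)
  structure(list(best_config = configs[[best]], best_loss = losses[best],
                 history = history, configs = configs, seed = seed),
            class = "tune_result")
}

#' Tuning factory for the PC-GBM (conformal intervals from training residuals)
#'
#' @param constraints monotone-constraint map for the descriptor layout.
#' @param level interval level.
#' @param base_config baseline [gbm_config()] supplying untuned fields.
#' @return factory function for [tune_model()].
#' @export
gbm_tune_factory <- function(constraints = constraint_map(), level = 0.95,
                             base_config = gbm_config()) {
  function(cfg) {
    full <- base_config
    for (nm in names(cfg)) full[[nm]] <- cfg[[nm]]
    full$n_estimators <- as.integer(full$n_estimators)
    full$max_depth <- as.integer(full$max_depth)
    full$constraints <- constraints
    list(
      fit = function(X, y) {
        m <- fit_pcgbm(X, y, full)
        m$calib_resid <- abs(y - m$train_pred)
        m
      },
      predict_ps = function(model, X, y) {
        conformal_intervals(y, predict(model, X), model$calib_resid, level)
      })
  }
}

#' Tuning factory for the BNN
#'
#' @param level interval level.
#' @param base_config baseline [bnn_config()].
#' @return factory function for [tune_model()].
#' @export
bnn_tune_factory <- function(level = 0.95, base_config = bnn_config()) {
  function(cfg) {
    full <- base_config
    for (nm in names(cfg)) full[[nm]] <- cfg[[nm]]
    full$patience <- as.integer(full$patience)
    full$mc_samples <- as.integer(max(full$mc_samples, 10))
    list(
      fit = function(X, y) fit_bnn(X, y, full),
      predict_ps = function(model, X, y)
        predict_dist(model, X, y = y, level = level))
  }
}
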