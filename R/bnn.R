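## Mean-field variational Bayesian neural network regressor.  Gaussian
## variational posteriors over every weight/bias, Gaussian priors with
## variance 1/fan-in, reparameterized stochastic gradients of the ELBO
## (expected Gaussian log-likelihood minus KL), Adam updates, early stopping
## on an internal validation split.  A homoscedastic observation noise SD is
## learned on the log scale.

softplus <- function(x) log1p(exp(-abs(x))) + pmax(x, 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

#' BNN configuration
#'
#' Defaults mirror the published optimal architecture: hidden layers (32, 16),
#' ReLU activations, zero-mean Gaussian priors with variance scaled inversely
#' to layer fan-in, Adam at learning rate 1e-3, early stopping on validation
#' loss.
#'
#' @param hidden integer vector of hidden layer widths.
#' @param learn_rate Adam learning rate.
#' @param max_epochs maximum training epochs.
#' @param patience epochs without validation improvement before stopping.
#' @param batch_size minibatch size.
#' @param mc_samples default number of posterior draws for prediction.
#' @param interval_level central interval level in (0, 1).
#' @param val_fraction internal early-stopping split fraction.
#' @param seed integer seed.
#' @return object of class `bnn_config`.
#' @export
bnn_config <- function(hidden = c(32, 16), learn_rate = 1e-3,
                       max_epochs = 400, patience = 30, batch_size = 64,
                       mc_samples = 200, interval_level = 0.95,
                       val_fraction = 0.1, seed = 1L) {
  stopifnot(interval_level > 0, interval_level < 1, mc_samples >= 10,
            all(hidden >= 1), learn_rate > 0, patience >= 1)
  structure(list(hidden = as.integer(hidden), learn_rate = learn_rate,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size),
                 mc_samples = as.integer(mc_samples),
                 interval_level = interval_level,
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "bnn_config")
}

bnn_init <- function(d_in, hidden) {
  sizes <- c(d_in, hidden, 1L)
  rho0 <- log(expm1(0.05))   # initial variational SD 0.05
  layers <- vector("list", length(sizes) - 1L)
  for (l in seq_along(layers)) {
    fan_in <- sizes[l]
    layers[[l]] <- list(
      mu_w = matrix(rnorm(fan_in * sizes[l + 1], 0, sqrt(1 / fan_in)),
                    fan_in, sizes[l + 1]),
      rho_w = matrix(rho0, fan_in, sizes[l + 1]),
      mu_b = numeric(sizes[l + 1]),
      rho_b = rep(rho0, sizes[l + 1]),
      prior_var_w = 1 / fan_in,   # "variance scaled to layer size"
      prior_var_b = 1)
  }
  layers
}

bnn_sample_weights <- function(layers) {
  lapply(layers, function(ly) {
    ew <- matrix(rnorm(length(ly$mu_w)), nrow(ly$mu_w))
    eb <- rnorm(length(ly$mu_b))
    list(W = ly$mu_w + softplus(ly$rho_w) * ew,
         b = ly$mu_b + softplus(ly$rho_b) * eb,
         eps_w = ew, eps_b = eb)
  })
}

bnn_forward <- function(wts, X) {
  a <- X
  zs <- as <- vector("list", length(wts))
  for (l in seq_along(wts)) {
    z <- a %*% wts[[l]]$W
    z <- sweep(z, 2, wts[[l]]$b, "+")
    zs[[l]] <- z
    a <- if (l < length(wts)) pmax(z, 0) else z
    as[[l]] <- a
  }
  list(out = drop(a), zs = zs, as = as)
}

bnn_mean_forward <- function(layers, X) {
  wts <- lapply(layers, function(ly) list(W = ly$mu_w, b = ly$mu_b))
  bnn_forward(wts, X)$out
}

bnn_kl <- function(layers) {
  kl_part <- function(mu, rho, pv) {
    s2 <- softplus(rho)^2
    sum(0.5 * (log(pv / s2) + (s2 + mu^2) / pv - 1))
  }
  sum(vapply(layers, function(ly)
    kl_part(ly$mu_w, ly$rho_w, ly$prior_var_w) +
      kl_part(ly$mu_b, ly$rho_b, ly$prior_var_b), 0))
}

#' Fit the variational BNN
#'
#' Maximizes the ELBO by reparameterized stochastic gradients (one posterior
#' draw per minibatch, KL divided evenly across the epoch's minibatches) with
#' Adam.  Standardized inputs are recommended.  Training stops early when the
#' internal validation NLL has not improved for `patience` epochs; the best
#' parameters are restored.
#'
#' @param X numeric matrix or [compound_table()] (n >= 20).
#' @param y response (taken from the table when omitted).
#' @param config a [bnn_config()].
#' @return object of class `bnn_model` (variational parameters, learned
#'   observation SD `sigma_y`, per-epoch ELBO trace).
#' @export
fit_bnn <- function(X, y = NULL, config = bnn_config()) {
  if (inherits(X, "compound_table")) { if (is.null(y)) y <- X$y; X <- X$X }
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (n < 20) stop_tox("fit_bnn requires n >= 20")

  with_seed(config$seed, {
    n_val <- max(2L, round(config$val_fraction * n))
    val_idx <- sample(n, n_val)
    tr_idx <- setdiff(seq_len(n), val_idx)
    Xtr <- X[tr_idx, , drop = FALSE]; ytr <- y[tr_idx]
    Xva <- X[val_idx, , drop = FALSE]; yva <- y[val_idx]
    ntr <- length(tr_idx)

    layers <- bnn_init(ncol(X), config$hidden)
    log_sig <- log(max(sd(ytr), 0.1))   # floored init keeps gradients sane

    # Adam state mirrors the parameter structure
    zero_like <- function() {
      lapply(layers, function(ly) list(mu_w = ly$mu_w * 0, rho_w = ly$rho_w * 0,
                                       mu_b = ly$mu_b * 0, rho_b = ly$rho_b * 0))
    }
    m_st <- zero_like(); v_st <- zero_like()
    m_sig <- 0; v_sig <- 0
    b1 <- 0.9; b2 <- 0.999; epsA <- 1e-8; lr <- config$learn_rate
    step <- 0L

    bs <- min(config$batch_size, ntr)
    n_batches <- ceiling(ntr / bs)
    elbo_trace <- numeric(0)
    best_val <- Inf; best_state <- NULL; wait <- 0L
    L <- length(layers)

    for (epoch in seq_len(config$max_epochs)) {
      perm <- sample(ntr)
      epoch_nll <- 0
      for (bidx in seq_len(n_batches)) {
        rows <- perm[((bidx - 1) * bs + 1):min(bidx * bs, ntr)]
        Xb <- Xtr[rows, , drop = FALSE]; yb <- ytr[rows]
        mb <- length(rows)
        scale <- ntr / mb          # scale batch likelihood to the full data
        kl_w <- 1 / n_batches      # spread KL across the epoch

        wts <- bnn_sample_weights(layers)
        fw <- bnn_forward(wts, Xb)
        sig2 <- exp(2 * log_sig)
        resid <- fw$out - yb
        nll_b <- 0.5 * mb * log(2 * pi * sig2) + sum(resid^2) / (2 * sig2)
        epoch_nll <- epoch_nll + nll_b

        # backprop of scale * nll through the sampled network
        dz <- matrix(scale * resid / sig2, ncol = 1)
        grads <- vector("list", L)
        for (l in L:1) {
          a_prev <- if (l == 1) Xb else fw$as[[l - 1]]
          gW <- crossprod(a_prev, dz)
          gb <- colSums(dz)
          sw <- softplus(wts_rho <- layers[[l]]$rho_w)  # sd of weights
          sb <- softplus(layers[[l]]$rho_b)
          pvw <- layers[[l]]$prior_var_w; pvb <- layers[[l]]$prior_var_b
          grads[[l]] <- list(
            mu_w = gW + kl_w * layers[[l]]$mu_w / pvw,
            rho_w = gW * wts[[l]]$eps_w * sigmoid(wts_rho) +
              kl_w * (-1 / sw + sw / pvw) * sigmoid(wts_rho),
            mu_b = gb + kl_w * layers[[l]]$mu_b / pvb,
            rho_b = gb * wts[[l]]$eps_b * sigmoid(layers[[l]]$rho_b) +
              kl_w * (-1 / sb + sb / pvb) * sigmoid(layers[[l]]$rho_b))
          if (l > 1) {
            da <- dz %*% t(wts[[l]]$W)
            dz <- da * (fw$zs[[l - 1]] > 0)
          }
        }
        g_sig <- scale * (mb - sum(resid^2) / sig2)

        if (!all(vapply(grads, function(g) all(vapply(g, function(v)
          all(is.finite(v)), TRUE)), TRUE)) || !is.finite(g_sig))
          stop_tox("BNN training diverged (non-finite gradient) at epoch %d",
                   epoch)

        step <- step + 1L
        corr <- lr * sqrt(1 - b2^step) / (1 - b1^step)
        for (l in seq_len(L)) {
          for (nm in c("mu_w", "rho_w", "mu_b", "rho_b")) {
            g <- grads[[l]][[nm]]
            m_st[[l]][[nm]] <- b1 * m_st[[l]][[nm]] + (1 - b1) * g
            v_st[[l]][[nm]] <- b2 * v_st[[l]][[nm]] + (1 - b2) * g^2
            layers[[l]][[nm]] <- layers[[l]][[nm]] -
              corr * m_st[[l]][[nm]] / (sqrt(v_st[[l]][[nm]]) + epsA)
          }
        }
        m_sig <- b1 * m_sig + (1 - b1) * g_sig
        v_sig <- b2 * v_sig + (1 - b2) * g_sig^2
        log_sig <- log_sig - corr * m_sig / (sqrt(v_sig) + epsA)
      }

      kl <- bnn_kl(layers)
      elbo <- -(epoch_nll + kl)
      if (!is.finite(elbo))
        stop_tox("BNN training diverged at epoch %d (last finite epoch %d)",
                 epoch, length(elbo_trace))
      elbo_trace <- c(elbo_trace, elbo)

      # validation NLL with posterior-mean weights
      fva <- bnn_mean_forward(layers, Xva)
      sig2 <- exp(2 * log_sig)
      val_nll <- 0.5 * log(2 * pi * sig2) +
        mean((yva - fva)^2) / (2 * sig2)
      if (val_nll < best_val - 1e-6) {
        best_val <- val_nll
        best_state <- list(layers = rapply(layers, identity, how = "replace"),
                           log_sig = log_sig, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }

    if (!is.null(best_state)) {
      layers <- best_state$layers
      log_sig <- best_state$log_sig
    }
    structure(list(layers = layers, sigma_y = exp(log_sig),
                   elbo_trace = elbo_trace, config = config,
                   feature_names = colnames(X),
                   best_epoch = if (is.null(best_state)) NA_integer_ else
                     best_state$epoch),
              class = "bnn_model")
  })
}

#' @export
print.bnn_model <- function(x, ...) {
  cat(sprintf("<bnn_model> hidden (%s), sigma_y = %.4f, %d epochs\n",
              paste(x$config$hidden, collapse = ", "), x$sigma_y,
              length(x$elbo_trace)))
  invisible(x)
}

#' Posterior-mean point predictions
#'
#' @param object a `bnn_model`.
#' @param newdata matrix or [compound_table()].
#' @param ... unused.
#' @return numeric vector (deterministic forward pass through the variational
#'   means).
#' @export
predict.bnn_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "compound_table")) newdata$X else
    as.matrix(newdata)
  if (ncol(X) != nrow(object$layers[[1]]$mu_w))
    stop_tox("newdata has %d columns; model expects %d", ncol(X),
             nrow(object$layers[[1]]$mu_w))
  bnn_mean_forward(object$layers, X)
}

#' Predictive distribution from the variational posterior
#'
#' Draws `S` weight samples, averages the induced outputs into a Monte Carlo
#' mean and epistemic SD, combines with the learned observation noise into a
#' total predictive SD, and forms Gaussian central intervals.
#'
#' @param model a fitted `bnn_model`.
#' @param newdata matrix or [compound_table()].
#' @param y observed responses for the returned [prediction_set()] (zeros if
#'   unknown).
#' @param S number of posterior draws (>= 2).
#' @param level central interval level.
#' @param seed integer seed for the draws.
#' @return a [prediction_set()] with `y_hat`, `lower`, `upper` and `sigma`.
#' @export
predict_dist <- function(model, newdata, y = NULL, S = model$config$mc_samples,
                         level = model$config$interval_level,
                         seed = model$config$seed) {
  stopifnot(inherits(model, "bnn_model"))
  if (S < 2) stop_tox("S must be >= 2")
  X <- if (inherits(newdata, "compound_table")) newdata$X else
    as.matrix(newdata)
  draws <- with_seed(seed, {
    vapply(seq_len(S), function(s) {
      wts <- bnn_sample_weights(model$layers)
      bnn_forward(wts, X)$out
    }, numeric(nrow(X)))
  })
  if (nrow(X) == 1) draws <- matrix(draws, nrow = 1)
  mu <- rowMeans(draws)
  epi <- apply(draws, 1, sd)
  sig <- sqrt(epi^2 + model$sigma_y^2)
  z <- z_mult(level)
  if (is.null(y)) y <- rep(0, nrow(X))
  prediction_set(y, mu, lower = mu - z * sig, upper = mu + z * sig,
                 sigma = sig)
}
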