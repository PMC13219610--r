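# shared fixtures, built in code and memoized per test run

.fixtures <- new.env(parent = emptyenv())

# calibrated default generator (marginal solves are deterministic)
calib_config <- function() {
  if (is.null(.fixtures$cfg))
    .fixtures$cfg <- calibrate_generator(generator_config())
  .fixtures$cfg
}

gen_table <- function(n, seed) generate_compounds(calib_config(), n, seed)

# small, fast PC-GBM configuration for tests that only need a working model
small_gbm <- function(..., constraints = constraint_map()) {
  args <- utils::modifyList(list(n_estimators = 80, max_depth = 4,
                                 constraints = constraints), list(...))
  do.call(gbm_config, args)
}

# small BNN configuration
small_bnn <- function(...) {
  args <- utils::modifyList(list(max_epochs = 80, patience = 15,
                                 mc_samples = 50), list(...))
  do.call(bnn_config, args)
}

r2_of <- function(y, p) 1 - sum((y - p)^2) / sum((y - mean(y))^2)

random_prediction_set <- function(n = 50) {
  y <- rnorm(n, 3, 1)
  y_hat <- y + rnorm(n, 0, 0.5)
  sigma <- runif(n, 0.2, 1)
  prediction_set(y, y_hat, lower = y_hat - 2 * sigma,
                 upper = y_hat + 2 * sigma, sigma = sigma)
}

make_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
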