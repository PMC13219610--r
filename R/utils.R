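#' Derive a stage-specific sub-seed from a global seed
#'
#' A single pipeline seed fans out to per-stage seeds through this counter
#' scheme so any stage can be re-run in isolation and reproduce its in-pipeline
#' behaviour.  Results always lie in `[0, 2^31 - 2]`.
#'
#' @param seed integer global seed.
#' @param offset integer stage counter (>= 0).
#' @return integer sub-seed.
#' @export
derive_seed <- function(seed, offset = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483647
  s <- (abs(as.numeric(seed)) %% m)
  as.integer((s * 48271 + as.numeric(offset) * 7919 + 12345) %% m)
}

## run code under a local RNG state, restoring the caller's stream afterwards
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

stop_tox <- function(...) stop(sprintf(...), call. = FALSE)

## sample-corrected Fisher excess kurtosis (normal -> 0); matches e1071 type 2
sample_kurtosis <- function(x, excess = TRUE, corrected = TRUE) {
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m4 <- mean((x - m)^4)
  if (m2 == 0) return(NaN)
  g2 <- m4 / m2^2 - 3
  k <- if (corrected && n > 3) {
    ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
  } else {
    g2
  }
  if (excess) k else k + 3
}

sample_skewness <- function(x, corrected = TRUE) {
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  if (m2 == 0) return(NaN)
  g1 <- m3 / m2^1.5
  if (corrected && n > 2) g1 * sqrt(n * (n - 1)) / (n - 2) else g1
}

## D'Agostino-Pearson K^2 omnibus normality test (skewness + kurtosis)
dagostino_k2 <- function(x) {
  n <- length(x)
  if (n < 20) stop_tox("normality test requires n >= 20 (got %d)", n)
  m <- mean(x); xc <- x - m
  m2 <- mean(xc^2); m3 <- mean(xc^3); m4 <- mean(xc^4)
  g1 <- m3 / m2^1.5
  g2 <- m4 / m2^2
  # skewness component (D'Agostino 1970)
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (b2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
  # kurtosis component (Anscombe & Glynn 1983)
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (g2 - eb2) / sqrt(vb2)
  sb2 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sb2 * (2 / sb2 + sqrt(1 + 4 / sb2^2))
  z2 <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + xk * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))
  k2 <- z1^2 + z2^2
  list(statistic = k2, p_value = pchisq(k2, df = 2, lower.tail = FALSE))
}

## normal quantile multiplier for a central interval at `level`
z_mult <- function(level) qnorm((1 + level) / 2)

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}
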