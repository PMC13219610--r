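## Data partitioning: cluster-aware train/test splitting (PCA -> k-means ->
## whole clusters to test, then exact-count rebalancing), k-fold CV planning,
## and label permutation for Y-scrambling.

#' Cluster-aware train/test split
#'
#' Standardizes the descriptor matrix, projects onto principal components
#' (enough to reach 95% variance, capped at 8, unless given), k-means clusters
#' the scores (seeded multi-start, best inertia, ties to the lowest start
#' index), then assigns entire clusters to the test set smallest-first until
#' the test set reaches `round(frac * n)` rows.  Because whole clusters rarely
#' hit the exact count, boundary compounds closest to the opposite set's
#' centroid are then transferred until `|test| == round(frac * n)` exactly;
#' the number of transfers is recorded.
#'
#' @param X numeric matrix of descriptors.
#' @param frac test fraction in (0, 1); default 0.2.
#' @param n_clusters number of k-means clusters (default 10).
#' @param n_pcs number of principal components (`NULL`: 95% variance, cap 8).
#' @param seed integer seed.
#' @return object of class `split_plan` with `train_idx`, `test_idx`,
#'   `cluster_labels`, `clusters_in_test`, `rebalanced_count`, `seed`.
#' @export
cluster_aware_split <- function(X, frac = 0.2, n_clusters = 10, n_pcs = NULL,
                                seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (!(frac > 0 && frac < 1)) stop_tox("frac must be in (0, 1)")
  if (n_clusters < 2 || n_clusters > n)
    stop_tox("need n >= n_clusters >= 2 (n = %d, n_clusters = %d)",
             n, n_clusters)
  sds <- apply(X, 2, sd)
  if (all(sds == 0)) stop_tox("all rows identical: cannot cluster")
  Z <- scale(X[, sds > 0, drop = FALSE])
  pc <- prcomp(Z, center = FALSE, scale. = FALSE)
  if (is.null(n_pcs)) {
    cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
    n_pcs <- min(which(cum >= 0.95)[1], 8L, ncol(pc$x))
  }
  S <- pc$x[, seq_len(n_pcs), drop = FALSE]

  km <- with_seed(seed, {
    best <- NULL
    for (i in 1:10) {   # seeded multi-start, keep lowest inertia
      fit <- tryCatch(kmeans(S, centers = n_clusters, iter.max = 100),
                      error = function(e) NULL)
      if (!is.null(fit) &&
          (is.null(best) || fit$tot.withinss < best$tot.withinss - 1e-12))
        best <- fit
    }
    if (is.null(best)) stop_tox("k-means failed on degenerate input")
    best
  })
  labels <- km$cluster

  target <- round(frac * n)
  sizes <- table(labels)
  ord <- as.integer(names(sort(sizes)))   # smallest clusters first
  test_clusters <- integer(0)
  count <- 0L
  for (cl in ord) {
    if (count >= target) break
    test_clusters <- c(test_clusters, cl)
    count <- count + sum(labels == cl)
  }
  in_test <- labels %in% test_clusters

  # exact-count rebalancing: move boundary compounds nearest the opposite
  # set's centroid (in PC space) until the test count is exact
  rebalanced <- 0L
  excess <- sum(in_test) - target
  if (excess > 0) {
    train_centroid <- colMeans(S[!in_test, , drop = FALSE])
    d <- sqrt(rowSums(sweep(S, 2, train_centroid)^2))
    move <- order(ifelse(in_test, d, Inf))[seq_len(excess)]
    in_test[move] <- FALSE
    rebalanced <- excess
  } else if (excess < 0) {
    test_centroid <- colMeans(S[in_test, , drop = FALSE])
    d <- sqrt(rowSums(sweep(S, 2, test_centroid)^2))
    move <- order(ifelse(in_test, Inf, d))[seq_len(-excess)]
    in_test[move] <- TRUE
    rebalanced <- -excess
  }

  structure(list(train_idx = which(!in_test), test_idx = which(in_test),
                 cluster_labels = labels, clusters_in_test = test_clusters,
                 rebalanced_count = as.integer(rebalanced),
                 n_pcs = n_pcs, seed = as.integer(seed)),
            class = "split_plan")
}

#' Plan balanced k-fold cross-validation
#'
#' Seeded random assignment with fold sizes differing by at most one.
#'
#' @param n number of rows.
#' @param k number of folds (default 10).
#' @param seed integer seed.
#' @return object of class `kfold_plan` with `fold_assignments` (values in
#'   `1..k`) and `seed`.
#' @export
kfold_plan <- function(n, k = 10, seed = 1L) {
  if (k > n) stop_tox("k (%d) exceeds n (%d)", k, n)
  if (k < 2) stop_tox("k must be >= 2")
  assign <- with_seed(seed, sample(rep(seq_len(k), length.out = n)))
  structure(list(fold_assignments = assign, k = as.integer(k),
                 seed = as.integer(seed)),
            class = "kfold_plan")
}

#' Generate permuted label vectors for Y-scrambling
#'
#' @param y response vector.
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed.
#' @return list of `n_perm` independent uniform permutations of `y`.
#' @export
yscramble_labels <- function(y, n_perm, seed = 1L) {
  if (n_perm < 1) stop_tox("n_perm must be >= 1")
  with_seed(seed, lapply(seq_len(n_perm), function(i) sample(y)))
}
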