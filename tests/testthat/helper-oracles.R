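# Independent brute-force oracles: eigen-decomposition based PCA
# reconstruction and feature scoring, written without reference to the
# package's svd code path.

oracle_pca_reconstruct <- function(X, k) {
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr, "-")
  C <- crossprod(Xc) / (nrow(X) - 1)
  eg <- eigen(C, symmetric = TRUE)
  k <- min(k, sum(eg$values > max(eg$values) * 1e-12), ncol(X), nrow(X) - 1)
  V <- eg$vectors[, seq_len(k), drop = FALSE]
  sweep(Xc %*% V %*% t(V), 2L, ctr, "+")
}

oracle_feature_errors <- function(X, Xhat, aggregation) {
  r <- (X - Xhat)^2
  if (aggregation == "sum") apply(r, 2, sum) else apply(r, 2, mean)
}

# Brute-force ClearF scores on the raw scale (no standardisation).
oracle_scores <- function(X, y, k, aggregation) {
  err_all <- oracle_feature_errors(X, oracle_pca_reconstruct(X, k), aggregation)
  err_cls <- 0
  for (cl in sort(unique(y))) {
    Xc <- X[y == cl, , drop = FALSE]
    err_cls <- err_cls +
      oracle_feature_errors(Xc, oracle_pca_reconstruct(Xc, k), aggregation)
  }
  unname(err_all - err_cls)
}

# Sample-covariance eigenvalues, for the residual identity checks.
cov_eigenvalues <- function(X) {
  eigen(stats::cov(X), symmetric = TRUE, only.values = TRUE)$values
}

random_dataset <- function(n, p, n_classes = 2L, seed = 1L) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  y <- rep(paste0("c", seq_len(n_classes)), length.out = n)
  labeled_dataset(X, y)
}
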