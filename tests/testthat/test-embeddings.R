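test_that("full-rank and collinear data reconstruct exactly under linear PCA", {
  set.seed(1)
  X <- matrix(rnorm(18), 6, 3)
  fr <- fit_reconstruct(X, embedding_spec("pca", 3))
  expect_lt(max(abs(fr$Xhat - X)), 1e-8)

  # rows on a line through the centroid: rank-1 data, k = 1 is exact
  t <- seq(-2, 3, length.out = 5)
  L <- cbind(1 + 2 * t, -1 + 0.5 * t, 3 - t)
  fr1 <- fit_reconstruct(L, embedding_spec("pca", 1))
  expect_lt(max(abs(fr1$Xhat - L)), 1e-8)
  expect_identical(fr1$fitted$effective_components, 1L)
})

test_that("rank-k reconstruction matches the eigen-decomposition oracle", {
  X <- matrix(c(0, 1, 2, 3, 0, 1, 2, 5), 4, 2)
  fr <- fit_reconstruct(X, embedding_spec("pca", 1))
  expect_equal(fr$Xhat, oracle_pca_reconstruct(X, 1),
               ignore_attr = TRUE, tolerance = 1e-10)
  for (seed in 1:5) {
    set.seed(seed)
    Xr <- matrix(rnorm(60), 12, 5)
    k <- sample(1:4, 1)
    fr <- fit_reconstruct(Xr, embedding_spec("pca", k))
    expect_equal(fr$Xhat, oracle_pca_reconstruct(Xr, k), tolerance = 1e-8)
  }
})

test_that("total squared error is elementwise arithmetic with shape guard", {
  X <- matrix(c(1, 3, 2, 4), 2, 2)
  Xhat <- matrix(c(1, 3, 0, 3), 2, 2)
  expect_equal(total_squared_error(X, Xhat), 5)
  expect_equal(total_squared_error(X, X), 0)
  expect_error(total_squared_error(X, matrix(0, 3, 2)),
               class = "clearf_shape_mismatch")
})

test_that("linear PCA residual equals (n-1) times the discarded eigenvalues", {
  for (seed in 1:6) {
    set.seed(seed)
    X <- matrix(rnorm(40 * 7), 40, 7)
    lam <- cov_eigenvalues(X)
    for (k in c(1, 3, 6)) {
      fr <- fit_reconstruct(X, embedding_spec("pca", k))
      expect_equal(total_squared_error(X, fr$Xhat),
                   (nrow(X) - 1) * sum(lam[-seq_len(k)]),
                   tolerance = 1e-8)
    }
  }
})

test_that("reconstruction error is non-increasing in the component count", {
  for (seed in 1:4) {
    set.seed(seed)
    X <- matrix(rnorm(15 * 6), 15, 6)
    errs <- vapply(1:6, function(k) {
      total_squared_error(X, fit_reconstruct(X, embedding_spec("pca", k))$Xhat)
    }, numeric(1))
    expect_true(all(diff(errs) <= 1e-10))
  }
})

test_that("permuting feature columns permutes the reconstruction identically", {
  set.seed(9)
  X <- matrix(rnorm(20 * 5), 20, 5)
  perm <- c(4, 1, 5, 2, 3)
  for (m in c("pca", "kpca-rbf", "kpca-poly")) {
    spec <- embedding_spec(m, 2)
    a <- fit_reconstruct(X, spec)$Xhat[, perm]
    b <- fit_reconstruct(X[, perm], spec)$Xhat
    tol <- if (m == "pca") 1e-10 else 1e-6
    expect_equal(a, b, tolerance = tol, ignore_attr = TRUE)
  }
})

test_that("kernel pre-image error stays within 10x the linear error on structured data", {
  set.seed(5)
  t <- rnorm(40)
  X <- cbind(t, 2 * t, -t) + matrix(rnorm(120, sd = 0.5), 40, 3)
  lin <- total_squared_error(X, fit_reconstruct(X, embedding_spec("pca", 1))$Xhat)
  for (m in c("kpca-rbf", "kpca-poly")) {
    kerr <- total_squared_error(
      X, fit_reconstruct(X, embedding_spec(m, 1))$Xhat)
    expect_lte(kerr, 10 * lin)
  }
})

test_that("kernel eigensystem agrees with an independent kernel-PCA fit", {
  set.seed(3)
  X <- matrix(rnorm(60), 20, 3)
  spec <- embedding_spec("kpca-rbf", 2)
  gam <- clearf:::resolve_gamma(spec, X)
  kp <- kernlab::kpca(X, kernel = "rbfdot", kpar = list(sigma = gam),
                      features = 2)
  # my centred-kernel eigenvalues are n times kernlab's
  kern <- kernlab::rbfdot(sigma = gam)
  K <- kernlab::kernelMatrix(kern, X)@.Data
  n <- nrow(K); J <- matrix(1 / n, n, n)
  Kc <- K - J %*% K - K %*% J + J %*% K %*% J
  ev <- eigen(Kc, symmetric = TRUE)
  expect_equal(ev$values[1:2] / n, kernlab::eig(kp), tolerance = 1e-6,
               ignore_attr = TRUE)
  # embedded coordinates span the same directions
  Z <- ev$vectors[, 1:2] %*% diag(sqrt(ev$values[1:2]))
  R <- kernlab::rotated(kp)
  expect_equal(abs(cor(Z[, 1], R[, 1])), 1, tolerance = 1e-8)
  expect_equal(abs(cor(Z[, 2], R[, 2])), 1, tolerance = 1e-8)
})

test_that("component requests beyond the feasible maximum are capped", {
  set.seed(2)
  X <- matrix(rnorm(12), 4, 3)
  expect_identical(
    fit_reconstruct(X, embedding_spec("pca", 10))$fitted$effective_components,
    3L)
  expect_lte(
    fit_reconstruct(X, embedding_spec("kpca-rbf", 10))$fitted$effective_components,
    4L)
})

test_that("degenerate inputs raise classed errors", {
  expect_error(fit_reconstruct(matrix(1:3, 1, 3), embedding_spec("pca", 1)),
               class = "clearf_insufficient_samples")
  X <- matrix(rnorm(8), 4, 2); X[1, 1] <- NaN
  expect_error(fit_reconstruct(X, embedding_spec("pca", 1)),
               class = "clearf_non_finite_input")
  expect_error(embedding_spec("pca", 0), class = "clearf_invalid_spec")
})
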