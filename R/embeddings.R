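#' Specify a low-dimensional embedding
#'
#' Describes the embedding backend used for reconstruction-error scoring:
#' linear PCA or kernel PCA with an RBF or polynomial kernel.  The same
#' specification (in particular the same component count) is applied to the
#' pooled dataset and to every class subset, which is what makes the
#' class-wise and whole-data reconstruction errors comparable.
#'
#' @param method One of `"pca"` (linear), `"kpca-rbf"` or `"kpca-poly"`.
#' @param n_components Number of embedding components `k` (positive
#'   integer).  Requested values beyond the feasible maximum of a fitted
#'   subset are capped silently at fit time; see [fit_reconstruct()].
#' @param poly_degree Polynomial kernel degree; the default of 3 matches
#'   the cubic kernel used throughout the benchmark protocol.
#' @param rbf_gamma RBF kernel width gamma in `exp(-gamma * |x - y|^2)`;
#'   `"auto"` uses `1 / (n_features * var(X))`, a scale-free default.
#' @param preimage_ridge Ridge regularisation of the linear pre-image map
#'   that carries kernel embedding coordinates back to input space.
#'
#' @return An object of class `embedding_spec`.
#' @examples
#' embedding_spec("pca", n_components = 2)
#' @export
embedding_spec <- function(method = c("pca", "kpca-rbf", "kpca-poly"),
                           n_components = 1L,
                           poly_degree = 3L,
                           rbf_gamma = "auto",
                           preimage_ridge = 1e-3) {
  method <- match.arg(method)
  n_components <- as.integer(n_components)
  if (is.na(n_components) || n_components < 1L)
    clearf_error("invalid-spec", "n_components must be a positive integer")
  if (!identical(rbf_gamma, "auto") &&
      (!is.numeric(rbf_gamma) || rbf_gamma <= 0))
    clearf_error("invalid-spec", "rbf_gamma must be positive or \"auto\"")
  if (!is.numeric(preimage_ridge) || preimage_ridge < 0)
    clearf_error("invalid-spec", "preimage_ridge must be non-negative")
  structure(list(method = method, n_components = n_components,
                 poly_degree = as.integer(poly_degree),
                 rbf_gamma = rbf_gamma, preimage_ridge = preimage_ridge),
            class = "embedding_spec")
}

#' @export
print.embedding_spec <- function(x, ...) {
  extra <- switch(x$method,
    "kpca-rbf"  = sprintf(", gamma=%s", format(x$rbf_gamma)),
    "kpca-poly" = sprintf(", degree=%d", x$poly_degree),
    "")
  cat(sprintf("embedding_spec: %s, k=%d%s\n", x$method, x$n_components, extra))
  invisible(x)
}

resolve_gamma <- function(spec, X) {
  if (identical(spec$rbf_gamma, "auto")) {
    v <- var(as.vector(X))
    if (!is.finite(v) || v <= 0) v <- 1
    1 / (ncol(X) * v)
  } else spec$rbf_gamma
}

#' Fit an embedding and reconstruct the data
#'
#' Fits the embedding described by `spec` to `X` and maps the embedded
#' coordinates back into the original feature space.  For linear PCA the
#' reconstruction is the usual rank-`k` truncation about the column means.
#' For kernel PCA the data are projected onto the leading `k` kernel
#' principal components and returned to input space through a
#' ridge-regularised linear pre-image map learned on the fit data.
#'
#' The requested component count is capped at the feasible maximum for the
#' data actually fitted: `min(k, n - 1, p)` for linear PCA and the number
#' of positive kernel eigenvalues (at most `n - 1`) for kernel methods.
#' Capping is silent because class subsets encountered during
#' cross-validation are routinely smaller than the component sizes proposed
#' by the candidate rule; the count actually used is recorded in
#' `fitted$effective_components`.
#'
#' @param X Numeric matrix, samples in rows.  At least two rows.
#' @param spec An [embedding_spec()].
#' @return A list with `Xhat` (reconstruction, same shape as `X`) and
#'   `fitted` (a `fitted_embedding` recording the spec, the effective
#'   component count, the sample count and the centering offsets).
#' @examples
#' X <- matrix(rnorm(40), 10, 4)
#' fr <- fit_reconstruct(X, embedding_spec("pca", 2))
#' dim(fr$Xhat)
#' @export
fit_reconstruct <- function(X, spec) {
  X <- as.matrix(X)
  if (nrow(X) < 2L)
    clearf_error("insufficient-samples", "embedding needs at least 2 samples")
  if (anyNA(X) || !all(is.finite(X)))
    clearf_error("non-finite-input", "X contains non-finite values")
  if (!inherits(spec, "embedding_spec"))
    clearf_error("invalid-spec", "spec must be an embedding_spec")
  n <- nrow(X); p <- ncol(X)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr, "-")

  if (spec$method == "pca") {
    k <- min(spec$n_components, n - 1L, p)
    sv <- svd(Xc, nu = k, nv = k)
    Xhat <- if (k == 0L) matrix(0, n, p) else
      sv$u %*% (sv$d[seq_len(k)] * t(sv$v))
    Xhat <- sweep(Xhat, 2L, ctr, "+")
    dimnames(Xhat) <- dimnames(X)
    return(list(Xhat = Xhat,
                fitted = structure(list(spec = spec, effective_components = k,
                                        n_samples_fitted = n, center = ctr),
                                   class = "fitted_embedding")))
  }

  # kernel PCA: kernel matrix via kernlab kernels, double-centred, then the
  # leading eigenvectors give the embedded coordinates
  kern <- switch(spec$method,
    "kpca-rbf"  = kernlab::rbfdot(sigma = resolve_gamma(spec, X)),
    "kpca-poly" = kernlab::polydot(degree = spec$poly_degree,
                                   scale = 1, offset = 1))
  K <- kernlab::kernelMatrix(kern, X)@.Data
  J <- matrix(1 / n, n, n)
  Kc <- K - J %*% K - K %*% J + J %*% K %*% J
  eg <- eigen(Kc, symmetric = TRUE)
  tol <- max(eg$values[1], 0) * 1e-10 + 1e-12
  n_pos <- sum(eg$values > tol)
  k <- min(spec$n_components, n_pos)
  if (k == 0L) {
    Xhat <- sweep(matrix(0, n, p), 2L, ctr, "+")
    dimnames(Xhat) <- dimnames(X)
    return(list(Xhat = Xhat,
                fitted = structure(list(spec = spec, effective_components = 0L,
                                        n_samples_fitted = n, center = ctr),
                                   class = "fitted_embedding")))
  }
  lam <- eg$values[seq_len(k)]
  # embedded coordinates with the conventional kPCA scaling: Z = V sqrt(lambda)
  Z <- eg$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(lam), k)
  # ridge pre-image: linear map from Z to the centred inputs; Z has
  # orthogonal columns so the normal equations are diagonal
  W <- diag(1 / (lam + spec$preimage_ridge), k) %*% crossprod(Z, Xc)
  Xhat <- sweep(Z %*% W, 2L, ctr, "+")
  dimnames(Xhat) <- dimnames(X)
  list(Xhat = Xhat,
       fitted = structure(list(spec = spec, effective_components = k,
                               n_samples_fitted = n, center = ctr),
                          class = "fitted_embedding"))
}

#' Total squared reconstruction error
#'
#' @param X,Xhat Numeric matrices of identical shape.
#' @return The sum over all cells of `(X - Xhat)^2`.
#' @examples
#' total_squared_error(matrix(1:4, 2), matrix(c(1, 3, 0, 3), 2))
#' @export
total_squared_error <- function(X, Xhat) {
  X <- as.matrix(X); Xhat <- as.matrix(Xhat)
  if (!all(dim(X) == dim(Xhat)))
    clearf_error("shape-mismatch", sprintf(
      "X is %dx%d but Xhat is %dx%d", nrow(X), ncol(X), nrow(Xhat), ncol(Xhat)))
  sum((X - Xhat)^2)
}
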