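#' Configure feature scoring
#'
#' @param embedding An [embedding_spec()] shared by the pooled fit and every
#'   class-wise fit.
#' @param aggregation How squared residuals are aggregated over samples into
#'   a per-feature error: `"mean"` (mean squared error, the default used by
#'   the benchmark protocol) or `"sum"`.
#' @param standardize If `TRUE` (default), features are z-scored using the
#'   mean and standard deviation of the *full* dataset before any embedding
#'   is fitted; the identical transform is applied to every class subset so
#'   that class-wise and whole-data errors stay on one scale.  Set `FALSE`
#'   to score on the raw scale.
#'
#' @return An object of class `score_config`.
#' @examples
#' score_config(embedding_spec("pca", 1))
#' @export
score_config <- function(embedding = embedding_spec("pca", 1L),
                         aggregation = c("mean", "sum"),
                         standardize = TRUE) {
  aggregation <- match.arg(aggregation)
  if (!inherits(embedding, "embedding_spec"))
    clearf_error("invalid-spec", "embedding must be an embedding_spec")
  structure(list(embedding = embedding, aggregation = aggregation,
                 standardize = isTRUE(standardize)),
            class = "score_config")
}

#' Per-feature reconstruction errors
#'
#' Decomposes the squared reconstruction residual column-wise: entry `j` is
#' the chosen aggregation over samples of `(X[, j] - Xhat[, j])^2`.  Under
#' `aggregation = "sum"` the entries add up to
#' [total_squared_error()]`(X, Xhat)`.
#'
#' @param X,Xhat Numeric matrices of identical shape.
#' @param aggregation `"mean"` or `"sum"`.
#' @return Named non-negative vector with one entry per feature.
#' @examples
#' feature_errors(matrix(c(1, 3, 2, 4), 2), matrix(c(1, 3, 0, 3), 2), "sum")
#' @export
feature_errors <- function(X, Xhat, aggregation = c("mean", "sum")) {
  aggregation <- match.arg(aggregation)
  X <- as.matrix(X); Xhat <- as.matrix(Xhat)
  if (!all(dim(X) == dim(Xhat)))
    clearf_error("shape-mismatch", sprintf(
      "X is %dx%d but Xhat is %dx%d", nrow(X), ncol(X), nrow(Xhat), ncol(Xhat)))
  R2 <- (X - Xhat)^2
  e <- if (aggregation == "sum") colSums(R2) else colMeans(R2)
  if (!is.null(colnames(X))) names(e) <- colnames(X)
  e
}

#' ClearF feature scores
#'
#' Scores every feature by the difference between its reconstruction error
#' under an embedding fitted to the pooled dataset and the sum of its
#' reconstruction errors under embeddings fitted separately to each class,
#' all with the same component count:
#' `score_j = err_all(j) - sum_c err_c(j)`.
#'
#' The pooled error plays the role of the feature's entropy and the
#' class-wise sum that of its conditional entropy given the label, so the
#' score is a continuous surrogate for the mutual information between the
#' feature and the class.  Features that vary strongly *between* classes
#' are hard to compress pooled but easy to compress per class, and score
#' high; features indifferent to the class score near zero.  Scores can be
#' negative (class-wise structure harder to compress than pooled) and are
#' reported as-is.
#'
#' @param d A validated [labeled_dataset()].
#' @param cfg A [score_config()].
#' @return A `clearf_scores` data frame with columns `feature`, `score` and
#'   `rank` (rank 1 = highest score, ties broken by feature order), rows in
#'   the original feature order.  The per-class effective component counts
#'   are attached as attribute `"effective_components"`.
#' @examples
#' d <- generate_two_class_2d("separated", 100, seed = 1)
#' clearf_scores(d, score_config(embedding_spec("pca", 1)))
#' @export
clearf_scores <- function(d, cfg = score_config()) {
  d <- validate_dataset(d)
  if (!inherits(cfg, "score_config"))
    clearf_error("invalid-spec", "cfg must be a score_config")
  X <- d$X
  if (cfg$standardize) {
    mu <- colMeans(X)
    sdev <- apply(X, 2L, sd)
    sdev[!is.finite(sdev) | sdev <= 0] <- 1
    X <- sweep(sweep(X, 2L, mu, "-"), 2L, sdev, "/")
  }
  fr_all <- fit_reconstruct(X, cfg$embedding)
  err_all <- feature_errors(X, fr_all$Xhat, cfg$aggregation)
  eff <- c(all = fr_all$fitted$effective_components)
  err_cls <- rep(0, ncol(X))
  for (cl in d$classes) {
    Xc <- X[d$y == cl, , drop = FALSE]
    fr_c <- fit_reconstruct(Xc, cfg$embedding)
    err_cls <- err_cls + feature_errors(Xc, fr_c$Xhat, cfg$aggregation)
    eff[cl] <- fr_c$fitted$effective_components
  }
  scores <- unname(err_all - err_cls)
  out <- data.frame(feature = d$feature_names, score = scores,
                    rank = rank_features(scores),
                    stringsAsFactors = FALSE)
  attr(out, "effective_components") <- eff
  attr(out, "aggregation") <- cfg$aggregation
  class(out) <- c("clearf_scores", "data.frame")
  out
}

#' Rank scores, highest first
#'
#' @param scores Finite numeric vector.
#' @return Integer vector of the same length: `ranks[j]` is the rank of
#'   feature `j`, with rank 1 for the highest score and ties broken by
#'   ascending feature index.
#' @examples
#' rank_features(c(0.4, 0.1, 0.4))
#' @export
rank_features <- function(scores) {
  if (!is.numeric(scores) || anyNA(scores) || !all(is.finite(scores)))
    clearf_error("non-finite-score", "scores must be finite")
  ord <- order(-scores, seq_along(scores))
  ranks <- integer(length(scores))
  ranks[ord] <- seq_along(scores)
  ranks
}

# Feature names in rank order (top_n optional), used by the CV harness.
top_features <- function(score_table, n = NULL) {
  feats <- score_table$feature[order(score_table$rank)]
  if (!is.null(n)) feats <- feats[seq_len(min(n, length(feats)))]
  feats
}

#' Write a score table
#'
#' Writes `feature`, `score` and optionally `rank` columns, sorted by rank
#' (highest score first), as delimited text.
#'
#' @param scores A `clearf_scores` table from [clearf_scores()].
#' @param path Output file path.
#' @param sep Field delimiter, default tab.
#' @param include_rank Include the `rank` column (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path, sep = "\t", include_rank = TRUE) {
  tab <- as.data.frame(scores)[order(scores$rank), , drop = FALSE]
  if (!include_rank) tab$rank <- NULL
  write.table(tab, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.clearf_scores <- function(x, n = 10L, ...) {
  cat(sprintf("clearf_scores: %d features (aggregation = %s)\n",
              nrow(x), attr(x, "aggregation")))
  top <- as.data.frame(x)[order(x$rank), , drop = FALSE]
  print(utils::head(top, n), row.names = FALSE)
  if (nrow(x) > n) cat(sprintf(" ... %d more features\n", nrow(x) - n))
  invisible(x)
}
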