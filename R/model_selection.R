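#' Configure the cross-validated benchmark harness
#'
#' Settings for the component-size search and the 10-fold cross-validated
#' accuracy protocol with an RBF-kernel SVM downstream classifier.
#'
#' @param feature_counts Strictly increasing positive integers: the numbers
#'   of top-ranked features at which classification accuracy is measured.
#'   Default `seq(5, 50, by = 5)`, the grid used throughout the benchmark
#'   protocol.
#' @param n_folds Number of outer cross-validation folds (default 10).
#' @param seed Integer seed governing fold assignment and the inner split;
#'   two runs with the same seed produce identical reports.
#' @param svm_cost SVM soft-margin cost (default 1).
#' @param svm_gamma RBF kernel width for the classifier; `NULL` uses the
#'   conventional `1 / n_features_selected` default.
#' @param selection_n_features Number of top features used while searching
#'   the component size; `NULL` (default) takes the middle entry of
#'   `feature_counts`.
#' @param rotate_inner If `TRUE`, the inner component-size search rotates
#'   the validation subset over all three inner subsets and averages; the
#'   default `FALSE` uses a single fixed split.
#'
#' @return An object of class `selection_config`.
#' @export
selection_config <- function(feature_counts = seq(5L, 50L, by = 5L),
                             n_folds = 10L,
                             seed = 1L,
                             svm_cost = 1,
                             svm_gamma = NULL,
                             selection_n_features = NULL,
                             rotate_inner = FALSE) {
  feature_counts <- as.integer(feature_counts)
  if (length(feature_counts) < 1L || anyNA(feature_counts) ||
      any(feature_counts < 1L) || is.unsorted(feature_counts, strictly = TRUE))
    clearf_error("invalid-spec",
                 "feature_counts must be strictly increasing positive integers")
  structure(list(feature_counts = feature_counts,
                 n_folds = as.integer(n_folds), seed = as.integer(seed),
                 svm_cost = svm_cost, svm_gamma = svm_gamma,
                 selection_n_features = selection_n_features,
                 rotate_inner = isTRUE(rotate_inner)),
            class = "selection_config")
}

#' Candidate component sizes from the smallest class
#'
#' Given `c_min`, the sample count of the smallest class, produces the five
#' candidate component sizes `1, c_min/4, c_min/2, 3*c_min/4, c_min`, each
#' rounded to the nearest integer, floored at 1, and deduplicated in
#' ascending order.
#'
#' @param c_min Positive integer, smallest class size.
#' @return Integer vector of distinct candidate sizes in ascending order.
#' @examples
#' candidate_component_sizes(20)
#' candidate_component_sizes(4)
#' @export
candidate_component_sizes <- function(c_min) {
  c_min <- as.integer(c_min)
  if (is.na(c_min) || c_min < 1L)
    clearf_error("invalid-cmin", "c_min must be a positive integer")
  raw <- c(1, c_min / 4, c_min / 2, 3 * c_min / 4, c_min)
  sizes <- pmax(1L, as.integer(floor(raw + 0.5)))
  sort(unique(sizes))
}

# Stratified fold assignment: shuffle within each class, deal round-robin.
# Falls back to unstratified folds (with a warning) when a class has fewer
# samples than folds.
stratified_folds <- function(y, n_folds, seed) {
  n <- length(y)
  counts <- table(y)
  with_seed(seed, {
    folds <- integer(n)
    if (any(counts < n_folds)) {
      warning("a class has fewer samples than folds; using unstratified folds",
              call. = FALSE)
      folds <- rep_len(seq_len(n_folds), n)[sample.int(n)]
    } else {
      for (cl in names(counts)) {
        idx <- which(y == cl)
        idx <- idx[sample.int(length(idx))]
        folds[idx] <- rep_len(seq_len(n_folds), length(idx))
      }
    }
    folds
  })
}

# Train an RBF-SVM on selected feature columns and measure held-out accuracy.
svm_accuracy <- function(X_train, y_train, X_test, y_test, cfg) {
  y_train <- factor(y_train)
  if (nlevels(droplevels(y_train)) < 2L) {
    # degenerate training set: predict the only class present
    pred <- rep(levels(droplevels(y_train)), length(y_test))
    return(mean(pred == y_test))
  }
  gamma <- if (is.null(cfg$svm_gamma)) 1 / ncol(X_train) else cfg$svm_gamma
  fit <- e1071::svm(x = X_train, y = droplevels(y_train), kernel = "radial",
                    cost = cfg$svm_cost, gamma = gamma, scale = FALSE)
  pred <- as.character(predict(fit, X_test))
  mean(pred == y_test)
}

#' Search the embedding component size on training data
#'
#' Implements the greedy component-size search: the training data are split
#' into three equal-sized class-stratified subsets, two for fitting and one
#' for validation.  For every candidate size from
#' [candidate_component_sizes()] (anchored on the smallest class in
#' `train`), features are scored on the fitting subsets, the top
#' `n_features_to_keep` features are selected, and an RBF-SVM trained on
#' them is evaluated on the validation subset.  The size with the highest
#' validation accuracy wins; ties go to the smaller size.
#'
#' @param train A [labeled_dataset()] of training samples.
#' @param cfg A [selection_config()]; its `seed` fixes the inner split.
#' @param score_cfg A [score_config()]; its `n_components` is overridden by
#'   each candidate in turn.
#' @param n_features_to_keep Number of top-ranked features handed to the
#'   validation classifier.
#' @return The selected component size (integer).
#' @export
select_component_size <- function(train, cfg, score_cfg, n_features_to_keep) {
  train <- validate_dataset(train)
  c_min <- min(train$class_counts)
  candidates <- candidate_component_sizes(c_min)
  if (length(candidates) == 1L) return(candidates)

  subsets <- stratified_folds(train$y, 3L, cfg$seed)
  val_ids <- if (cfg$rotate_inner) 1:3 else 3L
  acc <- numeric(length(candidates))
  for (ci in seq_along(candidates)) {
    sc <- score_cfg
    sc$embedding$n_components <- candidates[ci]
    a <- vapply(val_ids, function(v) {
      tr <- which(subsets != v); va <- which(subsets == v)
      tab <- clearf_scores(dataset_rows(train, tr), sc)
      feats <- top_features(tab, n_features_to_keep)
      svm_accuracy(train$X[tr, feats, drop = FALSE], train$y[tr],
                   train$X[va, feats, drop = FALSE], train$y[va], cfg)
    }, numeric(1))
    acc[ci] <- mean(a)
  }
  # candidates ascend, which.max takes the first maximum: ties -> smaller size
  candidates[which.max(acc)]
}

#' Cross-validated accuracy over a feature-count grid
#'
#' Runs the benchmark protocol: stratified `n_folds`-fold cross-validation
#' in which, per fold, (1) the component size is searched on the training
#' part alone via [select_component_size()], (2) ClearF scores are computed
#' on the training part alone, and (3) for every entry of
#' `cfg$feature_counts` an RBF-SVM is trained on the top-ranked features
#' and its accuracy measured on the held-out fold.  Feature scoring never
#' sees held-out samples.
#'
#' @param d A [labeled_dataset()].
#' @param cfg A [selection_config()].
#' @param score_cfg A [score_config()]; its component count is replaced by
#'   the per-fold selected size.
#' @param keep_scores If `TRUE`, the per-fold training score vectors are
#'   kept in the report (for leakage diagnostics).
#' @return A `cv_report`: list with `feature_counts`, `fold_accuracies`
#'   (folds x counts matrix), `mean_accuracy`, `sd_accuracy`,
#'   `selected_component_sizes` (one per fold), `method` and `seed`.
#' @examples
#' d <- generate_informative(80, 5, 10, shift = 4, seed = 1)
#' cv <- cross_validate(d, selection_config(feature_counts = c(2L, 5L),
#'                                          n_folds = 5L, seed = 1L))
#' cv$mean_accuracy
#' @export
cross_validate <- function(d, cfg = selection_config(),
                           score_cfg = score_config(), keep_scores = FALSE) {
  d <- validate_dataset(d)
  if (max(cfg$feature_counts) > ncol(d$X))
    clearf_error("too-many-features", sprintf(
      "largest feature count (%d) exceeds the %d available features",
      max(cfg$feature_counts), ncol(d$X)))
  n_sel <- cfg$selection_n_features
  if (is.null(n_sel))
    n_sel <- cfg$feature_counts[ceiling(length(cfg$feature_counts) / 2)]

  folds <- stratified_folds(d$y, cfg$n_folds, cfg$seed)
  n_counts <- length(cfg$feature_counts)
  accs <- matrix(NA_real_, cfg$n_folds, n_counts,
                 dimnames = list(paste0("fold", seq_len(cfg$n_folds)),
                                 cfg$feature_counts))
  selected <- integer(cfg$n_folds)
  fold_scores <- if (keep_scores) vector("list", cfg$n_folds)

  for (f in seq_len(cfg$n_folds)) {
    tr <- which(folds != f); te <- which(folds == f)
    train <- dataset_rows(d, tr)
    inner_cfg <- cfg
    inner_cfg$seed <- cfg$seed + 1000L * f
    selected[f] <- select_component_size(train, inner_cfg, score_cfg, n_sel)
    sc <- score_cfg
    sc$embedding$n_components <- selected[f]
    tab <- clearf_scores(train, sc)
    if (keep_scores) fold_scores[[f]] <- tab$score
    ranked <- top_features(tab)
    for (ci in seq_len(n_counts)) {
      feats <- ranked[seq_len(cfg$feature_counts[ci])]
      accs[f, ci] <- svm_accuracy(d$X[tr, feats, drop = FALSE], d$y[tr],
                                  d$X[te, feats, drop = FALSE], d$y[te], cfg)
    }
  }

  structure(list(feature_counts = cfg$feature_counts,
                 fold_accuracies = accs,
                 mean_accuracy = colMeans(accs),
                 sd_accuracy = apply(accs, 2L, sd),
                 selected_component_sizes = selected,
                 fold_scores = fold_scores,
                 method = cfg_summary(score_cfg), seed = cfg$seed),
            class = "cv_report")
}

cfg_summary <- function(score_cfg) {
  sprintf("%s (aggregation=%s, standardize=%s)",
          score_cfg$embedding$method, score_cfg$aggregation,
          score_cfg$standardize)
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("cv_report: %d folds, method %s, seed %d\n",
              nrow(x$fold_accuracies), x$method, x$seed))
  cat(" selected component sizes:",
      paste(x$selected_component_sizes, collapse = " "), "\n")
  tab <- data.frame(feature_count = x$feature_counts,
                    mean_accuracy = round(x$mean_accuracy, 4),
                    sd = round(x$sd_accuracy, 4))
  print(tab, row.names = FALSE)
  cat(sprintf(" grand mean over the grid: %.4f\n", mean(x$mean_accuracy)))
  invisible(x)
}

#' Write a cross-validation report
#'
#' Writes the long per-fold table (`fold`, `feature_count`, `accuracy`,
#' `selected_k`) and, optionally, a summary table (`feature_count`,
#' `mean_accuracy`, `sd`) next to it.
#'
#' @param report A `cv_report` from [cross_validate()].
#' @param path Output file for the long table.
#' @param summary_path Optional output file for the summary table.
#' @param sep Field delimiter, default tab.
#' @return `path`, invisibly.
#' @export
write_cv_report <- function(report, path, summary_path = NULL, sep = "\t") {
  n_folds <- nrow(report$fold_accuracies)
  long <- data.frame(
    fold = rep(seq_len(n_folds), times = length(report$feature_counts)),
    feature_count = rep(report$feature_counts, each = n_folds),
    accuracy = as.vector(report$fold_accuracies),
    selected_k = rep(report$selected_component_sizes,
                     times = length(report$feature_counts)))
  write.table(long, path, sep = sep, quote = FALSE, row.names = FALSE)
  if (!is.null(summary_path)) {
    summ <- data.frame(feature_count = report$feature_counts,
                       mean_accuracy = report$mean_accuracy,
                       sd = report$sd_accuracy)
    write.table(summ, summary_path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
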