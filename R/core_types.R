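#' @importFrom stats cor cov median predict rnorm sd var
#' @importFrom utils read.table write.table
NULL

# Classed error constructor: id "missing-data" becomes condition class
# "clearf_missing_data" so callers can branch on the failure mode.
clearf_error <- function(id, msg, call = sys.call(-1)) {
  cls <- paste0("clearf_", gsub("-", "_", id, fixed = TRUE))
  stop(errorCondition(msg, class = c(cls, "clearf_error"), call = call))
}

# Run expr under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Construct a labelled dataset
#'
#' Bundles a numeric samples-by-features matrix with one categorical class
#' label per sample.  This is the input container for [clearf_scores()] and
#' [cross_validate()].  Class order is always the sorted order of the label
#' strings, so downstream results are deterministic regardless of how rows
#' are arranged.
#'
#' @param X Numeric matrix or data frame, samples in rows, features in
#'   columns.  Must be free of missing or non-finite values; features with
#'   missing measurements should be removed upstream.
#' @param y Vector of class labels, one per row of `X`.  Treated as opaque
#'   categorical values.
#' @param feature_names Optional character vector of unique feature names;
#'   defaults to the column names of `X`, or `F1..Fp` when absent.
#'
#' @return An object of class `labeled_dataset`: a list with elements `X`
#'   (numeric matrix with column names), `y` (character vector),
#'   `feature_names`, `classes` (sorted unique labels) and `class_counts`.
#'
#' @examples
#' d <- labeled_dataset(matrix(rnorm(8), 4, 2), c("a", "a", "b", "b"))
#' d$class_counts
#' @export
labeled_dataset <- function(X, y, feature_names = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(feature_names)) {
    feature_names <- colnames(X)
    if (is.null(feature_names)) feature_names <- paste0("F", seq_len(ncol(X)))
  }
  colnames(X) <- feature_names
  y <- as.character(y)
  classes <- sort(unique(y))
  d <- structure(
    list(X = X, y = y, feature_names = feature_names,
         classes = classes,
         class_counts = vapply(classes, function(cl) sum(y == cl), integer(1))),
    class = "labeled_dataset")
  validate_dataset(d)
}

#' Validate a labelled dataset
#'
#' Checks the structural invariants of a [labeled_dataset()]: at least two
#' samples and one feature, a label for every sample, every class
#' represented, unique feature names, and no missing or non-finite values.
#'
#' @param d A `labeled_dataset`.
#' @return `d`, unchanged, if all invariants hold.  Otherwise a classed
#'   error is raised: `clearf_missing_data`, `clearf_degenerate_labels`,
#'   `clearf_duplicate_feature` or `clearf_shape_mismatch`.
#' @export
validate_dataset <- function(d) {
  if (!inherits(d, "labeled_dataset"))
    clearf_error("shape-mismatch", "not a labeled_dataset")
  if (nrow(d$X) < 2L)
    clearf_error("degenerate-labels", "need at least 2 samples")
  if (ncol(d$X) < 1L)
    clearf_error("shape-mismatch", "need at least 1 feature")
  if (length(d$y) != nrow(d$X))
    clearf_error("shape-mismatch", sprintf(
      "%d labels for %d samples", length(d$y), nrow(d$X)))
  if (anyNA(d$X) || !all(is.finite(d$X)))
    clearf_error("missing-data",
                 "X contains missing or non-finite values; remove such features upstream")
  if (anyNA(d$y) || length(d$classes) < 1L || any(d$class_counts < 1L))
    clearf_error("degenerate-labels", "every class must have at least one sample")
  if (anyDuplicated(d$feature_names))
    clearf_error("duplicate-feature", sprintf(
      "duplicated feature name(s): %s",
      paste(unique(d$feature_names[duplicated(d$feature_names)]), collapse = ", ")))
  if (length(d$feature_names) != ncol(d$X))
    clearf_error("shape-mismatch", "feature_names length must equal ncol(X)")
  d
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("labeled_dataset: %d samples x %d features, %d class(es)\n",
              nrow(x$X), ncol(x$X), length(x$classes)))
  cnt <- paste(sprintf("%s=%d", x$classes, x$class_counts), collapse = ", ")
  cat(" class counts:", cnt, "\n")
  invisible(x)
}

# Subset rows of a dataset without revalidating class coverage (used for
# class-wise splits and CV folds, where a fold legitimately drops classes).
dataset_rows <- function(d, idx) {
  y <- d$y[idx]
  classes <- sort(unique(y))
  structure(
    list(X = d$X[idx, , drop = FALSE], y = y,
         feature_names = d$feature_names, classes = classes,
         class_counts = vapply(classes, function(cl) sum(y == cl), integer(1))),
    class = "labeled_dataset")
}
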