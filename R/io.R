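#' Read a labelled dataset from delimited text
#'
#' Expects samples as rows, a header row of feature names, and one column
#' holding the class label.  All non-label columns must parse as finite
#' numbers.
#'
#' @param path File path.
#' @param label_column Name of the label column (default `"class"`).
#' @param sep Field delimiter; `NULL` (default) infers tab for `.tsv`/
#'   `.txt` and comma for `.csv`.
#' @return A validated [labeled_dataset()]; row order is preserved.
#' @export
read_dataset <- function(path, label_column = "class", sep = NULL) {
  if (!file.exists(path))
    clearf_error("dialect-error", sprintf("file not found: %s", path))
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE, comment.char = "")
  if (!label_column %in% names(df))
    clearf_error("dialect-error", sprintf(
      "label column '%s' not found in header (%s)",
      label_column, paste(names(df), collapse = ", ")))
  y <- as.character(df[[label_column]])
  feats <- df[names(df) != label_column]
  for (j in seq_along(feats)) {
    col <- feats[[j]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad) > 0L)
        clearf_error("parse-error", sprintf(
          "non-numeric value '%s' at row %d, column '%s'",
          col[bad[1]], bad[1], names(feats)[j]))
      feats[[j]] <- num
    }
  }
  labeled_dataset(as.matrix(feats), y, feature_names = names(feats))
}

#' Write a labelled dataset to delimited text
#'
#' Inverse of [read_dataset()]: one row per sample, feature columns named
#' by `feature_names`, plus the label column.
#'
#' @param d A [labeled_dataset()].
#' @param path Output file path.
#' @param label_column Name of the label column (default `"class"`).
#' @param sep Field delimiter; `NULL` infers from the file extension as in
#'   [read_dataset()].
#' @return `path`, invisibly.
#' @export
write_dataset <- function(d, path, label_column = "class", sep = NULL) {
  d <- validate_dataset(d)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- as.data.frame(d$X)
  df[[label_column]] <- d$y
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
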