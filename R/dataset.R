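#' Construct a labeled sample-by-feature dataset
#'
#' @param X Numeric matrix, one row per sample, one column per feature; no
#'   missing values.
#' @param y Class labels (factor, character or integer), one per row; at
#'   least two classes.
#' @param feature_names Optional feature names (default: column names).
#' @return An object of class `labeled_dataset` with `X`, integer class
#'   codes `y` (1-based, levels sorted), the original `labels` levels, and
#'   `feature_names`.
#' @export
labeled_dataset <- function(X, y, feature_names = colnames(X)) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (anyNA(X)) stop("`X` must not contain missing values")
  if (nrow(X) != length(y)) stop("`y` must have one label per row of `X`")
  lv <- sort(unique(as.vector(y)))
  if (length(lv) < 2L) stop("at least 2 classes are required")
  if (is.null(feature_names))
    feature_names <- sprintf("feature_%05d", seq_len(ncol(X)))
  structure(
    list(X = X, y = match(y, lv), labels = lv,
         feature_names = as.character(feature_names)),
    class = "labeled_dataset"
  )
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %d samples x %d features, %d classes\n",
              nrow(x$X), ncol(x$X), length(x$labels)))
  invisible(x)
}

#' Read a labeled dataset from CSV/TSV
#'
#' Expects a header row, one column holding the class label and all
#' remaining columns numeric features; row order is preserved. The delimiter
#' is inferred from the file extension (`.tsv` uses tab).
#'
#' @param path Input path.
#' @param label_col Name of the label column (default `"label"`).
#' @return A [labeled_dataset()].
#' @export
read_labeled_csv <- function(path, label_col = "label") {
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.csv(path, check.names = FALSE, sep = sep)
  if (!label_col %in% names(df))
    stop("no column named '", label_col, "' in ", path)
  y <- df[[label_col]]
  X <- as.matrix(df[, setdiff(names(df), label_col), drop = FALSE])
  storage.mode(X) <- "double"
  labeled_dataset(X, y, feature_names = colnames(X))
}

#' Write a labeled dataset as CSV/TSV
#'
#' Inverse of [read_labeled_csv()]: feature columns followed by a `label`
#' column holding the original label values.
#'
#' @param data A [labeled_dataset()].
#' @param path Output path (`.tsv` extension switches to tab delimiter).
#' @param label_col Name for the label column.
#' @return `path`, invisibly.
#' @export
write_labeled_csv <- function(data, path, label_col = "label") {
  stopifnot(inherits(data, "labeled_dataset"))
  df <- as.data.frame(data$X)
  names(df) <- data$feature_names
  df[[label_col]] <- data$labels[data$y]
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
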