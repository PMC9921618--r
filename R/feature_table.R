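#' Construct a feature table
#'
#' The central container of the package: a numeric matrix of samples by
#' named radiomic (or synthetic) features together with a binary label per
#' sample. All selection and classification functions consume this object.
#'
#' @param x numeric matrix, samples in rows, features in columns; column
#'   names must be unique and non-empty.
#' @param y binary labels, coercible to integer 0/1, one per row of `x`.
#' @param sample_ids optional character vector of sample identifiers;
#'   defaults to `sample_1 ... sample_n`.
#' @return An object of class `feature_table` with elements `x`, `y`
#'   (integer 0/1) and `sample_ids`.
#' @examples
#' ft <- feature_table(matrix(rnorm(20), 10, 2,
#'                            dimnames = list(NULL, c("f1", "f2"))),
#'                     y = rep(c(0, 1), 5))
#' dim(ft$x)
#' @export
feature_table <- function(x, y, sample_ids = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x)) || anyDuplicated(colnames(x)) || any(colnames(x) == "")) {
    stop("feature columns must carry unique, non-empty names", call. = FALSE)
  }
  if (any(!is.finite(x))) {
    bad <- unique(colnames(x)[which(!is.finite(x), arr.ind = TRUE)[, 2]])
    stop("non-finite values in feature column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  y <- as.integer(y)
  if (length(y) != nrow(x) || !all(y %in% c(0L, 1L))) {
    stop("'y' must be one 0/1 label per sample", call. = FALSE)
  }
  if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(nrow(x)))
  if (length(sample_ids) != nrow(x) || anyDuplicated(sample_ids)) {
    stop("'sample_ids' must be unique, one per sample", call. = FALSE)
  }
  structure(list(x = x, y = y, sample_ids = as.character(sample_ids)),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d samples x %d features (%d positive, %d negative)\n",
              nrow(x$x), ncol(x$x), sum(x$y == 1L), sum(x$y == 0L)))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$x)

# Subset rows (samples) and/or columns (features) of a feature table.
subset_table <- function(table, rows = NULL, features = NULL) {
  x <- table$x
  y <- table$y
  ids <- table$sample_ids
  if (!is.null(rows)) {
    x <- x[rows, , drop = FALSE]
    y <- y[rows]
    ids <- ids[rows]
  }
  if (!is.null(features)) {
    missing <- setdiff(features, colnames(x))
    if (length(missing)) {
      stop("unknown feature(s): ", paste(missing, collapse = ", "), call. = FALSE)
    }
    x <- x[, features, drop = FALSE]
  }
  feature_table(x, y, ids)
}

#' Write a feature table as delimited text
#'
#' Comma-delimited with a header row; first column `sample_id`, then one
#' column per feature, then the label column `label`. Raw (pre-binarization)
#' marker columns, when present in `extra`, are written with a `_raw` suffix.
#'
#' @param table a [feature_table()].
#' @param path output file path.
#' @param extra optional data frame of additional per-sample columns (e.g.
#'   raw marker values); column names get a `_raw` suffix if not already
#'   suffixed.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path, extra = NULL) {
  df <- data.frame(sample_id = table$sample_ids, table$x,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(extra)) {
    extra <- as.data.frame(extra)
    names(extra) <- ifelse(grepl("_raw$", names(extra)), names(extra),
                           paste0(names(extra), "_raw"))
    df <- cbind(df, extra)
  }
  df$label <- table$y
  write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path CSV path with `sample_id`, feature columns, optional `*_raw`
#'   columns and a `label` column.
#' @return A [feature_table()]; raw marker columns are attached as the
#'   `"raw_markers"` attribute.
#' @export
read_feature_table <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                 comment.char = "#")
  required <- c("sample_id", "label")
  if (!all(required %in% names(df))) {
    stop("feature table file must contain 'sample_id' and 'label' columns",
         call. = FALSE)
  }
  raw_cols <- grep("_raw$", names(df), value = TRUE)
  feat_cols <- names(df)[!names(df) %in% c(required, raw_cols)]  # keeps duplicates
  if (anyDuplicated(feat_cols)) {
    stop("duplicate feature column names: ",
         paste(unique(feat_cols[duplicated(feat_cols)]), collapse = ", "),
         call. = FALSE)
  }
  ft <- feature_table(as.matrix(df[, feat_cols, drop = FALSE]),
                      y = df$label, sample_ids = df$sample_id)
  if (length(raw_cols)) attr(ft, "raw_markers") <- df[, raw_cols, drop = FALSE]
  ft
}
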