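#' SMOTE oversampling of the minority class
#'
#' Balances a binary training table by synthesizing minority-class samples
#' through interpolation: each synthetic row is a convex combination of a
#' minority sample and one of its `k_neighbors` nearest minority
#' neighbours (Euclidean distance in feature space). Original rows are
#' returned unchanged, in their original order, followed by the synthetic
#' rows. An already balanced table is returned as-is.
#'
#' Apply this to training splits only: oversampling before the
#' train/test split leaks synthetic copies of evaluation samples into
#' training.
#'
#' @param table a [feature_table()] with both classes present.
#' @param k_neighbors number of minority-class nearest neighbours to
#'   interpolate with; reduced with a warning when the minority class is
#'   too small.
#' @param seed integer seed.
#' @return A [feature_table()] with equal class counts; synthetic samples
#'   get ids `smote_<i>`.
#' @export
smote_oversample <- function(table, k_neighbors = 5L, seed = 1L) {
  stopifnot(inherits(table, "feature_table"))
  y <- table$y
  n_pos <- sum(y == 1L)
  n_neg <- sum(y == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("SMOTE requires both classes in the training split", call. = FALSE)
  }
  if (n_pos == n_neg) return(table)
  minority <- if (n_pos < n_neg) 1L else 0L
  min_idx <- which(y == minority)
  n_min <- length(min_idx)
  n_new <- abs(n_pos - n_neg)
  k <- assert_count(k_neighbors, "k_neighbors")
  if (n_min == 1L) {
    # degenerate: duplicate the single minority sample
    warning("single minority sample: SMOTE duplicates it")
    new_x <- table$x[rep(min_idx, n_new), , drop = FALSE]
  } else {
    if (n_min <= k) {
      k <- n_min - 1L
      warning("minority class smaller than k_neighbors; using k = ", k)
    }
    xm <- table$x[min_idx, , drop = FALSE]
    d <- as.matrix(dist(xm))
    diag(d) <- Inf
    nn <- matrix(0L, n_min, k)  # k = 1 must still give one row per sample
    for (i in seq_len(n_min)) nn[i, ] <- order(d[i, ])[seq_len(k)]
    new_x <- local_seed(seed, {
      base <- sample(rep_len(seq_len(n_min), n_new))
      nb <- nn[cbind(base, sample.int(k, n_new, replace = TRUE))]
      u <- runif(n_new)
      xm[base, , drop = FALSE] + u * (xm[nb, , drop = FALSE] - xm[base, , drop = FALSE])
    })
  }
  x <- rbind(table$x, new_x)
  feature_table(x,
                c(y, rep(minority, n_new)),
                c(table$sample_ids, paste0("smote_", seq_len(n_new))))
}
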