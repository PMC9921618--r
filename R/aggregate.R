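#' Aggregate per-fold feature rankings by minimal rank
#'
#' The ensemble merge at the heart of the pipeline: across the fold-wise
#' rankings, each feature is summarized by `minpos`, the best (minimum)
#' 1-based rank it ever attained, and `numpos`, the number of folds in
#' which it attained exactly that rank. Features with `minpos <= threshold`
#' are kept and ordered by `minpos` ascending, then `numpos` descending,
#' then stable original index. Because different folds promote different
#' features, the kept list may be longer than the threshold itself.
#'
#' @param per_fold list of per-fold rankings: `ranked_list` data frames or
#'   plain character vectors of feature names, best first. Subset methods
#'   contribute only their selected features.
#' @param threshold keep features whose minimal rank is at most this.
#' @return Data frame with columns `feature`, `minpos`, `numpos`, ordered
#'   as described; the kept feature names are in `$feature`.
#' @export
aggregate_fold_rankings <- function(per_fold, threshold) {
  if (!length(per_fold)) stop("no fold rankings supplied", call. = FALSE)
  assert_count(threshold, "threshold")
  fold_names <- lapply(per_fold, function(f) {
    if (inherits(f, "ranked_list") || is.data.frame(f)) {
      as.character(f$feature[if ("selected" %in% names(f)) f$selected else TRUE])
    } else {
      as.character(f)
    }
  })
  if (any(!lengths(fold_names))) stop("empty fold ranking", call. = FALSE)

  # stable index: original column index when supplied, else first
  # appearance across folds in fold order
  idx_map <- new.env(hash = TRUE)
  nxt <- 1L
  for (f in seq_along(per_fold)) {
    rl <- per_fold[[f]]
    nm <- fold_names[[f]]
    oi <- if (is.data.frame(rl) && "orig_index" %in% names(rl)) {
      rl$orig_index[if ("selected" %in% names(rl)) rl$selected else TRUE]
    } else {
      NULL
    }
    for (t in seq_along(nm)) {
      if (is.null(idx_map[[nm[t]]])) {
        idx_map[[nm[t]]] <- if (is.null(oi)) {
          nxt
        } else {
          oi[t]
        }
      }
      nxt <- nxt + 1L
    }
  }

  stats <- new.env(hash = TRUE)
  for (nm in fold_names) {
    for (pos in seq_along(nm)) {
      f <- nm[pos]
      cur <- stats[[f]]
      if (is.null(cur)) {
        stats[[f]] <- c(minpos = pos, numpos = 1L)
      } else if (pos < cur["minpos"]) {
        stats[[f]] <- c(minpos = pos, numpos = 1L)
      } else if (pos == cur["minpos"]) {
        stats[[f]] <- c(minpos = cur[["minpos"]], numpos = cur[["numpos"]] + 1L)
      }
    }
  }
  feats <- ls(stats)
  minpos <- vapply(feats, function(f) stats[[f]][["minpos"]], numeric(1))
  numpos <- vapply(feats, function(f) stats[[f]][["numpos"]], numeric(1))
  sidx <- vapply(feats, function(f) as.numeric(idx_map[[f]]), numeric(1))
  keep <- minpos <= threshold
  ord <- order(minpos[keep], -numpos[keep], sidx[keep])
  data.frame(feature = feats[keep][ord],
             minpos = as.integer(minpos[keep][ord]),
             numpos = as.integer(numpos[keep][ord]),
             stringsAsFactors = FALSE)
}
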