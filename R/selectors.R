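# Feature-selection methods behind a uniform ranking interface. Five
# univariate/instance-based rankers (chi-squared, Fisher score, Gini
# index, ReliefF, mutual information), LASSO recursive feature
# elimination, and CFS subset search.

RANKER_METHODS <- c("chi_squared", "fisher", "gini_index", "relieff",
                    "mutual_information")
COMPLETE_RANKERS <- c("chi_squared", "fisher", "gini_index", "relieff")

ranked_list <- function(feature, score, method, orig_index,
                        selected = rep(TRUE, length(feature))) {
  structure(data.frame(rank = seq_along(feature), feature = feature,
                       score = score, method = method,
                       orig_index = orig_index, selected = selected,
                       stringsAsFactors = FALSE),
            class = c("ranked_list", "data.frame"))
}

# Order scores descending, ties by original column index; zero-variance
# (degenerate) features are forced to the bottom with score 0.
order_scores <- function(scores, degenerate, feature_names, method) {
  scores[degenerate] <- 0
  key <- ifelse(degenerate, -Inf, scores)
  ord <- order(-key, seq_along(scores))
  ranked_list(feature_names[ord], scores[ord], method, ord)
}

#' Score and rank all features with a filter method
#'
#' Every feature receives a relevance score for the binary label and the
#' full list is returned best-first. Ties resolve by original column
#' index; constant (zero-variance) features always rank last with score 0.
#'
#' Methods: `chi_squared` (features min-max scaled to `[0, 1]` and treated
#' as non-negative pseudo-frequencies in a two-class chi-squared
#' statistic), `fisher` (between-class over within-class scatter, with
#' population class variances), `gini_index` (impurity reduction of the
#' best single split threshold), `relieff` (hit/miss margin over the
#' `k = 10` nearest neighbours of every sample, Manhattan differences on
#' range-normalized features), `mutual_information` (nearest-neighbour
#' mixed continuous/discrete estimator with 3 neighbours).
#'
#' @param table a [feature_table()] with both classes present.
#' @param method one of `chi_squared, fisher, gini_index, relieff,
#'   mutual_information`.
#' @param seed seed for the methods that jitter ties (mutual information);
#'   ignored elsewhere.
#' @return A `ranked_list` data frame: `rank`, `feature`, `score`,
#'   `method`, `orig_index`, `selected`.
#' @export
score_features <- function(table, method, seed = 1L) {
  stopifnot(inherits(table, "feature_table"))
  method <- match.arg(method, RANKER_METHODS)
  y <- table$y
  if (length(unique(y)) < 2L) stop("both classes must be present", call. = FALSE)
  x <- table$x
  degenerate <- apply(x, 2, function(v) max(v) == min(v))
  scores <- switch(method,
    chi_squared = chi_squared_scores(x, y),
    fisher = fisher_scores(x, y),
    gini_index = gini_scores(x, y),
    relieff = relieff_scores(x, y, k = 10L),
    mutual_information = mi_scores(x, y, k = 3L, seed = seed))
  scores[!is.finite(scores)] <- 0
  order_scores(scores, degenerate, colnames(x), method)
}

chi_squared_scores <- function(x, y) {
  rngs <- apply(x, 2, range)
  span <- rngs[2, ] - rngs[1, ]
  span[span == 0] <- 1
  xs <- sweep(sweep(x, 2, rngs[1, ]), 2, span, "/")
  n <- nrow(xs)
  obs <- rbind(colSums(xs[y == 0L, , drop = FALSE]),
               colSums(xs[y == 1L, , drop = FALSE]))
  tot <- colSums(obs)
  prior <- c(mean(y == 0L), mean(y == 1L))
  expd <- outer(prior, tot)
  chi <- colSums((obs - expd)^2 / pmax(expd, .Machine$double.eps))
  chi[tot == 0] <- 0
  chi
}

fisher_scores <- function(x, y) {
  out <- numeric(ncol(x))
  mu <- colMeans(x)
  between <- 0
  within <- 0
  for (cls in c(0L, 1L)) {
    xi <- x[y == cls, , drop = FALSE]
    nk <- nrow(xi)
    mk <- colMeans(xi)
    vk <- colMeans(sweep(xi, 2, mk)^2)  # population variance
    between <- between + nk * (mk - mu)^2
    within <- within + nk * vk
  }
  sc <- ifelse(within > 0, between / within,
               ifelse(between > 0, 1e12, 0))
  sc
}

# Best-split Gini impurity reduction for a continuous feature.
gini_scores <- function(x, y) {
  n <- length(y)
  n1 <- sum(y == 1L)
  parent <- 1 - (n1 / n)^2 - ((n - n1) / n)^2
  apply(x, 2, function(v) {
    ord <- order(v)
    vs <- v[ord]
    ys <- y[ord]
    cum1 <- cumsum(ys == 1L)
    left_n <- seq_len(n - 1L)
    valid <- vs[-n] != vs[-1]          # split only between distinct values
    if (!any(valid)) return(0)
    l1 <- cum1[-n]
    r1 <- n1 - l1
    right_n <- n - left_n
    gl <- 1 - (l1 / left_n)^2 - ((left_n - l1) / left_n)^2
    gr <- 1 - (r1 / right_n)^2 - ((right_n - r1) / right_n)^2
    merit <- parent - (left_n * gl + right_n * gr) / n
    max(merit[valid])
  })
}

relieff_scores <- function(x, y, k = 10L) {
  n <- nrow(x)
  rngs <- apply(x, 2, range)
  span <- rngs[2, ] - rngs[1, ]
  span[span == 0] <- 1
  xs <- sweep(sweep(x, 2, rngs[1, ]), 2, span, "/")
  d <- as.matrix(dist(xs, method = "manhattan"))
  w <- numeric(ncol(x))
  k_hit <- min(k, min(table(y)) - 1L)
  k_miss <- min(k, min(table(y)))
  if (k_hit < 1L) stop("too few samples per class for ReliefF", call. = FALSE)
  for (i in seq_len(n)) {
    same <- which(y == y[i])
    same <- same[same != i]
    diff_cls <- which(y != y[i])
    hits <- same[order(d[i, same], same)][seq_len(k_hit)]
    misses <- diff_cls[order(d[i, diff_cls], diff_cls)][seq_len(k_miss)]
    hd <- abs(sweep(xs[hits, , drop = FALSE], 2, xs[i, ]))
    md <- abs(sweep(xs[misses, , drop = FALSE], 2, xs[i, ]))
    w <- w + colSums(md) / k_miss - colSums(hd) / k_hit
  }
  w / n
}

# Mixed continuous/discrete mutual information, nearest-neighbour
# estimator (Ross 2014) computed per feature in 1D.
mi_scores <- function(x, y, k = 3L, seed = 1L) {
  n <- nrow(x)
  local_seed(seed, {
    apply(x, 2, function(v) {
      if (max(v) == min(v)) return(0)
      # tiny jitter breaks ties deterministically under the local seed
      v <- v + rnorm(n, sd = 1e-10 * sd_pop(v) + 1e-300)
      psi_k <- numeric(n)
      m_i <- numeric(n)
      n_xi <- numeric(n)
      vs <- sort(v)
      for (cls in c(0L, 1L)) {
        idx <- which(y == cls)
        nc <- length(idx)
        kk <- min(k, nc - 1L)
        if (kk < 1L) {
          # singleton class: no within-class neighbour; contributes nothing
          psi_k[idx] <- NA
          next
        }
        vc <- sort(v[idx])
        for (a in seq_along(vc)) {
          lo <- max(1L, a - kk)
          hi <- min(nc, a + kk)
          cand <- sort(abs(vc[lo:hi] - vc[a]))
          r <- cand[kk + 1L]  # k-th neighbour distance (self excluded)
          orig <- idx[which(v[idx] == vc[a])[1]]
          psi_k[orig] <- kk
          # distance form, not interval endpoints: keeps the k-th
          # neighbour inside the ball despite floating-point rounding
          m_i[orig] <- sum(abs(vs - vc[a]) <= r) - 1L
          n_xi[orig] <- nc
        }
      }
      ok <- !is.na(psi_k)
      if (!any(ok)) return(0)
      mi <- digamma(n) - mean(digamma(n_xi[ok])) +
        mean(digamma(psi_k[ok])) - mean(digamma(pmax(m_i[ok], 1)))
      max(mi, 0)
    })
  })
}

#' LASSO recursive feature elimination
#'
#' Fits an L1-regularized logistic model, removes the feature with the
#' smallest absolute coefficient, and repeats until one feature remains;
#' the elimination order defines the ranking (eliminated later = better).
#' The penalty is chosen once per call by internal 5-fold cross-validation
#' over the default logarithmic lambda grid and then held fixed across
#' elimination rounds. Features are z-standardized internally.
#'
#' @param table a [feature_table()].
#' @param k number of features to keep (`selected = TRUE` in the result).
#' @param seed seed controlling the internal cross-validation folds.
#' @return A `ranked_list` of the top-`k` features; `score` is the
#'   elimination round (higher = survived longer).
#' @export
lr_rfe_select <- function(table, k, seed = 1L) {
  stopifnot(inherits(table, "feature_table"))
  p <- ncol(table$x)
  assert_count(k, "k")
  if (k > p) stop("'k' exceeds the number of features", call. = FALSE)
  if (length(unique(table$y)) < 2L) stop("both classes must be present", call. = FALSE)
  x <- scale(table$x)
  x[, attr(x, "scaled:scale") == 0] <- 0
  y <- table$y
  feats <- colnames(table$x)

  if (p == 1L) {
    return(ranked_list(feats, 1, "lr_rfe", 1L))
  }
  elim_round <- integer(p)  # 0 = survivor
  remaining <- seq_len(p)
  local_seed(seed, {
    foldid <- sample(rep_len(seq_len(5L), length(y)))
    lambda <- tryCatch(
      glmnet::cv.glmnet(x, y, family = "binomial", alpha = 1,
                        foldid = foldid, nfolds = 5L)$lambda.min,
      error = function(e) 0.01)
    round <- 0L
    while (length(remaining) > 1L) {
      round <- round + 1L
      cf <- if (length(remaining) >= 2L) {
        fit <- glmnet::glmnet(x[, remaining, drop = FALSE], y,
                              family = "binomial", alpha = 1, lambda = lambda)
        abs(as.numeric(coef(fit))[-1])
      } else {
        1
      }
      # drop the weakest; among ties keep earlier columns longer
      weak <- which(cf == min(cf))
      drop_pos <- weak[length(weak)]
      elim_round[remaining[drop_pos]] <- round
      remaining <- remaining[-drop_pos]
    }
  })
  elim_round[remaining] <- max(elim_round) + 1L  # survivor outranks all
  ord <- order(-elim_round, seq_len(p))
  ranked_list(feats[ord], elim_round[ord], "lr_rfe", ord,
              selected = seq_len(p) <= k)
}

cfs_merit <- function(subset, r_cf, r_ff) {
  k <- length(subset)
  rcf <- mean(r_cf[subset])
  rff <- if (k > 1) mean(r_ff[subset, subset][upper.tri(matrix(0, k, k))]) else 0
  k * rcf / sqrt(k + k * (k - 1) * rff)
}

#' Correlation-based feature selection (CFS)
#'
#' Best-first search over feature subsets maximizing the CFS merit
#' `k * mean(|r_cf|) / sqrt(k + k (k - 1) * mean(|r_ff|))`, the ratio of
#' average feature-class to average feature-feature correlation. The
#' search expands the best open subset by one feature at a time and stops
#' after 5 consecutive non-improving expansions. The subset size is chosen
#' by the method itself.
#'
#' @param table a [feature_table()] with at least two features.
#' @param max_expansions stop after this many consecutive expansions
#'   without improving the best merit.
#' @return A `ranked_list` of the selected subset, ordered by decreasing
#'   class correlation; `score` holds `|r_cf|`, the attribute `"merit"`
#'   the merit of the winning subset.
#' @export
cfs_select <- function(table, max_expansions = 5L) {
  stopifnot(inherits(table, "feature_table"))
  x <- table$x
  if (ncol(x) < 2L) {
    r <- abs(cor(x[, 1], table$y))
    out <- ranked_list(colnames(x), r, "cfs", 1L)
    attr(out, "merit") <- r
    return(out)
  }
  keep <- apply(x, 2, function(v) max(v) > min(v))
  if (!all(keep)) {
    warning("excluding ", sum(!keep), " zero-variance feature(s) from CFS")
    x <- x[, keep, drop = FALSE]
  }
  y <- table$y
  r_cf <- abs(as.numeric(cor(x, y)))
  r_ff <- abs(cor(x))
  p <- ncol(x)

  seen <- new.env(hash = TRUE)
  open <- list(list(set = integer(0), merit = -Inf))
  best_set <- integer(0)
  best_merit <- -Inf
  stall <- 0L
  while (length(open) && stall < max_expansions) {
    merits <- vapply(open, `[[`, numeric(1), "merit")
    pick <- which.max(merits)
    node <- open[[pick]]
    open[[pick]] <- NULL
    improved <- FALSE
    for (f in setdiff(seq_len(p), node$set)) {
      cand <- sort(c(node$set, f))
      key <- paste(cand, collapse = ",")
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      m <- cfs_merit(cand, r_cf, r_ff)
      open[[length(open) + 1L]] <- list(set = cand, merit = m)
      if (m > best_merit + 1e-12) {
        best_merit <- m
        best_set <- cand
        improved <- TRUE
      }
    }
    stall <- if (improved) 0L else stall + 1L
  }
  ord <- best_set[order(-r_cf[best_set], best_set)]
  out <- ranked_list(colnames(x)[ord], r_cf[ord], "cfs",
                     match(colnames(x)[ord], colnames(table$x)))
  attr(out, "merit") <- best_merit
  out
}
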