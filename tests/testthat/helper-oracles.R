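# Independent brute-force oracles. These re-derive every score from its
# defining formula with plain loops, deliberately sharing no code with the
# package implementations.

oracle_minpos_numpos <- function(folds, threshold) {
  feats <- unique(unlist(folds))
  rows <- lapply(feats, function(f) {
    pos <- vapply(folds, function(fold) {
      w <- which(fold == f)
      if (length(w)) w else NA_integer_
    }, integer(1))
    mp <- suppressWarnings(min(pos, na.rm = TRUE))
    c(minpos = mp, numpos = sum(pos == mp, na.rm = TRUE))
  })
  df <- data.frame(feature = feats,
                   minpos = vapply(rows, `[[`, numeric(1), "minpos"),
                   numpos = vapply(rows, `[[`, numeric(1), "numpos"),
                   idx = seq_along(feats), stringsAsFactors = FALSE)
  df <- df[df$minpos <= threshold, , drop = FALSE]
  df[order(df$minpos, -df$numpos, df$idx), c("feature", "minpos", "numpos")]
}

oracle_fisher <- function(x, y) {
  apply(x, 2, function(v) {
    mu <- mean(v)
    num <- 0; den <- 0
    for (cls in unique(y)) {
      vi <- v[y == cls]
      num <- num + length(vi) * (mean(vi) - mu)^2
      den <- den + length(vi) * mean((vi - mean(vi))^2)
    }
    if (den > 0) num / den else if (num > 0) 1e12 else 0
  })
}

oracle_chi_squared <- function(x, y) {
  apply(x, 2, function(v) {
    if (max(v) == min(v)) return(0)
    v <- (v - min(v)) / (max(v) - min(v))
    chi <- 0
    tot <- sum(v)
    if (tot == 0) return(0)
    for (cls in c(0, 1)) {
      obs <- sum(v[y == cls])
      expd <- tot * mean(y == cls)
      chi <- chi + (obs - expd)^2 / expd
    }
    chi
  })
}

oracle_gini <- function(x, y) {
  n <- length(y)
  gini <- function(lbl) 1 - mean(lbl == 1)^2 - mean(lbl == 0)^2
  parent <- gini(y)
  apply(x, 2, function(v) {
    cuts <- sort(unique(v))
    if (length(cuts) < 2) return(0)
    best <- 0
    for (c in head(cuts, -1)) {
      left <- y[v <= c]; right <- y[v > c]
      red <- parent - (length(left) * gini(left) + length(right) * gini(right)) / n
      if (red > best) best <- red
    }
    best
  })
}

oracle_relieff <- function(x, y, k = 10) {
  n <- nrow(x)
  xs <- apply(x, 2, function(v) {
    if (max(v) == min(v)) rep(0, length(v)) else (v - min(v)) / (max(v) - min(v))
  })
  w <- numeric(ncol(x))
  k_hit <- min(k, min(table(y)) - 1)
  k_miss <- min(k, min(table(y)))
  for (i in seq_len(n)) {
    d <- rowSums(abs(sweep(xs, 2, xs[i, ])))
    same <- setdiff(which(y == y[i]), i)
    diff_cls <- which(y != y[i])
    hits <- same[order(d[same], same)][seq_len(k_hit)]
    misses <- diff_cls[order(d[diff_cls], diff_cls)][seq_len(k_miss)]
    for (f in seq_len(ncol(x))) {
      w[f] <- w[f] + sum(abs(xs[misses, f] - xs[i, f])) / k_miss -
        sum(abs(xs[hits, f] - xs[i, f])) / k_hit
    }
  }
  setNames(w / n, colnames(x))
}

# Nearest-neighbour mixed-type mutual information, naive O(n^2) version.
oracle_mi <- function(x, y, k = 3) {
  n <- nrow(x)
  apply(x, 2, function(v) {
    if (max(v) == min(v)) return(0)
    psi_k <- m_i <- n_xi <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      same <- setdiff(which(y == y[i]), i)
      if (!length(same)) next
      kk <- min(k, length(same))
      dists <- sort(abs(v[same] - v[i]))
      r <- dists[kk]
      psi_k[i] <- kk
      m_i[i] <- sum(abs(v[-i] - v[i]) <= r)
      n_xi[i] <- length(same) + 1
    }
    ok <- !is.na(psi_k)
    mi <- digamma(n) - mean(digamma(n_xi[ok])) + mean(digamma(psi_k[ok])) -
      mean(digamma(pmax(m_i[ok], 1)))
    max(mi, 0)
  })
}

# Cohen's d with pooled population-style standard deviation.
empirical_cohens_d <- function(v, y) {
  v1 <- v[y == 1]; v0 <- v[y == 0]
  sp <- sqrt(((length(v1) - 1) * var(v1) + (length(v0) - 1) * var(v0)) /
               (length(v1) + length(v0) - 2))
  (mean(v1) - mean(v0)) / sp
}

# F1 of the best trivial constant predictor, positive class as positive.
majority_baseline_f1 <- function(y) {
  q <- mean(y == 1)
  2 * q / (1 + q)  # predict-all-positive; predict-all-negative scores 0
}
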