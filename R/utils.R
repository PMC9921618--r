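# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG state without disturbing the caller's
# stream. Everything stochastic in the package funnels through this.
local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a stream-specific 31-bit sub-seed from a base seed.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 7919 + as.double(offset) * 104729) %% 2147483647L)
}

assert_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x != round(x) || x < min) {
    stop(sprintf("'%s' must be a single integer >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}

assert_fraction <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x <= 0 || x >= 1) {
    stop(sprintf("'%s' must lie strictly between 0 and 1", name), call. = FALSE)
  }
  invisible(as.numeric(x))
}

# Stratified fold assignment; guarantees both classes in every training split
# when each class has at least n_folds/... members spread round-robin.
stratified_folds <- function(y, n_folds, seed) {
  y <- as.integer(y)
  folds <- integer(length(y))
  local_seed(seed, {
    for (cls in sort(unique(y))) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  folds
}

# Population standard deviation (divisor n).
sd_pop <- function(x) {
  sqrt(mean((x - mean(x))^2))
}
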