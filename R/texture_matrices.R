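# Grey-level texture matrices on discretized 3D ROIs. All matrices use the
# 26-neighborhood (13 unique direction offsets) and merge counts across
# directions before feature computation.

# 13 canonical 3D direction offsets (one orientation per axis pair).
direction_offsets_3d <- function() {
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  # keep one of each +/- pair: first nonzero component positive
  keep <- apply(offs, 1, function(o) o[which(o != 0)[1]] > 0)
  unname(offs[keep, , drop = FALSE])
}

# Fixed-bin-count discretization of in-mask intensities to 1..n_bins.
# Returns a 3D integer array with NA outside the mask.
discretize_roi <- function(volume_data, mask, n_bins = 32L) {
  vals <- volume_data[mask == 1L]
  lo <- min(vals)
  hi <- max(vals)
  disc <- array(NA_integer_, dim = dim(volume_data))
  if (hi == lo) {
    disc[mask == 1L] <- 1L
  } else {
    b <- pmin(floor((volume_data[mask == 1L] - lo) / (hi - lo) * n_bins) + 1L, n_bins)
    disc[mask == 1L] <- as.integer(b)
  }
  disc
}

# Overlapping sub-array index ranges for an offset along each axis.
offset_ranges <- function(dims, off) {
  lapply(1:3, function(ax) {
    if (off[ax] >= 0) {
      list(a = seq_len(dims[ax] - off[ax]), b = seq_len(dims[ax] - off[ax]) + off[ax])
    } else {
      list(a = seq_len(dims[ax] + off[ax]) - off[ax], b = seq_len(dims[ax] + off[ax]))
    }
  })
}

# Grey-level co-occurrence matrix: symmetric, normalized, counts pooled
# over the 13 directions at distance 1.
glcm_matrix <- function(disc, n_bins = 32L) {
  dims <- dim(disc)
  counts <- matrix(0, n_bins, n_bins)
  for (r in seq_len(nrow(direction_offsets_3d()))) {
    off <- direction_offsets_3d()[r, ]
    rg <- offset_ranges(dims, off)
    a <- disc[rg[[1]]$a, rg[[2]]$a, rg[[3]]$a]
    b <- disc[rg[[1]]$b, rg[[2]]$b, rg[[3]]$b]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    idx <- (a[ok] - 1L) * n_bins + b[ok]
    tab <- tabulate(idx, nbins = n_bins * n_bins)
    counts <- counts + matrix(tab, n_bins, n_bins, byrow = TRUE)
  }
  counts <- counts + t(counts)  # symmetric co-occurrence
  if (sum(counts) == 0) counts[1, 1] <- 1
  counts / sum(counts)
}

# Grey-level run-length matrix: rows = grey level, cols = run length,
# counts pooled over the 13 directions.
glrlm_matrix <- function(disc, n_bins = 32L) {
  dims <- dim(disc)
  nvox <- prod(dims)
  coords <- arrayInd(seq_len(nvox), dims)
  max_run <- max(dims)
  counts <- matrix(0, n_bins, max_run)
  v_flat <- as.vector(disc)
  offs <- direction_offsets_3d()
  for (r in seq_len(nrow(offs))) {
    off <- offs[r, ]
    # backward steps until the line leaves the grid; identifies the line start
    t_ax <- sapply(1:3, function(ax) {
      if (off[ax] == 1) coords[, ax] - 1L
      else if (off[ax] == -1) dims[ax] - coords[, ax]
      else rep.int(nvox, nvox)  # no constraint from this axis
    })
    tpos <- do.call(pmin, as.data.frame(t_ax))
    start <- coords - tpos %o% off
    key <- (start[, 3] - 1) * (dims[1] * dims[2]) + (start[, 2] - 1) * dims[1] + start[, 1]
    ord <- order(key, tpos)
    v <- v_flat[ord]
    k <- key[ord]
    n <- length(v)
    prev_v <- c(NA_integer_, v[-n])
    same_line <- c(FALSE, k[-1] == k[-n])
    cont <- same_line & !is.na(v) & !is.na(prev_v) & (v == prev_v)
    run_id <- cumsum(!cont)
    keep <- !is.na(v)
    if (!any(keep)) next
    lens <- tabulate(run_id[keep])
    gray <- v[!cont]               # first voxel of each run (NA runs included)
    gl <- gray[seq_along(lens)][lens > 0]
    ln <- lens[lens > 0]
    idx <- (gl - 1L) * max_run + ln
    tab <- tabulate(idx, nbins = n_bins * max_run)
    counts <- counts + matrix(tab, n_bins, max_run, byrow = TRUE)
  }
  counts
}

# Grey-level size-zone matrix: zones are 26-connected components of equal
# grey level inside the ROI; rows = grey level, cols = zone size.
glszm_matrix <- function(disc, n_bins = 32L) {
  dims <- dim(disc)
  vox <- which(!is.na(disc))
  nvox <- length(vox)
  pos <- match(seq_len(prod(dims)), vox)  # flat index -> voxel rank
  coords <- arrayInd(vox, dims)
  offs <- direction_offsets_3d()
  ea <- integer(0); eb <- integer(0)
  for (r in seq_len(nrow(offs))) {
    off <- offs[r, ]
    nb <- sweep(coords, 2, off, "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
          nb[, 2] >= 1 & nb[, 2] <= dims[2] &
          nb[, 3] >= 1 & nb[, 3] <= dims[3]
    flat <- (nb[ok, 3] - 1) * dims[1] * dims[2] + (nb[ok, 2] - 1) * dims[1] + nb[ok, 1]
    nb_rank <- pos[flat]
    src <- which(ok)
    good <- !is.na(nb_rank) & disc[vox[src]] == disc[vox[nb_rank]]
    ea <- c(ea, src[good]); eb <- c(eb, nb_rank[good])
  }
  el <- cbind(ea, eb)
  storage.mode(el) <- "double"
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nvox - igraph::vcount(g)))
  comp <- igraph::components(g)$membership[seq_len(nvox)]
  sizes <- tabulate(comp)                      # zone sizes by component id
  gray <- disc[vox][match(seq_along(sizes), comp)]  # grey level per component
  max_size <- max(sizes)
  idx <- (gray - 1L) * max_size + sizes
  tab <- tabulate(idx, nbins = n_bins * max_size)
  matrix(tab, n_bins, max_size, byrow = TRUE)
}

# Neighbouring grey-tone difference matrix ingredients: per grey level i,
# p_i (occurrence probability) and s_i (summed absolute difference from the
# mean of in-ROI 26-neighbors).
ngtdm_table <- function(disc, n_bins = 32L) {
  dims <- dim(disc)
  valid <- !is.na(disc)
  nb_sum <- array(0, dim = dims)
  nb_cnt <- array(0L, dim = dims)
  offs <- direction_offsets_3d()
  for (r in seq_len(nrow(offs))) {
    for (sgn in c(1, -1)) {
      off <- offs[r, ] * sgn
      rg <- offset_ranges(dims, off)
      a <- rg[[1]]$a; b <- rg[[1]]$b
      a2 <- rg[[2]]$a; b2 <- rg[[2]]$b
      a3 <- rg[[3]]$a; b3 <- rg[[3]]$b
      nbv <- disc[b, b2, b3]
      ok <- !is.na(nbv)
      add <- ifelse(ok, nbv, 0L)
      nb_sum[a, a2, a3] <- nb_sum[a, a2, a3] + add
      nb_cnt[a, a2, a3] <- nb_cnt[a, a2, a3] + ok
    }
  }
  use <- valid & nb_cnt > 0L
  lv <- disc[use]
  abar <- nb_sum[use] / nb_cnt[use]
  n_i <- tabulate(lv, nbins = n_bins)
  s_i <- vapply(seq_len(n_bins), function(i) sum(abs(i - abar)[lv == i]), numeric(1))
  list(n = n_i, s = s_i, N = sum(n_i))
}

# Grey-level dependence matrix: dependence of a voxel = number of 26-
# neighbors inside the ROI with identical discretized level (alpha = 0);
# rows = grey level, cols = dependence + 1.
gldm_matrix <- function(disc, n_bins = 32L) {
  dims <- dim(disc)
  dep <- array(0L, dim = dims)
  offs <- direction_offsets_3d()
  for (r in seq_len(nrow(offs))) {
    for (sgn in c(1, -1)) {
      off <- offs[r, ] * sgn
      rg <- offset_ranges(dims, off)
      a <- disc[rg[[1]]$a, rg[[2]]$a, rg[[3]]$a]
      b <- disc[rg[[1]]$b, rg[[2]]$b, rg[[3]]$b]
      same <- !is.na(a) & !is.na(b) & a == b
      sub <- dep[rg[[1]]$a, rg[[2]]$a, rg[[3]]$a]
      sub[same] <- sub[same] + 1L
      dep[rg[[1]]$a, rg[[2]]$a, rg[[3]]$a] <- sub
    }
  }
  inmask <- !is.na(disc)
  gl <- disc[inmask]
  dp <- dep[inmask] + 1L
  max_dep <- max(dp)
  idx <- (gl - 1L) * max_dep + dp
  tab <- tabulate(idx, nbins = n_bins * max_dep)
  matrix(tab, n_bins, max_dep, byrow = TRUE)
}
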