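# Feature formulas per family, IBSI-style definitions. Each function
# returns a named numeric vector; names follow the radiomics convention
# (CamelCase feature names within a lowercase family).

firstorder_features <- function(vals, voxel_volume, n_bins = 32L) {
  n <- length(vals)
  mu <- mean(vals)
  p10 <- unname(quantile(vals, 0.10, type = 7))
  p90 <- unname(quantile(vals, 0.90, type = 7))
  mid <- vals[vals >= p10 & vals <= p90]
  # discretized histogram probabilities for entropy/uniformity
  rng <- range(vals)
  if (diff(rng) == 0) {
    pr <- 1
  } else {
    b <- pmin(floor((vals - rng[1]) / diff(rng) * n_bins) + 1L, n_bins)
    pr <- tabulate(b, n_bins) / n
    pr <- pr[pr > 0]
  }
  m2 <- mean((vals - mu)^2)
  m3 <- mean((vals - mu)^3)
  m4 <- mean((vals - mu)^4)
  c(Energy = sum(vals^2),
    TotalEnergy = voxel_volume * sum(vals^2),
    Entropy = -sum(pr * log2(pr)),
    Minimum = min(vals),
    `10Percentile` = p10,
    `90Percentile` = p90,
    Maximum = max(vals),
    Mean = mu,
    Median = median(vals),
    InterquartileRange = unname(quantile(vals, 0.75) - quantile(vals, 0.25)),
    Range = diff(rng),
    MeanAbsoluteDeviation = mean(abs(vals - mu)),
    RobustMeanAbsoluteDeviation = if (length(mid)) mean(abs(mid - mean(mid))) else 0,
    RootMeanSquared = sqrt(mean(vals^2)),
    Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    Variance = m2,
    Uniformity = sum(pr^2))
}

# Shape descriptors of the binary ROI. Surface area is the voxel-face
# surface (exposed faces times face area); axis lengths come from the
# principal components of the physical voxel coordinates; diameters are
# maximal pairwise distances over boundary voxels.
shape_features <- function(mask, spacing) {
  dims <- dim(mask)
  vox <- which(mask == 1L)
  n <- length(vox)
  coords <- arrayInd(vox, dims)
  voxvol <- prod(spacing)

  # exposed faces per axis
  surf <- 0
  boundary <- rep(FALSE, n)
  pos <- match(seq_len(prod(dims)), vox)
  for (ax in 1:3) {
    for (sgn in c(-1L, 1L)) {
      nb <- coords
      nb[, ax] <- nb[, ax] + sgn
      inside <- nb[, ax] >= 1L & nb[, ax] <= dims[ax]
      flat <- (nb[, 3] - 1) * dims[1] * dims[2] + (nb[, 2] - 1) * dims[1] + nb[, 1]
      covered <- inside & !is.na(pos[ifelse(inside, flat, 1L)])
      exposed <- !covered
      face_area <- voxvol / spacing[ax]
      surf <- surf + sum(exposed) * face_area
      boundary <- boundary | exposed
    }
  }

  phys <- sweep(coords, 2, spacing, "*")
  cen <- colMeans(phys)
  cc <- sweep(phys, 2, cen)
  ev <- if (n > 1) sort(eigen(crossprod(cc) / n, symmetric = TRUE)$values,
                        decreasing = TRUE) else c(0, 0, 0)
  ev <- pmax(ev, 0)
  axis_len <- 4 * sqrt(ev)

  bc <- phys[boundary, , drop = FALSE]
  max_diam <- function(pts) {
    if (nrow(pts) < 2) return(0)
    max(dist(pts))
  }
  d3 <- max_diam(bc)
  d_slice <- max_diam(bc[, 1:2, drop = FALSE])   # in-plane (rows x cols)
  d_col <- max_diam(bc[, c(1, 3), drop = FALSE])
  d_row <- max_diam(bc[, c(2, 3), drop = FALSE])

  vol <- n * voxvol
  sphericity <- if (surf > 0) (pi^(1 / 3) * (6 * vol)^(2 / 3)) / surf else 0

  c(MeshVolume = vol,
    VoxelVolume = vol,
    SurfaceArea = surf,
    SurfaceVolumeRatio = if (vol > 0) surf / vol else 0,
    Sphericity = sphericity,
    MajorAxisLength = axis_len[1],
    MinorAxisLength = axis_len[2],
    LeastAxisLength = axis_len[3],
    Elongation = if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 0,
    Flatness = if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 0,
    Maximum3DDiameter = d3,
    Maximum2DDiameterSlice = d_slice,
    Maximum2DDiameterColumn = d_col,
    Maximum2DDiameterRow = d_row)
}

glcm_features <- function(P) {
  ng <- nrow(P)
  i <- row(P)
  j <- col(P)
  px <- rowSums(P)
  py <- colSums(P)
  mux <- sum(seq_len(ng) * px)
  muy <- sum(seq_len(ng) * py)
  sigx <- sqrt(sum((seq_len(ng) - mux)^2 * px))
  sigy <- sqrt(sum((seq_len(ng) - muy)^2 * py))
  # diagonal and cross-diagonal distributions
  pxy_sum <- vapply(2:(2 * ng), function(k) sum(P[i + j == k]), numeric(1))
  ksum <- 2:(2 * ng)
  pxy_diff <- vapply(0:(ng - 1), function(k) sum(P[abs(i - j) == k]), numeric(1))
  kdiff <- 0:(ng - 1)
  eps <- 2.2e-16
  HX <- -sum(px[px > 0] * log2(px[px > 0]))
  HY <- -sum(py[py > 0] * log2(py[py > 0]))
  HXY <- -sum(P[P > 0] * log2(P[P > 0]))
  pxpy <- outer(px, py)
  HXY1 <- -sum(P * log2(pxpy + eps))
  HXY2 <- -sum(pxpy[pxpy > 0] * log2(pxpy[pxpy > 0]))
  da <- sum(kdiff * pxy_diff)

  # MCC: square root of the second-largest eigenvalue of Q
  mcc <- tryCatch({
    nz <- which(px > 0)
    Pn <- P[nz, nz, drop = FALSE]
    Q <- (Pn / px[nz]) %*% t(Pn / matrix(py[nz], nrow(Pn), ncol(Pn), byrow = TRUE))
    evq <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    if (length(evq) >= 2) sqrt(max(evq[2], 0)) else 1
  }, error = function(e) 1)

  corr <- if (sigx * sigy > 0) {
    (sum(i * j * P) - mux * muy) / (sigx * sigy)
  } else 1

  c(Autocorrelation = sum(i * j * P),
    ClusterProminence = sum((i + j - mux - muy)^4 * P),
    ClusterShade = sum((i + j - mux - muy)^3 * P),
    ClusterTendency = sum((i + j - mux - muy)^2 * P),
    Contrast = sum((i - j)^2 * P),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = -sum(pxy_diff[pxy_diff > 0] * log2(pxy_diff[pxy_diff > 0])),
    DifferenceVariance = sum((kdiff - da)^2 * pxy_diff),
    Id = sum(P / (1 + abs(i - j))),
    Idm = sum(P / (1 + (i - j)^2)),
    Idmn = sum(P / (1 + (i - j)^2 / ng^2)),
    Idn = sum(P / (1 + abs(i - j) / ng)),
    Imc1 = if (max(HX, HY) > 0) (HXY - HXY1) / max(HX, HY) else 0,
    Imc2 = sqrt(pmax(1 - exp(-2 * (HXY2 - HXY)), 0)),
    InverseVariance = sum((P / (i - j)^2)[i != j]),
    JointAverage = mux,
    JointEnergy = sum(P^2),
    JointEntropy = HXY,
    MCC = mcc,
    MaximumProbability = max(P),
    SumAverage = sum(ksum * pxy_sum),
    SumEntropy = -sum(pxy_sum[pxy_sum > 0] * log2(pxy_sum[pxy_sum > 0])),
    SumSquares = sum((i - mux)^2 * P))
}

glrlm_features <- function(P, n_voxels) {
  Nr <- sum(P)
  if (Nr == 0) Nr <- 1
  i <- row(P)
  j <- col(P)
  p <- P / Nr
  ri <- rowSums(P)
  rj <- colSums(P)
  mu_i <- sum(row(P) * p)
  mu_j <- sum(col(P) * p)
  c(ShortRunEmphasis = sum(P / j^2) / Nr,
    LongRunEmphasis = sum(P * j^2) / Nr,
    GrayLevelNonUniformity = sum(ri^2) / Nr,
    GrayLevelNonUniformityNormalized = sum(ri^2) / Nr^2,
    RunLengthNonUniformity = sum(rj^2) / Nr,
    RunLengthNonUniformityNormalized = sum(rj^2) / Nr^2,
    RunPercentage = Nr / n_voxels,
    GrayLevelVariance = sum((i - mu_i)^2 * p),
    RunVariance = sum((j - mu_j)^2 * p),
    RunEntropy = -sum(p[p > 0] * log2(p[p > 0])),
    LowGrayLevelRunEmphasis = sum(P / i^2) / Nr,
    HighGrayLevelRunEmphasis = sum(P * i^2) / Nr,
    ShortRunLowGrayLevelEmphasis = sum(P / (i^2 * j^2)) / Nr,
    ShortRunHighGrayLevelEmphasis = sum(P * i^2 / j^2) / Nr,
    LongRunLowGrayLevelEmphasis = sum(P * j^2 / i^2) / Nr,
    LongRunHighGrayLevelEmphasis = sum(P * i^2 * j^2) / Nr)
}

glszm_features <- function(P, n_voxels) {
  Nz <- sum(P)
  if (Nz == 0) Nz <- 1
  i <- row(P)
  j <- col(P)
  p <- P / Nz
  zi <- rowSums(P)
  zj <- colSums(P)
  mu_i <- sum(i * p)
  mu_j <- sum(j * p)
  c(SmallAreaEmphasis = sum(P / j^2) / Nz,
    LargeAreaEmphasis = sum(P * j^2) / Nz,
    GrayLevelNonUniformity = sum(zi^2) / Nz,
    GrayLevelNonUniformityNormalized = sum(zi^2) / Nz^2,
    SizeZoneNonUniformity = sum(zj^2) / Nz,
    SizeZoneNonUniformityNormalized = sum(zj^2) / Nz^2,
    ZonePercentage = Nz / n_voxels,
    GrayLevelVariance = sum((i - mu_i)^2 * p),
    ZoneVariance = sum((j - mu_j)^2 * p),
    ZoneEntropy = -sum(p[p > 0] * log2(p[p > 0])),
    LowGrayLevelZoneEmphasis = sum(P / i^2) / Nz,
    HighGrayLevelZoneEmphasis = sum(P * i^2) / Nz,
    SmallAreaLowGrayLevelEmphasis = sum(P / (i^2 * j^2)) / Nz,
    SmallAreaHighGrayLevelEmphasis = sum(P * i^2 / j^2) / Nz,
    LargeAreaLowGrayLevelEmphasis = sum(P * j^2 / i^2) / Nz,
    LargeAreaHighGrayLevelEmphasis = sum(P * i^2 * j^2) / Nz)
}

ngtdm_features <- function(tab) {
  n_i <- tab$n
  s_i <- tab$s
  N <- tab$N
  p_i <- n_i / N
  act <- which(p_i > 0)
  Ngp <- length(act)
  lev <- seq_along(p_i)
  coars_den <- sum(p_i * s_i)
  contrast <- if (Ngp > 1) {
    (sum(outer(p_i[act], p_i[act]) * outer(lev[act], lev[act], "-")^2) /
       (Ngp * (Ngp - 1))) * (sum(s_i) / N)
  } else 0
  busy_den <- sum(abs(outer(lev[act] * p_i[act], lev[act] * p_i[act], "-")))
  complexity <- if (N > 0) {
    pi_si <- p_i[act] * N  # n_i
    sum(abs(outer(lev[act], lev[act], "-")) *
          outer(p_i[act] * s_i[act], p_i[act] * s_i[act], "+") /
          outer(p_i[act], p_i[act], "+")) / N
  } else 0
  strength <- if (sum(s_i) > 0) {
    sum(outer(p_i[act], p_i[act], "+") * outer(lev[act], lev[act], "-")^2) / sum(s_i)
  } else 0
  c(Coarseness = if (coars_den > 0) 1 / coars_den else 1e6,
    Contrast = contrast,
    Busyness = if (busy_den > 0) coars_den / busy_den else 0,
    Complexity = complexity,
    Strength = strength)
}

gldm_features <- function(P) {
  Nz <- sum(P)
  if (Nz == 0) Nz <- 1
  i <- row(P)
  j <- col(P)
  p <- P / Nz
  gi <- rowSums(P)
  dj <- colSums(P)
  mu_i <- sum(i * p)
  mu_j <- sum(j * p)
  c(SmallDependenceEmphasis = sum(P / j^2) / Nz,
    LargeDependenceEmphasis = sum(P * j^2) / Nz,
    GrayLevelNonUniformity = sum(gi^2) / Nz,
    DependenceNonUniformity = sum(dj^2) / Nz,
    DependenceNonUniformityNormalized = sum(dj^2) / Nz^2,
    GrayLevelVariance = sum((i - mu_i)^2 * p),
    DependenceVariance = sum((j - mu_j)^2 * p),
    DependenceEntropy = -sum(p[p > 0] * log2(p[p > 0])),
    LowGrayLevelEmphasis = sum(P / i^2) / Nz,
    HighGrayLevelEmphasis = sum(P * i^2) / Nz,
    SmallDependenceLowGrayLevelEmphasis = sum(P / (i^2 * j^2)) / Nz,
    SmallDependenceHighGrayLevelEmphasis = sum(P * i^2 / j^2) / Nz,
    LargeDependenceLowGrayLevelEmphasis = sum(P * j^2 / i^2) / Nz,
    LargeDependenceHighGrayLevelEmphasis = sum(P * i^2 * j^2) / Nz)
}
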