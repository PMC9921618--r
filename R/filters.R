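# Image filters feeding the filtered-channel feature families: separable
# 1D convolution primitives, single-level undecimated 3D wavelet channels,
# and Laplacian-of-Gaussian band-pass responses.

# Convolve a 3D array with a 1D kernel along one axis, symmetric (reflect)
# boundary. Implemented as a sum of shifted copies: kernels are short, so
# this vectorizes well.
conv_axis <- function(a, kernel, axis) {
  d <- dim(a)
  n <- d[axis]
  half <- (length(kernel) - 1L) / 2
  offsets <- seq_along(kernel) - 1L - half
  # reflected index lookup for each offset
  out <- array(0, dim = d)
  base <- seq_len(n)
  for (t in seq_along(kernel)) {
    idx <- base + offsets[t]
    # reflect at the edges (symmetric padding without edge duplication fallback)
    idx <- ifelse(idx < 1L, 2L - idx, idx)
    idx <- ifelse(idx > n, 2L * n - idx, idx)
    idx <- pmin(pmax(idx, 1L), n)
    shifted <- switch(axis,
                      a[idx, , , drop = FALSE],
                      a[, idx, , drop = FALSE],
                      a[, , idx, drop = FALSE])
    out <- out + kernel[t] * shifted
  }
  out
}

conv_separable <- function(a, kernels) {
  for (axis in 1:3) a <- conv_axis(a, kernels[[axis]], axis)
  a
}

gaussian_kernel_1d <- function(sigma_vox, truncate = 3) {
  if (sigma_vox <= 0) return(1)
  half <- max(1L, ceiling(truncate * sigma_vox))
  x <- seq(-half, half)
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# Second-derivative-of-Gaussian kernel, used on one axis of the LoG filter.
gaussian_d2_kernel_1d <- function(sigma_vox, truncate = 3) {
  half <- max(2L, ceiling(truncate * sigma_vox))
  x <- seq(-half, half)
  g <- exp(-x^2 / (2 * sigma_vox^2))
  g <- g / sum(g)
  k <- g * (x^2 - sigma_vox^2) / sigma_vox^4
  k - mean(k)  # zero-sum: flat regions respond 0
}

gaussian_smooth_3d <- function(a, sigma_vox) {
  conv_separable(a, lapply(sigma_vox, gaussian_kernel_1d))
}

#' Laplacian-of-Gaussian filtered volume
#'
#' Band-pass response emphasizing structure at scale `sigma_mm`; the sigma
#' is given in millimetres and converted per-axis to voxels via the volume
#' spacing. Computed as the sum over axes of the second
#' Gaussian-derivative response (separable implementation).
#'
#' @param volume a [volume_grid()].
#' @param sigma_mm filter scale in mm.
#' @return A [volume_grid()] with the filtered intensities.
#' @export
log_filter <- function(volume, sigma_mm) {
  stopifnot(inherits(volume, "volume_grid"), sigma_mm > 0)
  a <- volume$data
  sig <- sigma_mm / volume$spacing
  out <- array(0, dim = dim(a))
  for (axis in 1:3) {
    kernels <- lapply(1:3, function(ax) {
      if (ax == axis) gaussian_d2_kernel_1d(sig[ax]) else gaussian_kernel_1d(sig[ax])
    })
    out <- out + conv_separable(a, kernels)
  }
  # scale-normalized response (sigma^2), standard for blob detection
  volume_grid(out * sigma_mm^2, volume$spacing)
}

# Haar analysis filters, normalized so the LLL channel preserves the mean.
wavelet_kernels <- function() {
  list(L = c(1, 1) / sqrt(2), H = c(1, -1) / sqrt(2))
}

# One-axis convolution with a 2-tap kernel (offsets 0 and +1, reflect edge).
conv_axis_2tap <- function(a, kernel, axis) {
  d <- dim(a)
  n <- d[axis]
  idx2 <- c(seq_len(n - 1L) + 1L, n)  # neighbor index, clamped at edge
  shifted <- switch(axis,
                    a[idx2, , , drop = FALSE],
                    a[, idx2, , drop = FALSE],
                    a[, , idx2, drop = FALSE])
  kernel[1] * a + kernel[2] * shifted
}

#' Single-level 3D wavelet decomposition (undecimated)
#'
#' Produces the eight sub-band channels `LLL ... HHH` of a one-level
#' separable Haar decomposition; `L`/`H` denote the low-/high-pass filter
#' applied along the first/second/third array axis respectively. Channels
#' are not downsampled, so each response stays congruent with the input
#' grid and mask.
#'
#' @param volume a [volume_grid()].
#' @param channels character vector of sub-band names to return.
#' @return Named list of [volume_grid()] objects, one per channel.
#' @export
wavelet_channels <- function(volume, channels = wavelet_channel_names()) {
  stopifnot(inherits(volume, "volume_grid"))
  bad <- setdiff(channels, wavelet_channel_names())
  if (length(bad)) stop("unknown wavelet channel(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  k <- wavelet_kernels()
  out <- list()
  for (ch in channels) {
    letters3 <- strsplit(ch, "")[[1]]
    a <- volume$data
    for (axis in 1:3) a <- conv_axis_2tap(a, k[[letters3[axis]]], axis)
    out[[ch]] <- volume_grid(a, volume$spacing)
  }
  out
}

#' The eight single-level wavelet channel names
#' @return Character vector `c("LLL", ..., "HHH")`.
#' @export
wavelet_channel_names <- function() {
  c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")
}
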