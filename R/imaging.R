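# Volume preprocessing: intensity normalization and peak-phase selection.

#' Construct a volume grid
#'
#' A 3D intensity array plus its voxel spacing in mm. NIfTI volumes read
#' with [read_volume()] come back as this class.
#'
#' @param data 3D numeric array of intensities.
#' @param spacing voxel spacing in mm (triple, positive).
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(data, spacing = c(1, 1, 1)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("'data' must be a 3D array", call. = FALSE)
  if (any(!is.finite(data))) stop("volume intensities must be finite", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop("'spacing' must be three positive lengths (mm)", call. = FALSE)
  }
  structure(list(data = data, spacing = spacing), class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("volume_grid: %s voxels, spacing %s mm\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = "x")))
  invisible(x)
}

#' Read a NIfTI volume
#' @param path NIfTI file.
#' @return A [volume_grid()].
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)[1:3]
  volume_grid(array(as.numeric(img), dim = dim(img)[1:3]), spacing)
}

#' Read a binary NIfTI mask
#' @param path NIfTI file holding values in \{0, 1\}.
#' @return Integer 3D array.
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  m <- array(as.numeric(img), dim = dim(img)[1:3])
  if (!all(m %in% c(0, 1))) stop("mask must be strictly binary {0,1}", call. = FALSE)
  array(as.integer(m), dim = dim(m))
}

check_mask <- function(volume, mask) {
  if (!identical(dim(volume$data), dim(mask))) {
    stop("mask and volume shapes differ", call. = FALSE)
  }
  if (!any(mask == 1L)) stop("mask has no foreground voxel", call. = FALSE)
  invisible(TRUE)
}

#' Normalize volume intensities to zero mean and unit variance
#'
#' Centers all grey values at their mean and scales by the population
#' standard deviation of all grey values in the volume, the standard
#' whole-image normalization applied to T2 and post-contrast series before
#' feature extraction.
#'
#' @param volume a [volume_grid()].
#' @return A [volume_grid()] with mean 0 and (population) sd 1.
#' @export
normalize_intensity <- function(volume) {
  stopifnot(inherits(volume, "volume_grid"))
  v <- volume$data
  s <- sd_pop(as.vector(v))
  if (s == 0) stop("constant volume: standard deviation is zero", call. = FALSE)
  volume_grid((v - mean(v)) / s, volume$spacing)
}

#' Select the subtraction phase with maximal mean ROI intensity
#'
#' Radiomic features of the dynamic series are extracted from the single
#' subtraction phase whose mean signal inside the lesion ROI is highest.
#' Ties resolve to the lowest phase index.
#'
#' @param series list of [volume_grid()] phases (or 3D arrays).
#' @param mask binary 3D array congruent with each phase.
#' @return 1-based index of the peak phase.
#' @export
select_peak_subtraction_phase <- function(series, mask) {
  if (!length(series)) stop("empty phase series", call. = FALSE)
  means <- vapply(series, function(v) {
    d <- if (inherits(v, "volume_grid")) v$data else as.array(v)
    if (!identical(dim(d), dim(mask))) stop("mask and volume shapes differ", call. = FALSE)
    if (!any(mask == 1L)) stop("mask has no foreground voxel", call. = FALSE)
    mean(d[mask == 1L])
  }, numeric(1))
  which.max(means)  # which.max takes the first maximum: lowest index on ties
}
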