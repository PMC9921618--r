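# Feature extraction orchestration: which families on which image
# channels, with the naming convention
#   <modality>_<filter>_<family>_<FeatureName>
# e.g. T2_wavelet-LLH_firstorder_Skewness.

FAMILY_SIZES <- c(shape = 14L, firstorder = 18L, glcm = 24L, glrlm = 16L,
                  glszm = 16L, ngtdm = 5L, gldm = 14L)

family_feature_names <- function(family) {
  switch(family,
    shape = c("MeshVolume", "VoxelVolume", "SurfaceArea", "SurfaceVolumeRatio",
              "Sphericity", "MajorAxisLength", "MinorAxisLength",
              "LeastAxisLength", "Elongation", "Flatness", "Maximum3DDiameter",
              "Maximum2DDiameterSlice", "Maximum2DDiameterColumn",
              "Maximum2DDiameterRow"),
    firstorder = c("Energy", "TotalEnergy", "Entropy", "Minimum",
                   "10Percentile", "90Percentile", "Maximum", "Mean", "Median",
                   "InterquartileRange", "Range", "MeanAbsoluteDeviation",
                   "RobustMeanAbsoluteDeviation", "RootMeanSquared",
                   "Skewness", "Kurtosis", "Variance", "Uniformity"),
    glcm = c("Autocorrelation", "ClusterProminence", "ClusterShade",
             "ClusterTendency", "Contrast", "Correlation", "DifferenceAverage",
             "DifferenceEntropy", "DifferenceVariance", "Id", "Idm", "Idmn",
             "Idn", "Imc1", "Imc2", "InverseVariance", "JointAverage",
             "JointEnergy", "JointEntropy", "MCC", "MaximumProbability",
             "SumAverage", "SumEntropy", "SumSquares"),
    glrlm = c("ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
              "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
              "RunLengthNonUniformityNormalized", "RunPercentage",
              "GrayLevelVariance", "RunVariance", "RunEntropy",
              "LowGrayLevelRunEmphasis", "HighGrayLevelRunEmphasis",
              "ShortRunLowGrayLevelEmphasis", "ShortRunHighGrayLevelEmphasis",
              "LongRunLowGrayLevelEmphasis", "LongRunHighGrayLevelEmphasis"),
    glszm = c("SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
              "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
              "SizeZoneNonUniformityNormalized", "ZonePercentage",
              "GrayLevelVariance", "ZoneVariance", "ZoneEntropy",
              "LowGrayLevelZoneEmphasis", "HighGrayLevelZoneEmphasis",
              "SmallAreaLowGrayLevelEmphasis", "SmallAreaHighGrayLevelEmphasis",
              "LargeAreaLowGrayLevelEmphasis", "LargeAreaHighGrayLevelEmphasis"),
    ngtdm = c("Coarseness", "Contrast", "Busyness", "Complexity", "Strength"),
    gldm = c("SmallDependenceEmphasis", "LargeDependenceEmphasis",
             "GrayLevelNonUniformity", "DependenceNonUniformity",
             "DependenceNonUniformityNormalized", "GrayLevelVariance",
             "DependenceVariance", "DependenceEntropy", "LowGrayLevelEmphasis",
             "HighGrayLevelEmphasis", "SmallDependenceLowGrayLevelEmphasis",
             "SmallDependenceHighGrayLevelEmphasis",
             "LargeDependenceLowGrayLevelEmphasis",
             "LargeDependenceHighGrayLevelEmphasis"),
    stop("unknown feature family: ", family, call. = FALSE))
}

#' Construct a radiomic extraction profile
#'
#' Describes which feature families are computed on which image channels.
#' The default profile computes all seven families on the
#' original image, and first-order plus the five texture families on the
#' eight single-level wavelet channels and four Laplacian-of-Gaussian
#' scales (sigma 2-5 mm), with a two-feature exclusion list applied to the
#' filtered channels only. Under these defaults each filtered channel
#' yields 91 features (18 first-order + 73 textural), hence 728 wavelet +
#' 364 LoG = 1092 filtered features in total.
#'
#' The default exclusions are `glcm_SumAverage` (duplicates `JointAverage`
#' on a symmetric co-occurrence matrix, up to a factor of two) and
#' `glcm_MCC` (frequently degenerate on small filtered-channel ROIs).
#'
#' @param families feature families for the original image; subset of
#'   `shape, firstorder, glcm, glrlm, glszm, ngtdm, gldm`.
#' @param wavelet_channels wavelet sub-bands to filter with; `character(0)`
#'   disables the wavelet channels.
#' @param log_sigmas_mm LoG scales in mm; `numeric(0)` disables LoG.
#' @param exclusions feature names (`family_Feature`) dropped from the
#'   filtered-image families.
#' @param n_bins fixed bin count for grey-level discretization.
#' @return An object of class `extraction_profile`.
#' @export
extraction_profile <- function(families = names(FAMILY_SIZES),
                               wavelet_channels = wavelet_channel_names(),
                               log_sigmas_mm = c(2, 3, 4, 5),
                               exclusions = c("glcm_SumAverage", "glcm_MCC"),
                               n_bins = 32L) {
  bad <- setdiff(families, names(FAMILY_SIZES))
  if (length(bad)) stop("unknown family: ", paste(bad, collapse = ", "), call. = FALSE)
  bad <- setdiff(wavelet_channels, wavelet_channel_names())
  if (length(bad)) stop("unknown wavelet channel: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (any(log_sigmas_mm <= 0)) stop("LoG sigmas must be positive", call. = FALSE)
  for (ex in exclusions) {
    parts <- strsplit(ex, "_", fixed = TRUE)[[1]]
    if (length(parts) != 2L || !parts[1] %in% names(FAMILY_SIZES) ||
        !parts[2] %in% family_feature_names(parts[1])) {
      stop("unknown feature in exclusion list: ", ex, call. = FALSE)
    }
  }
  assert_count(n_bins, "n_bins", min = 2L)
  structure(list(families = families,
                 wavelet_channels = wavelet_channels,
                 log_sigmas_mm = as.numeric(log_sigmas_mm),
                 exclusions = exclusions,
                 n_bins = as.integer(n_bins)),
            class = "extraction_profile")
}

log_channel_name <- function(sigma_mm) {
  sprintf("log-sigma-%s-mm-3D", gsub(".", "-", sprintf("%.1f", sigma_mm), fixed = TRUE))
}

# Families computed on filtered channels: every enabled intensity-based
# family (shape is geometry-only and stays on the original image).
filtered_families <- function(profile) {
  setdiff(profile$families, "shape")
}

# Count of features per filtered channel after exclusions.
per_channel_count <- function(profile) {
  fams <- filtered_families(profile)
  total <- sum(FAMILY_SIZES[fams])
  excl_fams <- vapply(strsplit(profile$exclusions, "_", fixed = TRUE), `[`, "", 1)
  total - sum(excl_fams %in% fams)
}

#' Closed-form feature counts per family for a profile
#'
#' Predicts, without running the extraction, how many features
#' [extract_features()] returns for each family and channel group. Under
#' the default profile: 14 shape, 18 first-order, 75 original textural,
#' 728 wavelet, 364 LoG, 1092 filtered in total.
#'
#' @param profile an [extraction_profile()].
#' @return Named integer vector with one entry per enabled original-image
#'   family plus `wavelet`, `log`, `filtered_total` and `total`.
#' @export
feature_count_by_family <- function(profile) {
  stopifnot(inherits(profile, "extraction_profile"))
  counts <- FAMILY_SIZES[profile$families]
  if (!length(counts)) counts <- integer(0)
  per_ch <- per_channel_count(profile)
  wav <- length(profile$wavelet_channels) * per_ch
  lg <- length(profile$log_sigmas_mm) * per_ch
  out <- c(counts, wavelet = wav, log = lg,
           filtered_total = wav + lg,
           total = sum(counts) + wav + lg)
  storage.mode(out) <- "integer"
  out
}

# All intensity-based features of one image channel.
channel_features <- function(volume_data, mask, spacing, families, n_bins,
                             exclusions = character()) {
  vals <- volume_data[mask == 1L]
  out <- numeric(0)
  disc <- NULL
  need_disc <- any(families %in% c("glcm", "glrlm", "glszm", "ngtdm", "gldm"))
  if (need_disc) disc <- discretize_roi(volume_data, mask, n_bins)
  nvox <- sum(mask == 1L)
  for (fam in families) {
    vec <- switch(fam,
      firstorder = firstorder_features(vals, prod(spacing), n_bins),
      glcm = glcm_features(glcm_matrix(disc, n_bins)),
      glrlm = glrlm_features(glrlm_matrix(disc, n_bins), nvox),
      glszm = glszm_features(glszm_matrix(disc, n_bins), nvox),
      ngtdm = ngtdm_features(ngtdm_table(disc, n_bins)),
      gldm = gldm_features(gldm_matrix(disc, n_bins)))
    names(vec) <- paste0(fam, "_", names(vec))
    out <- c(out, vec)
  }
  out[setdiff(names(out), exclusions)]
}

#' Extract radiomic features from a volume and ROI mask
#'
#' Computes the enabled feature families on the original image (shape
#' features from the mask geometry alone) and first-order plus texture
#' families on every enabled wavelet channel and LoG scale. Names follow
#' `<modality>_<filter>_<family>_<Feature>`; an empty `modality_tag` drops
#' the modality prefix.
#'
#' @param volume a [volume_grid()].
#' @param mask binary 3D array congruent with `volume`.
#' @param profile an [extraction_profile()].
#' @param modality_tag modality label prefixed to every feature name
#'   (e.g. `"T2"`, `"PC"`, `"SUB"`, `"ADC"`), or `""` for none.
#' @return Named numeric vector of features (a feature vector); all values
#'   finite, names unique.
#' @export
extract_features <- function(volume, mask, profile = extraction_profile(),
                             modality_tag = "") {
  stopifnot(inherits(volume, "volume_grid"), inherits(profile, "extraction_profile"))
  check_mask(volume, mask)
  tag <- if (nzchar(modality_tag)) paste0(modality_tag, "_") else ""
  out <- numeric(0)

  intensity_fams <- filtered_families(profile)
  if ("shape" %in% profile$families) {
    v <- shape_features(mask, volume$spacing)
    names(v) <- paste0(tag, "original_shape_", names(v))
    out <- c(out, v)
  }
  if (length(intensity_fams)) {
    v <- channel_features(volume$data, mask, volume$spacing, intensity_fams,
                          profile$n_bins)
    names(v) <- paste0(tag, "original_", names(v))
    out <- c(out, v)
  }
  if (length(intensity_fams) && length(profile$wavelet_channels)) {
    wavs <- wavelet_channels(volume, profile$wavelet_channels)
    for (ch in names(wavs)) {
      v <- channel_features(wavs[[ch]]$data, mask, volume$spacing,
                            intensity_fams, profile$n_bins, profile$exclusions)
      names(v) <- paste0(tag, "wavelet-", ch, "_", names(v))
      out <- c(out, v)
    }
  }
  if (length(intensity_fams)) {
    for (sigma in profile$log_sigmas_mm) {
      filt <- log_filter(volume, sigma)
      v <- channel_features(filt$data, mask, volume$spacing, intensity_fams,
                            profile$n_bins, profile$exclusions)
      names(v) <- paste0(tag, log_channel_name(sigma), "_", names(v))
      out <- c(out, v)
    }
  }
  if (anyDuplicated(names(out))) stop("internal: duplicate feature names", call. = FALSE)
  bad <- !is.finite(out)
  if (any(bad)) out[bad] <- 0  # degenerate channels (e.g. flat response) -> 0
  out
}
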