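# Synthetic data: feature tables with planted signal, and dynamic lesion
# phantoms. Both give every downstream stage a desk-scale test surface with
# known ground truth.

#' Specification of a synthetic feature table
#'
#' Describes a samples-by-features table with a planted binary signal:
#' `n_informative` features whose class means differ by `effect_size`
#' standard deviations (Cohen's d), each optionally accompanied by
#' `n_redundant` correlated copies, the remainder pure standard-normal
#' noise. The defaults mirror a small radiomic cohort: about 80 lesions,
#' about 1000 extracted features, a handful of truly informative ones.
#'
#' @param n_samples number of samples (rows).
#' @param n_features total number of feature columns.
#' @param n_informative number of class-informative features.
#' @param effect_size standardized mean difference (Cohen's d) between the
#'   two classes for each informative feature; 0 gives a pure null table.
#' @param n_redundant correlated copies generated per informative feature.
#' @param redundancy_rho correlation between a redundant copy and its
#'   parent, in `[0, 1]`.
#' @param class_balance fraction of positive samples, strictly in (0, 1).
#' @param seed integer seed; the whole table is reproducible from it.
#' @return An object of class `synthetic_table_spec`.
#' @export
synthetic_table_spec <- function(n_samples = 80L, n_features = 1000L,
                                 n_informative = 10L, effect_size = 1.5,
                                 n_redundant = 0L, redundancy_rho = 0.8,
                                 class_balance = 0.5, seed = 1L) {
  assert_count(n_samples, "n_samples", min = 4L)
  assert_count(n_features, "n_features")
  assert_count(n_informative, "n_informative", min = 0L)
  assert_count(n_redundant, "n_redundant", min = 0L)
  assert_fraction(class_balance, "class_balance")
  if (!is.finite(effect_size) || effect_size < 0) {
    stop("'effect_size' must be a non-negative number", call. = FALSE)
  }
  if (redundancy_rho < 0 || redundancy_rho > 1) {
    stop("'redundancy_rho' must lie in [0, 1]", call. = FALSE)
  }
  if (n_informative + n_informative * n_redundant > n_features) {
    stop("n_informative * (1 + n_redundant) exceeds n_features", call. = FALSE)
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_features = as.integer(n_features),
                 n_informative = as.integer(n_informative),
                 effect_size = as.numeric(effect_size),
                 n_redundant = as.integer(n_redundant),
                 redundancy_rho = as.numeric(redundancy_rho),
                 class_balance = as.numeric(class_balance),
                 seed = as.integer(seed)),
            class = "synthetic_table_spec")
}

#' Generate a synthetic feature table with planted informative features
#'
#' Labels are drawn Bernoulli(`class_balance`) (at least one sample per
#' class enforced). Informative feature j is `noise + d * label`, so its
#' standardized two-class mean difference is `effect_size` in expectation.
#' A redundant copy is `rho * parent + sqrt(1 - rho^2) * fresh-noise`, which
#' correlates with its parent at about `rho`. All remaining columns are
#' independent standard normal noise.
#'
#' Column naming: `inf_<i>` for informative features, `red_<i>_<k>` for the
#' k-th copy of `inf_<i>`, `noise_<j>` otherwise.
#'
#' @param spec a [synthetic_table_spec()].
#' @return A [feature_table()]; the attribute `"informative"` holds the
#'   ground-truth informative feature names and `"redundant"` the names of
#'   their correlated copies.
#' @export
generate_feature_table <- function(spec) {
  stopifnot(inherits(spec, "synthetic_table_spec"))
  n <- spec$n_samples
  p <- spec$n_features
  local_seed(spec$seed, {
    y <- rbinom(n, 1L, spec$class_balance)
    # both classes must be present for supervised scoring downstream
    if (all(y == y[1])) y[sample.int(n, 1L)] <- 1L - y[1]

    x <- matrix(rnorm(n * p), n, p)
    inf_idx <- seq_len(spec$n_informative)
    inf_names <- if (spec$n_informative) paste0("inf_", inf_idx) else character()
    red_names <- character()
    if (spec$n_informative) {
      x[, inf_idx] <- x[, inf_idx] + spec$effect_size * y
      if (spec$n_redundant > 0L) {
        pos <- spec$n_informative
        for (i in inf_idx) {
          for (k in seq_len(spec$n_redundant)) {
            pos <- pos + 1L
            x[, pos] <- spec$redundancy_rho * x[, i] +
              sqrt(1 - spec$redundancy_rho^2) * rnorm(n)
            red_names <- c(red_names, paste0("red_", i, "_", k))
          }
        }
      }
    }
    n_noise <- p - length(inf_names) - length(red_names)
    colnames(x) <- c(inf_names, red_names,
                     if (n_noise) paste0("noise_", seq_len(n_noise)))
    ft <- feature_table(x, y)
    attr(ft, "informative") <- inf_names
    attr(ft, "redundant") <- red_names
    ft
  })
}

#' Specification of a dynamic lesion phantom
#'
#' A small 3D grid holding an ellipsoidal lesion observed over `n_phases`
#' dynamic phases, emulating a subtracted contrast-enhanced series: the
#' lesion signal follows a fixed kinetic profile with a single peak phase,
#' plus Gaussian-smoothed noise texture inside the region of interest.
#' Class 1 lesions carry an additional constant intensity offset
#' (`class_contrast`) and a doubled texture smoothing length, so texture
#' statistics genuinely differ between classes.
#'
#' @param grid_shape integer triple of voxel counts per axis.
#' @param lesion_semiaxes numeric triple of ellipsoid semi-axes in voxels;
#'   the lesion is centred in the grid and must fit inside it.
#' @param class_contrast intensity offset added inside the lesion for
#'   class 1 (arbitrary units).
#' @param texture_scale Gaussian smoothing length (voxels) of the in-lesion
#'   texture for class 0; class 1 uses twice this length.
#' @param n_phases number of dynamic phases (>= 1).
#' @param noise_sd standard deviation of additive voxel noise.
#' @param spacing voxel spacing in mm (triple).
#' @param seed integer seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(32L, 32L, 24L),
                         lesion_semiaxes = c(9, 7, 6),
                         class_contrast = 2, texture_scale = 1.2,
                         n_phases = 4L, noise_sd = 0.5,
                         spacing = c(1, 1, 1), seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 4L)) {
    stop("'grid_shape' must be three voxel counts >= 4", call. = FALSE)
  }
  if (length(lesion_semiaxes) != 3L || any(lesion_semiaxes <= 0)) {
    stop("'lesion_semiaxes' must be three positive lengths", call. = FALSE)
  }
  if (any(2 * lesion_semiaxes + 2 > grid_shape)) {
    stop("lesion does not fit inside the grid", call. = FALSE)
  }
  assert_count(n_phases, "n_phases")
  if (any(spacing <= 0) || length(spacing) != 3L) {
    stop("'spacing' must be three positive lengths (mm)", call. = FALSE)
  }
  structure(list(grid_shape = grid_shape,
                 lesion_semiaxes = as.numeric(lesion_semiaxes),
                 class_contrast = as.numeric(class_contrast),
                 texture_scale = as.numeric(texture_scale),
                 n_phases = as.integer(n_phases),
                 noise_sd = as.numeric(noise_sd),
                 spacing = as.numeric(spacing),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Kinetic weights over phases: rise to a single strict peak, then washout.
phantom_kinetics <- function(n_phases) {
  if (n_phases == 1L) return(1)
  peak <- max(2L, ceiling(n_phases / 2))
  k <- numeric(n_phases)
  for (p in seq_len(n_phases)) {
    k[p] <- if (p <= peak) p / peak else 1 - 0.35 * (p - peak) / n_phases
  }
  k
}

#' Generate a dynamic lesion phantom
#'
#' Background noise is identical for the two classes under the same spec
#' and seed; the class label only affects voxels inside the lesion mask.
#' Exactly one phase attains the maximal mean in-lesion intensity.
#'
#' @param spec a [phantom_spec()].
#' @param class_label 0 or 1.
#' @return A list with `phases` (list of 3D arrays, one per phase), `mask`
#'   (binary 3D array), `spacing` (mm triple) and `class_label`.
#' @export
generate_phantom_volume <- function(spec, class_label = 0L) {
  stopifnot(inherits(spec, "phantom_spec"))
  class_label <- as.integer(class_label)
  if (!class_label %in% c(0L, 1L)) stop("'class_label' must be 0 or 1", call. = FALSE)
  dims <- spec$grid_shape
  ctr <- (dims + 1) / 2
  ax <- expand.grid(i = seq_len(dims[1]), j = seq_len(dims[2]), k = seq_len(dims[3]))
  r2 <- ((ax$i - ctr[1]) / spec$lesion_semiaxes[1])^2 +
        ((ax$j - ctr[2]) / spec$lesion_semiaxes[2])^2 +
        ((ax$k - ctr[3]) / spec$lesion_semiaxes[3])^2
  mask <- array(as.integer(r2 <= 1), dim = dims)
  if (!any(mask == 1L)) stop("empty lesion mask", call. = FALSE)

  kin <- phantom_kinetics(spec$n_phases)
  base_enh <- 10    # lesion enhancement amplitude at the kinetic peak
  tex_sd <- 1.5     # texture amplitude before smoothing
  scale <- spec$texture_scale * (1 + class_label)  # class 1: doubled length

  local_seed(spec$seed, {
    # background noise first: identical across classes for a fixed seed
    bg <- lapply(seq_len(spec$n_phases),
                 function(p) array(rnorm(prod(dims), sd = spec$noise_sd), dim = dims))
    # class-dependent texture field, shared across phases
    tex <- gaussian_smooth_3d(array(rnorm(prod(dims), sd = tex_sd), dim = dims),
                              sigma_vox = rep(scale, 3))
    # rescale so in-mask texture has zero mean / unit-free fixed sd
    inroi <- mask == 1L
    tex <- (tex - mean(tex[inroi])) / max(sd_pop(tex[inroi]), 1e-12) * tex_sd
    phases <- vector("list", spec$n_phases)
    for (p in seq_len(spec$n_phases)) {
      vol <- bg[[p]]
      vol[inroi] <- vol[inroi] + base_enh * kin[p] + tex[inroi] +
        spec$class_contrast * class_label
      phases[[p]] <- vol
    }
    list(phases = phases, mask = mask, spacing = spec$spacing,
         class_label = class_label)
  })
}

#' Write a phantom to NIfTI files
#'
#' One volume per phase (`<prefix>_phase<i>.nii.gz`) plus the binary mask
#' (`<prefix>_mask.nii.gz`).
#'
#' @param phantom result of [generate_phantom_volume()].
#' @param prefix output path prefix.
#' @return Character vector of written paths, invisibly.
#' @export
write_phantom_nifti <- function(phantom, prefix) {
  as_img <- function(a) {
    img <- RNifti::asNifti(a)
    RNifti::pixdim(img) <- phantom$spacing
    img
  }
  paths <- character()
  for (p in seq_along(phantom$phases)) {
    path <- sprintf("%s_phase%d.nii.gz", prefix, p)
    RNifti::writeNifti(as_img(phantom$phases[[p]]), path)
    paths <- c(paths, path)
  }
  mpath <- sprintf("%s_mask.nii.gz", prefix)
  RNifti::writeNifti(as_img(phantom$mask), mpath)
  invisible(c(paths, mpath))
}
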