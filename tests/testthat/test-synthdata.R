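test_that("table generation is reproducible and respects the spec contract", {
  spec <- synthetic_table_spec(n_samples = 60, n_features = 40, n_informative = 4,
                               effect_size = 1.5, n_redundant = 2,
                               redundancy_rho = 0.8, seed = 7)
  ft1 <- generate_feature_table(spec)
  ft2 <- generate_feature_table(spec)
  expect_identical(ft1$x, ft2$x)
  expect_identical(ft1$y, ft2$y)
  expect_identical(attr(ft1, "informative"), paste0("inf_", 1:4))
  expect_length(attr(ft1, "redundant"), 8)
  expect_equal(dim(ft1$x), c(60, 40))
  # redundant copies correlate with their parents at about rho
  for (i in 1:4) {
    expect_gt(cor(ft1$x[, paste0("inf_", i)], ft1$x[, paste0("red_", i, "_1")]), 0.6)
  }
})

test_that("inconsistent spec counts are rejected", {
  expect_error(synthetic_table_spec(n_features = 10, n_informative = 6,
                                    n_redundant = 1),
               "exceeds")
  expect_error(synthetic_table_spec(class_balance = 0), "between 0 and 1")
  expect_error(synthetic_table_spec(effect_size = -1), "non-negative")
})

test_that("null tables carry no class signal beyond sampling noise", {
  spec <- synthetic_table_spec(n_samples = 80, n_features = 1000,
                               n_informative = 10, effect_size = 0, seed = 5)
  ft <- generate_feature_table(spec)
  pvals <- apply(ft$x, 2, function(v) t.test(v[ft$y == 1], v[ft$y == 0])$p.value)
  # alpha = 0.001 should reject about 0.1% of pure-noise features
  expect_lte(mean(pvals < 0.001), 0.008)
})

test_that("planted effect size is recovered empirically", {
  spec <- synthetic_table_spec(n_samples = 2000, n_features = 20,
                               n_informative = 5, effect_size = 1.0, seed = 11)
  ft <- generate_feature_table(spec)
  for (f in attr(ft, "informative")) {
    expect_lt(abs(empirical_cohens_d(ft$x[, f], ft$y) - 1.0), 0.1)
  }
})

test_that("phantom signal is confined to the lesion mask and reproducible", {
  spec <- phantom_spec(grid_shape = c(24, 24, 20), lesion_semiaxes = c(7, 6, 5),
                       n_phases = 3, seed = 21)
  p0 <- generate_phantom_volume(spec, 0)
  p1 <- generate_phantom_volume(spec, 1)
  expect_identical(p0$mask, p1$mask)
  out <- p0$mask == 0L
  for (ph in 1:3) {
    expect_identical(p0$phases[[ph]][out], p1$phases[[ph]][out])
  }
  p0b <- generate_phantom_volume(spec, 0)
  expect_identical(p0$phases, p0b$phases)
})

test_that("one dynamic phase attains the strictly maximal ROI mean", {
  spec <- phantom_spec(grid_shape = c(24, 24, 20), lesion_semiaxes = c(7, 6, 5),
                       n_phases = 5, noise_sd = 0.1, seed = 3)
  ph <- generate_phantom_volume(spec, 0)
  means <- vapply(ph$phases, function(v) mean(v[ph$mask == 1L]), numeric(1))
  expect_equal(sum(abs(means - max(means)) < 1e-9), 1)
  single <- generate_phantom_volume(phantom_spec(grid_shape = c(16, 16, 12),
                                                 lesion_semiaxes = c(4, 4, 3),
                                                 n_phases = 1, seed = 2), 0)
  expect_equal(select_peak_subtraction_phase(
    lapply(single$phases, volume_grid), single$mask), 1)
})

test_that("class contrast shifts the mean ROI intensity by its stated amount", {
  diffs <- vapply(1:50, function(s) {
    spec <- phantom_spec(grid_shape = c(20, 20, 16), lesion_semiaxes = c(6, 5, 4),
                         class_contrast = 5, noise_sd = 1, n_phases = 2, seed = s)
    p0 <- generate_phantom_volume(spec, 0)
    p1 <- generate_phantom_volume(spec, 1)
    m <- function(p) mean(vapply(p$phases, function(v) mean(v[p$mask == 1L]),
                                 numeric(1)))
    m(p1) - m(p0)
  }, numeric(1))
  expect_lt(abs(mean(diffs) - 5), 0.5)
})

test_that("oversized lesions are rejected", {
  expect_error(phantom_spec(grid_shape = c(10, 10, 10),
                            lesion_semiaxes = c(8, 3, 3)), "fit")
})

test_that("phantoms round-trip through NIfTI", {
  spec <- phantom_spec(grid_shape = c(12, 12, 10), lesion_semiaxes = c(3, 3, 3),
                       n_phases = 2, seed = 8, spacing = c(1, 1, 1.5))
  ph <- generate_phantom_volume(spec, 1)
  tmp <- file.path(tempdir(), "phantom_rt")
  paths <- write_phantom_nifti(ph, tmp)
  v <- read_volume(paste0(tmp, "_phase1.nii.gz"))
  m <- read_mask(paste0(tmp, "_mask.nii.gz"))
  expect_equal(v$data, ph$phases[[1]], tolerance = 1e-6)
  expect_equal(v$spacing, c(1, 1, 1.5), tolerance = 1e-6)
  expect_identical(m, ph$mask)
  unlink(paste0(tmp, "_*"))
})
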