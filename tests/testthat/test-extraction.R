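# A small shared phantom keeps the extraction tests fast.
small_phantom <- local({
  spec <- phantom_spec(grid_shape = c(20, 20, 16), lesion_semiaxes = c(6, 5, 4),
                       n_phases = 2, seed = 19)
  generate_phantom_volume(spec, 1)
})
small_volume <- volume_grid(small_phantom$phases[[1]], small_phantom$spacing)

test_that("closed-form counts match the observed extraction cardinalities", {
  profiles <- list(
    extraction_profile(),
    extraction_profile(families = c("firstorder", "glcm"),
                       wavelet_channels = c("LLL", "HHH"),
                       log_sigmas_mm = 2, exclusions = "glcm_Idmn"),
    extraction_profile(families = "firstorder", wavelet_channels = character(),
                       log_sigmas_mm = numeric()))
  for (prof in profiles) {
    counts <- feature_count_by_family(prof)
    fv <- extract_features(small_volume, small_phantom$mask, prof, "T2")
    expect_length(fv, counts[["total"]])
    expect_equal(sum(grepl("_wavelet-", names(fv))), counts[["wavelet"]])
    expect_equal(sum(grepl("_log-sigma", names(fv))), counts[["log"]])
    for (fam in prof$families) {
      expect_equal(sum(grepl(paste0("_original_", fam, "_"), names(fv))),
                   unname(counts[fam]))
    }
  }
})

test_that("the default profile reproduces the reference taxonomy counts", {
  counts <- feature_count_by_family(extraction_profile())
  expect_equal(unname(counts["shape"]), 14L)
  expect_equal(unname(counts["firstorder"]), 18L)
  expect_equal(unname(counts["glcm"]), 24L)
  expect_equal(unname(counts["glrlm"]), 16L)
  expect_equal(unname(counts["glszm"]), 16L)
  expect_equal(unname(counts["ngtdm"]), 5L)
  expect_equal(unname(counts["gldm"]), 14L)
  expect_equal(unname(counts["wavelet"]), 728L)   # 91 x 8 channels
  expect_equal(unname(counts["log"]), 364L)       # 91 x 4 sigmas
  expect_equal(unname(counts["filtered_total"]), 1092L)
})

test_that("a first-order-only profile yields exactly 18 features", {
  prof <- extraction_profile(families = "firstorder",
                             wavelet_channels = character(),
                             log_sigmas_mm = numeric())
  fv <- extract_features(small_volume, small_phantom$mask, prof)
  expect_length(fv, 18L)
  expect_true(all(grepl("^original_firstorder_", names(fv))))
})

test_that("an empty profile counts to all zeros", {
  prof <- extraction_profile(families = character(),
                             wavelet_channels = character(),
                             log_sigmas_mm = numeric())
  expect_equal(unname(feature_count_by_family(prof)[["total"]]), 0L)
})

test_that("feature names follow the modality_filter_family_feature convention", {
  prof <- extraction_profile(families = c("shape", "firstorder", "glcm"),
                             wavelet_channels = "LLH", log_sigmas_mm = 4)
  fv <- extract_features(small_volume, small_phantom$mask, prof, "T2")
  expect_true("T2_original_shape_Flatness" %in% names(fv))
  expect_true("T2_wavelet-LLH_firstorder_Skewness" %in% names(fv))
  expect_true("T2_log-sigma-4-0-mm-3D_glcm_Imc2" %in% names(fv))
  expect_false(anyDuplicated(names(fv)) > 0)
  expect_true(all(is.finite(fv)))
})

test_that("shape features are invariant to intensity rescaling", {
  prof <- extraction_profile(families = "shape", wavelet_channels = character(),
                             log_sigmas_mm = numeric())
  f1 <- extract_features(small_volume, small_phantom$mask, prof)
  rescaled <- volume_grid(small_volume$data * 37 + 11, small_volume$spacing)
  f2 <- extract_features(rescaled, small_phantom$mask, prof)
  expect_equal(f1, f2)
})

test_that("extraction is deterministic and validates its inputs", {
  prof <- extraction_profile(families = c("firstorder", "ngtdm"),
                             wavelet_channels = character(),
                             log_sigmas_mm = numeric())
  f1 <- extract_features(small_volume, small_phantom$mask, prof)
  f2 <- extract_features(small_volume, small_phantom$mask, prof)
  expect_identical(f1, f2)
  expect_error(extract_features(small_volume, small_phantom$mask[1:10, , ], prof),
               "shapes differ")
  expect_error(extraction_profile(families = "glcm2"), "unknown family")
  expect_error(extraction_profile(exclusions = "glcm_NotAFeature"), "exclusion")
})

test_that("texture matrices react to the texture scale of the lesion", {
  # coarser texture (class 1 doubles the smoothing length) should raise
  # GLCM correlation relative to the fine-textured class 0 lesion
  spec <- phantom_spec(grid_shape = c(20, 20, 16), lesion_semiaxes = c(6, 5, 4),
                       n_phases = 1, noise_sd = 0.1, seed = 4)
  prof <- extraction_profile(families = "glcm", wavelet_channels = character(),
                             log_sigmas_mm = numeric())
  corr <- vapply(0:1, function(cls) {
    ph <- generate_phantom_volume(spec, cls)
    fv <- extract_features(volume_grid(ph$phases[[1]], ph$spacing), ph$mask, prof)
    fv[["original_glcm_Correlation"]]
  }, numeric(1))
  expect_gt(corr[2], corr[1])
})
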