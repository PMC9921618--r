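planted_table <- function(n = 80, p = 205, d = 2, n_inf = 5, seed = 1) {
  generate_feature_table(synthetic_table_spec(
    n_samples = n, n_features = p, n_informative = n_inf, effect_size = d,
    seed = seed))
}

test_that("SMOTE balances counts and preserves the original rows", {
  set.seed(3)
  x <- matrix(rnorm(16), 8, 2, dimnames = list(NULL, c("a", "b")))
  ft <- feature_table(x, c(rep(0L, 6), rep(1L, 2)))
  out <- smote_oversample(ft, k_neighbors = 1, seed = 2)
  expect_equal(as.vector(table(out$y)), c(6L, 6L))
  expect_identical(out$x[1:8, ], ft$x)
  expect_identical(out$y[1:8], ft$y)
  # balanced input returned unchanged
  bal <- feature_table(x, rep(c(0L, 1L), 4))
  expect_identical(smote_oversample(bal, 1, 1), bal)
})

test_that("synthetic SMOTE points lie on segments between minority neighbours", {
  x <- rbind(matrix(rnorm(20, mean = 5), 10, 2), c(0, 0), c(1, 1))
  colnames(x) <- c("u", "v")
  ft <- feature_table(x, c(rep(0L, 10), 1L, 1L))
  out <- suppressWarnings(smote_oversample(ft, k_neighbors = 1, seed = 7))
  synth <- out$x[out$y == 1L, ][-(1:2), , drop = FALSE]
  # the two minority points define the segment u = v, 0 <= u <= 1
  expect_true(all(abs(synth[, "u"] - synth[, "v"]) < 1e-12))
  expect_true(all(synth[, "u"] >= 0 & synth[, "u"] <= 1))
})

test_that("SMOTE degenerate classes are handled explicitly", {
  x <- matrix(rnorm(12), 6, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(smote_oversample(feature_table(x, rep(0L, 6)), 1, 1),
               "both classes")
  expect_warning(smote_oversample(feature_table(x, c(0L, 0L, 0L, 0L, 1L, 1L)),
                                  k_neighbors = 5, seed = 1), "k = 1")
})

test_that("minpos/numpos aggregation reproduces the worked examples", {
  agg <- aggregate_fold_rankings(list(c("A", "B", "C"), c("B", "A", "C")), 2)
  expect_equal(agg$feature, c("A", "B"))
  expect_equal(agg$minpos, c(1L, 1L))
  expect_equal(agg$numpos, c(1L, 1L))
  # one fold: exactly the top-t in fold order
  agg1 <- aggregate_fold_rankings(list(c("X", "Y", "Z", "W")), 3)
  expect_equal(agg1$feature, c("X", "Y", "Z"))
  # all features reach rank 1 somewhere: kept set exceeds the threshold
  agg2 <- aggregate_fold_rankings(
    list(c("A", "B", "C"), c("C", "B", "A"), c("B", "A", "C")), 1)
  expect_equal(agg2$feature, c("A", "B", "C"))
  expect_error(aggregate_fold_rankings(list(), 1), "no fold")
})

test_that("aggregation equals brute-force enumeration over fold permutations", {
  feats <- c("a", "b", "c", "d", "e", "f")
  set.seed(41)
  for (rep in 1:30) {
    n_folds <- sample(2:4, 1)
    folds <- lapply(seq_len(n_folds), function(i) sample(feats))
    for (t in c(1, 3, 6)) {
      got <- aggregate_fold_rankings(folds, t)
      want <- oracle_minpos_numpos(folds, t)
      expect_equal(got$feature, want$feature)
      expect_equal(got$minpos, as.integer(want$minpos))
      expect_equal(got$numpos, as.integer(want$numpos))
    }
  }
})

test_that("kept sets grow monotonically with the threshold", {
  set.seed(6)
  folds <- lapply(1:5, function(i) sample(paste0("f", 1:12)))
  prev <- character()
  for (t in 1:12) {
    kept <- aggregate_fold_rankings(folds, t)$feature
    expect_true(all(prev %in% kept))
    prev <- kept
  }
})

test_that("per-fold selection depends only on the training rows", {
  ft <- planted_table(n = 40, p = 30, seed = 3)
  n_folds <- 4L
  folds <- radsel:::stratified_folds(ft$y, n_folds, seed = 11)
  f <- 2L
  tr <- which(folds != f)
  rank_from <- function(table) {
    scaler <- radsel:::fit_scaler(table$x[tr, , drop = FALSE])
    xtr <- radsel:::apply_scaler(table$x[tr, , drop = FALSE], scaler)
    score_features(feature_table(xtr, table$y[tr]), "fisher")
  }
  # corrupt the held-out rows: the fold's ranking must not move
  ft2 <- ft
  ft2$x[folds == f, ] <- ft2$x[folds == f, ] * 100 + 7
  expect_identical(rank_from(ft)$feature, rank_from(ft2)$feature)
})

test_that("a degenerate single-combination grid returns one configuration", {
  ft <- planted_table(n = 40, p = 20, seed = 5)
  cfg <- step_config(selectors = "fisher", classifiers = "nb", thresholds = 5L,
                     n_folds = 3, seed = 2)
  res <- run_selection_step(ft, cfg)
  expect_equal(nrow(res$results), 1L)
  expect_length(res$top, 1L)
  expect_equal(res$top[[1]]$selector, "fisher")
})

test_that("selection-step results are reproducible for a fixed seed", {
  ft <- planted_table(n = 40, p = 30, seed = 8)
  cfg <- step_config(selectors = c("fisher", "chi_squared"),
                     classifiers = c("nb", "knn"), thresholds = c(5L, 10L),
                     n_folds = 3, seed = 4)
  r1 <- run_selection_step(ft, cfg)
  r2 <- run_selection_step(ft, cfg)
  expect_identical(r1$results, r2$results)
  expect_identical(r1$top[[1]]$features, r2$top[[1]]$features)
})

test_that("step 1 recovers planted features in the winning aggregated list", {
  wins <- vapply(1:10, function(s) {
    ft <- planted_table(seed = s)
    cfg <- step_config(selectors = COMPLETE_RANKERS,
                       classifiers = c("nb", "knn"),
                       thresholds = seq(5L, 50L, 15L), n_folds = 10, seed = s)
    res <- run_selection_step(ft, cfg)
    sum(attr(ft, "informative") %in% res$top[[1]]$features)
  }, numeric(1))
  expect_gte(mean(wins >= 4), 0.5 + 1e-9)
})

test_that("the two-step pipeline validates its selector sets", {
  ft <- planted_table(n = 30, p = 15, seed = 2)
  s1 <- step_config(selectors = "fisher", classifiers = "nb", thresholds = 5L,
                    n_folds = 3)
  s2 <- step_config(selectors = "mutual_information", classifiers = "nb",
                    thresholds = 3L, n_folds = 3)
  expect_error(two_step_pipeline(ft, s2, s2), "complete rankers")
  expect_error(two_step_pipeline(ft, s1, s1), "step 2 selectors")
})

test_that("step-2 thresholding above the list size leaves the list unchanged", {
  ft <- planted_table(n = 40, p = 25, n_inf = 3, seed = 6)
  s1 <- step_config(selectors = "fisher", classifiers = "nb", thresholds = 6L,
                    n_folds = 4, seed = 3)
  res1 <- run_selection_step(ft, s1)
  m <- length(res1$top[[1]]$features)
  s2 <- step_config(selectors = "mutual_information", classifiers = "nb",
                    thresholds = as.integer(m + 5L), n_folds = 4, seed = 3)
  res2 <- run_selection_step(ft, s2, candidate_features = res1$top[[1]]$features)
  expect_setequal(res2$top[[1]]$features, res1$top[[1]]$features)
})

test_that("two-step provenance is deterministic across reruns", {
  ft <- planted_table(n = 40, p = 40, n_inf = 3, seed = 9)
  s1 <- step_config(selectors = c("fisher", "gini_index"), classifiers = "nb",
                    thresholds = c(5L, 10L), n_folds = 4, seed = 7)
  s2 <- step_config(selectors = c("mutual_information", "cfs"),
                    classifiers = "nb", thresholds = c(2L, 4L), n_folds = 4,
                    seed = 7)
  r1 <- two_step_pipeline(ft, s1, s2)
  r2 <- two_step_pipeline(ft, s1, s2)
  expect_identical(r1$provenance, r2$provenance)
  expect_identical(r1$final_features, r2$final_features)
})

test_that("LOOCV scores a separable toy perfectly and predicts every sample", {
  set.seed(12)
  n <- 24
  y <- rep_len(c(0L, 1L), n)
  x <- matrix(y * 4 + rnorm(n, sd = 0.2), n, 1, dimnames = list(NULL, "sep"))
  ft <- feature_table(x, y)
  res <- suppressWarnings(loocv_select_model(ft, "sep",
                                             classifiers = c("knn", "nb", "dt"),
                                             seed = 2))
  expect_equal(nrow(res$predictions), n)
  for (m in c("knn", "nb", "dt")) {
    expect_equal(res$metrics[[m]]$f1_positive, 1.0, info = m)
  }
  expect_s3_class(res$predictor, "predictor_model")
  # the refitted predictor reproduces the training labels
  expect_equal(as.integer(predict(res$predictor, ft)), y)
})

test_that("LOOCV rejects degenerate inputs", {
  x <- matrix(rnorm(30), 15, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(loocv_select_model(feature_table(x, rep(0L, 15)), "a"),
               "both classes")
  expect_error(loocv_select_model(feature_table(x, rep_len(c(0L, 1L), 15)),
                                  character()), "empty")
})
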