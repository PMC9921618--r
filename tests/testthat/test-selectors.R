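random_table <- function(n, p, seed, y = NULL) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", seq_len(p))))
  if (is.null(y)) y <- rep_len(c(0L, 1L), n)
  feature_table(x, y)
}

test_that("fisher score matches its defining formula on the worked example", {
  ft <- feature_table(matrix(c(1, 2, 3, 4), 4, 1, dimnames = list(NULL, "f")),
                      c(0, 0, 1, 1))
  rl <- score_features(ft, "fisher")
  expect_equal(rl$score, 4.0)
})

test_that("each ranker matches its brute-force oracle on small tables", {
  oracles <- list(chi_squared = oracle_chi_squared, fisher = oracle_fisher,
                  gini_index = oracle_gini, relieff = oracle_relieff,
                  mutual_information = oracle_mi)
  for (seed in 1:5) {
    ft <- random_table(24, 6, seed)
    for (m in names(oracles)) {
      rl <- score_features(ft, m, seed = seed)
      expected <- oracles[[m]](ft$x, ft$y)
      ord <- colnames(ft$x)[order(-expected, seq_along(expected))]
      expect_equal(rl$feature, ord, info = paste(m, "seed", seed))
      expect_equal(rl$score, unname(expected[rl$feature]), tolerance = 1e-6,
                   info = paste(m, "seed", seed))
    }
  }
})

test_that("constant features score zero and rank last", {
  set.seed(2)
  x <- cbind(good = rnorm(20) + rep(c(0, 2), each = 10), flat = rep(3, 20),
             noise = rnorm(20))
  ft <- feature_table(x, rep(c(0L, 1L), each = 10))
  for (m in c("chi_squared", "fisher", "gini_index", "relieff",
              "mutual_information")) {
    rl <- score_features(ft, m)
    expect_equal(rl$feature[nrow(rl)], "flat", info = m)
    expect_equal(rl$score[nrow(rl)], 0, info = m)
  }
})

test_that("rankings are equivariant under column permutation", {
  ft <- random_table(30, 8, seed = 9)
  perm <- c(5, 3, 8, 1, 7, 2, 6, 4)
  ft_p <- feature_table(ft$x[, perm], ft$y)
  for (m in c("chi_squared", "fisher", "gini_index", "relieff")) {
    r1 <- score_features(ft, m)
    r2 <- score_features(ft_p, m)
    expect_equal(r1$feature, r2$feature, info = m)
  }
})

test_that("scores are invariant to affine positive rescaling where implied", {
  ft <- random_table(30, 6, seed = 13)
  scaled <- feature_table(sweep(sweep(ft$x, 2, c(2, 5, 0.1, 3, 7, 11), "*"),
                                2, c(-4, 2, 0, 1, 9, -2), "+"), ft$y)
  for (m in c("chi_squared", "fisher", "relieff")) {
    r1 <- score_features(ft, m)
    r2 <- score_features(scaled, m)
    expect_equal(r1$feature, r2$feature, info = m)
    expect_equal(r1$score, r2$score, tolerance = 1e-8, info = m)
  }
})

test_that("relieff puts a perfectly separating feature first on a toy table", {
  x <- cbind(sep = c(0, 0, 0, 1, 1, 1), noise = c(0.9, 0.1, 0.5, 0.4, 0.8, 0.2))
  ft <- feature_table(x, c(0L, 0L, 0L, 1L, 1L, 1L))
  rl <- score_features(ft, "relieff")
  expect_equal(rl$feature[1], "sep")
  expect_equal(rl$score, unname(oracle_relieff(ft$x, ft$y)[rl$feature]),
               tolerance = 1e-9)
})

test_that("single-class labels are rejected", {
  ft <- random_table(10, 3, seed = 1, y = rep(1L, 10))
  expect_error(score_features(ft, "fisher"), "both classes")
})

test_that("LASSO-RFE keeps a label-copy feature and is deterministic", {
  set.seed(31)
  n <- 60
  y <- rep_len(c(0L, 1L), n)
  x <- cbind(copy = y + rnorm(n, sd = 0.01),
             matrix(rnorm(n * 20), n, 20,
                    dimnames = list(NULL, paste0("n", 1:20))))
  ft <- feature_table(x, y)
  r1 <- lr_rfe_select(ft, k = 1, seed = 5)
  expect_equal(r1$feature[r1$selected], "copy")
  r2 <- lr_rfe_select(ft, k = 1, seed = 5)
  expect_identical(r1, r2)
  # k = p is the identity selection
  rall <- lr_rfe_select(ft, k = ncol(x), seed = 5)
  expect_setequal(rall$feature[rall$selected], colnames(x))
  expect_error(lr_rfe_select(ft, k = 0), "k")
})

test_that("CFS keeps one of two duplicate informative features", {
  set.seed(17)
  n <- 80
  y <- rep_len(c(0L, 1L), n)
  base <- y + rnorm(n, sd = 0.3)
  x <- cbind(dup1 = base, dup2 = base,
             matrix(rnorm(n * 10), n, 10, dimnames = list(NULL, paste0("n", 1:10))))
  ft <- feature_table(x, y)
  sel <- cfs_select(ft)
  expect_equal(sum(c("dup1", "dup2") %in% sel$feature), 1)
})

test_that("CFS merit at k = 1 equals the absolute class correlation", {
  set.seed(23)
  y <- rep_len(c(0L, 1L), 40)
  v <- y + rnorm(40, sd = 0.5)
  ft <- feature_table(matrix(v, 40, 1, dimnames = list(NULL, "f")), y)
  sel <- cfs_select(ft)
  expect_equal(attr(sel, "merit"), abs(cor(v, y)), tolerance = 1e-12)
})

test_that("CFS recovers planted informative features across seeds", {
  hits <- vapply(1:20, function(s) {
    ft <- generate_feature_table(synthetic_table_spec(
      n_samples = 100, n_features = 53, n_informative = 3, effect_size = 2,
      seed = s))
    sel <- cfs_select(ft)
    sum(attr(ft, "informative") %in% sel$feature)
  }, numeric(1))
  expect_gte(mean(hits >= 2), 0.9)
})
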