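# The ensemble core: per-fold selection, SMOTE-balanced classification,
# minpos/numpos aggregation across folds, and the two-step pipeline.

STEP2_METHODS <- c("lr_rfe", "mutual_information", "cfs")

#' Configuration of one selection/classification step
#'
#' @param selectors feature-selection methods to try. Step 1 uses the
#'   complete rankers (`chi_squared`, `fisher`, `gini_index`, `relieff`);
#'   step 2 uses `lr_rfe`, `mutual_information` and/or `cfs`.
#' @param classifiers subset of `knn, nb, svm, dt, mlp, rf`.
#' @param thresholds positive integer rank thresholds; the coarse step
#'   default is `seq(5, 50, by = 5)` (t1) and the fine step uses `1:10`
#'   (t2).
#' @param n_folds number of stratified cross-validation folds.
#' @param seed integer seed driving fold assignment, SMOTE and the
#'   stochastic classifiers.
#' @param smote_k SMOTE neighbour count.
#' @param classifier_params named list overriding classifier defaults
#'   (`knn_k`, `mlp_size`, `mlp_maxit`, `mlp_decay`, `rf_ntree`).
#' @return An object of class `step_config`.
#' @export
step_config <- function(selectors = COMPLETE_RANKERS,
                        classifiers = CLASSIFIER_METHODS,
                        thresholds = seq(5L, 50L, by = 5L),
                        n_folds = 10L, seed = 1L, smote_k = 5L,
                        classifier_params = list()) {
  known <- c(RANKER_METHODS, STEP2_METHODS)
  bad <- setdiff(selectors, known)
  if (length(bad)) stop("unknown selector(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  bad <- setdiff(classifiers, CLASSIFIER_METHODS)
  if (length(bad)) stop("unknown classifier(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (!length(thresholds) || any(thresholds != round(thresholds)) ||
      any(thresholds < 1)) {
    stop("'thresholds' must be positive integers", call. = FALSE)
  }
  assert_count(n_folds, "n_folds", min = 2L)
  structure(list(selectors = unique(selectors),
                 classifiers = unique(classifiers),
                 thresholds = as.integer(sort(unique(thresholds))),
                 n_folds = as.integer(n_folds), seed = as.integer(seed),
                 smote_k = as.integer(smote_k),
                 classifier_params = classifier_params),
            class = "step_config")
}

# z-standardization fitted on training rows only.
fit_scaler <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, sd_pop)
  sdv[sdv == 0] <- 1
  list(mu = mu, sd = sdv)
}

apply_scaler <- function(x, scaler) {
  sweep(sweep(x, 2, scaler$mu), 2, scaler$sd, "/")
}

# Full ranking of one training split with one selector; thresholds are
# applied downstream. For subset/partial methods a maximal k is used so
# one run serves every threshold.
fold_ranking <- function(train_table, selector, seed, max_k) {
  if (selector %in% RANKER_METHODS) {
    score_features(train_table, selector, seed = seed)
  } else if (selector == "lr_rfe") {
    lr_rfe_select(train_table, k = min(max_k, ncol(train_table$x)), seed = seed)
  } else {  # cfs
    cfs_select(train_table)
  }
}

# Features used for classification at threshold t: top-t of the fold
# ranking, except CFS whose subset size is self-determined.
fold_selected <- function(ranking, selector, t) {
  feats <- as.character(ranking$feature[ranking$selected])
  if (selector == "cfs") feats else head(feats, t)
}

#' Run one selection/classification step over cross-validation folds
#'
#' For every combination of selector, rank threshold and classifier:
#' features are ranked on each training split alone (after
#' z-standardization fitted on that split), the split's top-ranked
#' features are kept, SMOTE balances the training split, the classifier
#' is fitted and scored by F1 (positive class) on the held-out fold.
#' Per-fold rankings of each selector are merged with
#' [aggregate_fold_rankings()] at the combination's threshold. The two
#' best combinations by mean F1 are returned together with their
#' aggregated feature lists.
#'
#' @param table a [feature_table()].
#' @param config a [step_config()].
#' @param candidate_features optional character vector restricting
#'   selection and classification to these columns.
#' @return An object of class `selection_step`: `results` (one row per
#'   combination: selector, threshold, classifier, mean_f1, var_f1,
#'   n_features) and `top`, a list of (up to) the two best configurations,
#'   each carrying its aggregated `features`.
#' @export
run_selection_step <- function(table, config, candidate_features = NULL) {
  stopifnot(inherits(table, "feature_table"), inherits(config, "step_config"))
  if (!is.null(candidate_features)) {
    table <- subset_table(table, features = candidate_features)
  }
  y <- table$y
  if (length(unique(y)) < 2L) stop("both classes must be present", call. = FALSE)
  folds <- stratified_folds(y, config$n_folds, config$seed)
  max_t <- max(config$thresholds)

  # one full ranking per (fold, selector)
  rankings <- vector("list", config$n_folds)
  scalers <- vector("list", config$n_folds)
  train_tables <- vector("list", config$n_folds)
  for (f in seq_len(config$n_folds)) {
    tr <- which(folds != f)
    scaler <- fit_scaler(table$x[tr, , drop = FALSE])
    xtr <- apply_scaler(table$x[tr, , drop = FALSE], scaler)
    train_tables[[f]] <- feature_table(xtr, y[tr], table$sample_ids[tr])
    scalers[[f]] <- scaler
    rankings[[f]] <- lapply(setNames(config$selectors, config$selectors),
                            function(s) {
                              fold_ranking(train_tables[[f]], s,
                                           derive_seed(config$seed, f), max_t)
                            })
  }

  grid <- expand.grid(selector = config$selectors,
                      threshold = config$thresholds,
                      classifier = config$classifiers,
                      stringsAsFactors = FALSE)
  res <- grid
  res$mean_f1 <- NA_real_
  res$var_f1 <- NA_real_
  res$n_features <- NA_integer_
  agg_cache <- new.env(hash = TRUE)

  for (r in seq_len(nrow(grid))) {
    sel <- grid$selector[r]
    t <- grid$threshold[r]
    clf <- grid$classifier[r]
    f1s <- numeric(config$n_folds)
    for (f in seq_len(config$n_folds)) {
      te <- which(folds == f)
      feats <- fold_selected(rankings[[f]][[sel]], sel, t)
      tr_tab <- subset_table(train_tables[[f]], features = feats)
      tr_bal <- smote_oversample(tr_tab, config$smote_k,
                                 seed = derive_seed(config$seed, f * 131 + r))
      model <- fit_classifier(tr_bal$x, tr_bal$y, clf,
                              seed = derive_seed(config$seed, f * 733 + r),
                              params = config$classifier_params)
      xte <- apply_scaler(table$x[te, , drop = FALSE], scalers[[f]])
      pred <- predict_classifier(model, xte[, feats, drop = FALSE])
      m <- compute_metrics(y[te], pred$class)
      f1s[f] <- m$f1_positive
    }
    res$mean_f1[r] <- mean(f1s)
    res$var_f1[r] <- var(f1s)
    key <- paste(sel, t)
    if (is.null(agg_cache[[key]])) {
      agg_cache[[key]] <- aggregate_fold_rankings(
        lapply(rankings, `[[`, sel), threshold = t)
    }
    res$n_features[r] <- nrow(agg_cache[[key]])
  }

  ord <- order(-res$mean_f1, res$var_f1, seq_len(nrow(res)))
  top_rows <- head(ord, 2L)
  top <- lapply(top_rows, function(r) {
    agg <- agg_cache[[paste(res$selector[r], res$threshold[r])]]
    list(selector = res$selector[r], threshold = res$threshold[r],
         classifier = res$classifier[r], mean_f1 = res$mean_f1[r],
         var_f1 = res$var_f1[r], features = agg$feature, aggregation = agg)
  })
  structure(list(results = res[ord, ], top = top, n_folds = config$n_folds),
            class = "selection_step")
}

#' @export
print.selection_step <- function(x, ...) {
  cat("selection_step:", nrow(x$results), "combinations over", x$n_folds, "folds\n")
  b <- x$top[[1]]
  cat(sprintf("best: %s @ t=%d + %s  F1 = %.3f +/- %.3f (%d features kept)\n",
              b$selector, b$threshold, b$classifier, b$mean_f1, b$var_f1,
              length(b$features)))
  invisible(x)
}

#' Run the full two-step feature-selection pipeline
#'
#' Step 1 screens the complete feature set with fast complete-ranker
#' filters at coarse thresholds (t1); the two best configurations'
#' aggregated feature lists each feed step 2, where slower fine-tuning
#' selectors (LASSO-RFE, mutual information, CFS) are restricted to those
#' candidates and filtered at fine thresholds (t2). The final list is the
#' aggregated list of the best step-2 configuration by mean F1, with full
#' provenance of the winning settings at each step.
#'
#' @param table a [feature_table()].
#' @param step1 a [step_config()] whose selectors are complete rankers.
#' @param step2 a [step_config()] whose selectors are among `lr_rfe`,
#'   `mutual_information`, `cfs`.
#' @return An object of class `two_step_result`: `final_features`,
#'   `provenance` (winning selector/threshold/classifier of both steps and
#'   which step-1 candidate won), `step1` and `step2_candidates` (the two
#'   step-2 `selection_step` objects).
#' @export
two_step_pipeline <- function(table, step1, step2) {
  stopifnot(inherits(step1, "step_config"), inherits(step2, "step_config"))
  if (!all(step1$selectors %in% COMPLETE_RANKERS)) {
    stop("step 1 selectors must be complete rankers (",
         paste(COMPLETE_RANKERS, collapse = ", "), ")", call. = FALSE)
  }
  if (!all(step2$selectors %in% STEP2_METHODS)) {
    stop("step 2 selectors must be among ",
         paste(STEP2_METHODS, collapse = ", "), call. = FALSE)
  }
  s1 <- run_selection_step(table, step1)
  candidates <- vector("list", length(s1$top))
  for (i in seq_along(s1$top)) {
    candidates[[i]] <- run_selection_step(table, step2,
                                          candidate_features = s1$top[[i]]$features)
  }
  best_f1 <- vapply(candidates, function(s) s$top[[1]]$mean_f1, numeric(1))
  win <- which.max(best_f1)
  w2 <- candidates[[win]]$top[[1]]
  w1 <- s1$top[[win]]
  structure(list(
    final_features = w2$features,
    provenance = list(
      step1 = w1[c("selector", "threshold", "classifier", "mean_f1", "var_f1")],
      step1_candidate_rank = win,
      step2 = w2[c("selector", "threshold", "classifier", "mean_f1", "var_f1")]),
    step1 = s1,
    step2_candidates = candidates), class = "two_step_result")
}

#' @export
print.two_step_result <- function(x, ...) {
  p <- x$provenance
  cat(sprintf("two-step pipeline: step1 %s@t1=%d (+%s, F1=%.3f) -> step2 %s@t2=%d (+%s, F1=%.3f)\n",
              p$step1$selector, p$step1$threshold, p$step1$classifier,
              p$step1$mean_f1, p$step2$selector, p$step2$threshold,
              p$step2$classifier, p$step2$mean_f1))
  cat("final features (", length(x$final_features), "): ",
      paste(head(x$final_features, 8), collapse = ", "),
      if (length(x$final_features) > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}
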