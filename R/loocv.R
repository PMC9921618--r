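# Final model selection: leave-one-out cross-validation over the chosen
# feature list, one run per classification algorithm.

#' Select the final classifier by leave-one-out cross-validation
#'
#' For every classifier, each sample is predicted by a model trained on
#' all other samples (z-standardization and SMOTE fitted on the training
#' part of every round); the n pooled predictions yield a full metrics
#' report. The classifier with the best positive-class F1 wins and is
#' refitted on the whole (SMOTE-balanced) dataset to form the final
#' predictor.
#'
#' @param table a [feature_table()].
#' @param final_features character vector of feature names (non-empty,
#'   subset of the table's columns).
#' @param classifiers classifiers to compare (subset of
#'   `knn, nb, svm, dt, mlp, rf`).
#' @param seed integer seed.
#' @param smote_k SMOTE neighbour count.
#' @param classifier_params named list of classifier overrides, as in
#'   [step_config()].
#' @param scheme optional [marker_scheme()] recorded in the predictor.
#' @param provenance optional provenance record (e.g. from
#'   [two_step_pipeline()]).
#' @return A list with `predictor` (class `predictor_model`: features,
#'   classifier tag, fitted state, scaler, scheme, provenance), `metrics`
#'   (named list of `metrics_report`, one per classifier), `predictions`
#'   (matrix n x classifiers) and `winner`.
#' @export
loocv_select_model <- function(table, final_features, classifiers = CLASSIFIER_METHODS,
                               seed = 1L, smote_k = 5L, classifier_params = list(),
                               scheme = NULL, provenance = NULL) {
  stopifnot(inherits(table, "feature_table"))
  if (!length(final_features)) stop("empty final feature list", call. = FALSE)
  classifiers <- match.arg(classifiers, CLASSIFIER_METHODS, several.ok = TRUE)
  tab <- subset_table(table, features = final_features)
  n <- nrow(tab$x)
  y <- tab$y
  if (length(unique(y)) < 2L) stop("both classes must be present", call. = FALSE)
  if (n < 10L) warning("fewer than 10 samples: LOOCV estimates will be unstable")

  preds <- matrix(NA_integer_, n, length(classifiers),
                  dimnames = list(tab$sample_ids, classifiers))
  scores <- matrix(NA_real_, n, length(classifiers),
                   dimnames = list(tab$sample_ids, classifiers))
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    scaler <- fit_scaler(tab$x[tr, , drop = FALSE])
    xtr <- apply_scaler(tab$x[tr, , drop = FALSE], scaler)
    tr_tab <- feature_table(xtr, y[tr], tab$sample_ids[tr])
    tr_bal <- suppressWarnings(
      smote_oversample(tr_tab, smote_k, seed = derive_seed(seed, i)))
    xte <- apply_scaler(tab$x[i, , drop = FALSE], scaler)
    for (m in classifiers) {
      model <- fit_classifier(tr_bal$x, tr_bal$y, m,
                              seed = derive_seed(seed, i * 17L),
                              params = classifier_params)
      pr <- predict_classifier(model, xte)
      preds[i, m] <- pr$class
      scores[i, m] <- pr$score
    }
  }
  metrics <- lapply(setNames(classifiers, classifiers), function(m) {
    compute_metrics(y, preds[, m], scores = scores[, m])
  })
  f1s <- vapply(metrics, `[[`, numeric(1), "f1_positive")
  winner <- classifiers[which.max(f1s)]

  scaler <- fit_scaler(tab$x)
  full <- feature_table(apply_scaler(tab$x, scaler), y, tab$sample_ids)
  full_bal <- suppressWarnings(smote_oversample(full, smote_k,
                                                seed = derive_seed(seed, 9999L)))
  final_fit <- fit_classifier(full_bal$x, full_bal$y, winner,
                              seed = derive_seed(seed, 4242L),
                              params = classifier_params)
  predictor <- structure(list(features = final_features, classifier = winner,
                              fit = final_fit, scaler = scaler, scheme = scheme,
                              provenance = provenance, loocv_f1 = max(f1s)),
                         class = "predictor_model")
  list(predictor = predictor, metrics = metrics, predictions = preds,
       scores = scores, winner = winner)
}

#' Predict marker status for new samples
#' @param object a `predictor_model`.
#' @param newdata numeric matrix (or [feature_table()]) containing the
#'   predictor's feature columns.
#' @param ... unused.
#' @return Integer 0/1 predictions with a `"score"` attribute.
#' @export
predict.predictor_model <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "feature_table")) newdata$x else as.matrix(newdata)
  x <- apply_scaler(x[, object$features, drop = FALSE], object$scaler)
  pr <- predict_classifier(object$fit, x)
  structure(pr$class, score = pr$score)
}

#' @export
print.predictor_model <- function(x, ...) {
  cat(sprintf("predictor_model: %s on %d features (LOOCV F1 = %.3f)%s\n",
              x$classifier, length(x$features), x$loocv_f1,
              if (!is.null(x$scheme)) paste0(" [", x$scheme$marker, "]") else ""))
  invisible(x)
}

#' Serialize a predictor: structured text plus a binary fitted state
#'
#' Writes `<prefix>.yaml` (feature list, classifier tag, marker scheme,
#' provenance) and `<prefix>.rds` (the fitted state).
#'
#' @param predictor a `predictor_model`.
#' @param prefix output path prefix.
#' @return The two paths, invisibly.
#' @export
write_predictor <- function(predictor, prefix) {
  stopifnot(inherits(predictor, "predictor_model"))
  txt <- list(classifier = predictor$classifier,
              features = as.list(predictor$features),
              loocv_f1 = predictor$loocv_f1,
              scheme = if (!is.null(predictor$scheme)) {
                predictor$scheme[c("marker", "type", "threshold")]
              },
              provenance = predictor$provenance)
  ypath <- paste0(prefix, ".yaml")
  rpath <- paste0(prefix, ".rds")
  yaml::write_yaml(txt, ypath)
  saveRDS(predictor, rpath)
  invisible(c(ypath, rpath))
}
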