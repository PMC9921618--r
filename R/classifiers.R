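# Uniform fit/predict interface over the six classification algorithms.
# Hyperparameters are library defaults with fixed seeds; the MLP uses a
# single hidden layer (100 units by default, 1000 iterations).

CLASSIFIER_METHODS <- c("knn", "nb", "svm", "dt", "mlp", "rf")

default_classifier_params <- function() {
  list(knn_k = 5L, mlp_size = 100L, mlp_maxit = 1000L, mlp_decay = 1e-4,
       rf_ntree = 500L)
}

fit_classifier <- function(x, y, method, seed = 1L, params = list()) {
  method <- match.arg(method, CLASSIFIER_METHODS)
  params <- modifyList(default_classifier_params(), params)
  yf <- factor(y, levels = c(0L, 1L))
  x <- as.matrix(x)
  fit <- local_seed(seed, switch(method,
    knn = list(train_x = x, train_y = yf, k = min(params$knn_k, nrow(x))),
    nb = e1071::naiveBayes(x, yf),
    svm = e1071::svm(x, yf, kernel = "radial", scale = FALSE,
                     probability = FALSE),
    dt = {
      df <- data.frame(x, check.names = FALSE)
      df$.label <- yf
      rpart::rpart(.label ~ ., data = df, method = "class")
    },
    mlp = {
      size <- params$mlp_size
      nnet::nnet(x, matrix(as.numeric(yf == "1"), ncol = 1),
                 size = size, maxit = params$mlp_maxit, decay = params$mlp_decay,
                 trace = FALSE, entropy = TRUE,
                 MaxNWts = (ncol(x) + 2) * size + size + 10)
    },
    rf = randomForest::randomForest(x, yf, ntree = params$rf_ntree)))
  structure(list(method = method, fit = fit, seed = seed,
                 feature_names = colnames(x)), class = "radsel_classifier")
}

# Predict classes and a positive-class score.
predict_classifier <- function(model, newx) {
  stopifnot(inherits(model, "radsel_classifier"))
  newx <- as.matrix(newx)[, model$feature_names, drop = FALSE]
  method <- model$method
  fit <- model$fit
  if (method == "knn") {
    pred <- local_seed(model$seed,
      class::knn(fit$train_x, newx, fit$train_y, k = fit$k, prob = TRUE))
    pwin <- attr(pred, "prob")
    cls <- as.integer(as.character(pred))
    score <- ifelse(cls == 1L, pwin, 1 - pwin)
  } else if (method == "nb") {
    pr <- predict(fit, newx, type = "raw")
    score <- pr[, "1"]
    cls <- as.integer(score >= 0.5)
  } else if (method == "svm") {
    pred <- predict(fit, newx, decision.values = TRUE)
    cls <- as.integer(as.character(pred))
    dv <- attr(pred, "decision.values")
    # orient the decision value towards class "1"
    score <- as.numeric(dv) * (if (grepl("^1", colnames(dv)[1])) 1 else -1)
  } else if (method == "dt") {
    pr <- predict(fit, data.frame(newx, check.names = FALSE), type = "prob")
    score <- pr[, "1"]
    cls <- as.integer(score >= 0.5)
  } else if (method == "mlp") {
    score <- as.numeric(predict(fit, newx))
    cls <- as.integer(score >= 0.5)
  } else {  # rf
    pr <- predict(fit, newx, type = "prob")
    score <- pr[, "1"]
    cls <- as.integer(score >= 0.5)
  }
  list(class = cls, score = as.numeric(score))
}
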