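# The nine candidate classifiers behind the model-comparison grid, each
# wrapped to a common fit(x, y) / score(fit, x) surface returning the
# predicted probability of the PD class. Hyperparameters are the
# ecosystem defaults, frozen here (logistic regression carries the
# conventional ridge penalty of the reference implementations, which
# keeps it defined under perfect separation); scale-sensitive learners
# receive z-scored inputs (training statistics), tree learners raw
# values.

MODEL_NAMES <- c("LR", "LDA", "SVM", "DT", "GBT", "RF", "SGD", "GNB", "MP")

# Documented model-complexity order used as the final parsimony tie-break.
MODEL_COMPLEXITY <- c(LR = 1, LDA = 2, GNB = 3, SGD = 4, DT = 5,
                      SVM = 6, RF = 7, GBT = 8, MP = 9)

model_needs_scaling <- function(model) {
  model %in% c("LR", "LDA", "SVM", "SGD", "GNB", "MP")
}

# Drop zero-variance columns (they break LDA/GNB) and z-score.
scale_fit <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, sd)
  keep <- is.finite(sdv) & sdv > 1e-12
  list(mu = mu, sd = sdv, keep = keep)
}

scale_apply <- function(sf, x) {
  x <- x[, sf$keep, drop = FALSE]
  sweep(sweep(x, 2, sf$mu[sf$keep]), 2, sf$sd[sf$keep], "/")
}

#' Fit one of the nine candidate classifiers
#'
#' @param model one of `"LR"`, `"LDA"`, `"SVM"`, `"DT"`, `"GBT"`, `"RF"`,
#'   `"SGD"`, `"GNB"`, `"MP"`
#' @param x numeric feature matrix (rows = participants)
#' @param y group labels, `"PD"`/`"HC"` (PD is the positive class)
#' @param seed integer seed threaded to stochastic learners
#' @return a `bm_fit` object for [predict_scores()]
#' @export
fit_model <- function(model, x, y, seed = 1) {
  model <- match.arg(model, MODEL_NAMES)
  x <- as.matrix(x)
  colnames(x) <- paste0("f", seq_len(ncol(x))) # syntactic, stable names
  ypd <- factor(ifelse(y == "PD", "PD", "HC"), levels = c("HC", "PD"))
  sf <- NULL
  if (model_needs_scaling(model)) {
    sf <- scale_fit(x)
    x <- scale_apply(sf, x)
  }
  fit <- with_seed_(check_seed(seed), tryCatch(switch(model,
    LR = suppressWarnings(glmnet::glmnet(x, ypd, family = "binomial",
                                         alpha = 0, lambda = 1 / nrow(x),
                                         standardize = FALSE)),
    LDA = suppressWarnings(MASS::lda(x, grouping = ypd)),
    SVM = e1071::svm(x, ypd, probability = TRUE, kernel = "radial"),
    DT = rpart::rpart(y ~ ., data = data.frame(y = ypd, x),
                      method = "class"),
    GBT = xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = 3,
                    eta = 0.1, nthread = 1),
      data = xgboost::xgb.DMatrix(x, label = as.numeric(ypd) - 1,
                                  nthread = 1),
      nrounds = 100),
    RF = ranger::ranger(x = x, y = ypd, probability = TRUE,
                        num.trees = 100, importance = "impurity",
                        num.threads = 1,
                        seed = check_seed(seed)),
    SGD = sgd_logistic(x, as.numeric(ypd) - 1),
    GNB = suppressWarnings(e1071::naiveBayes(x, ypd)),
    MP = suppressWarnings(nnet::nnet(x, as.numeric(ypd) - 1, size = 5,
                                     decay = 1e-4, maxit = 100,
                                     MaxNWts = 200000, trace = FALSE))
  ), error = function(e) NULL))
  structure(list(model = model, fit = fit, scaler = sf,
                 n_features = ncol(x)), class = "bm_fit")
}

#' Predicted PD probabilities from a fitted classifier
#'
#' @param object a `bm_fit` from [fit_model()]
#' @param x feature matrix of rows to score
#' @param ... unused
#' @return numeric vector of PD-class probabilities (`NA` if the fit
#'   failed)
#' @export
predict_scores <- function(object, x, ...) {
  x <- as.matrix(x)
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  if (is.null(object$fit)) return(rep(NA_real_, nrow(x)))
  if (!is.null(object$scaler)) x <- scale_apply(object$scaler, x)
  fit <- object$fit
  out <- tryCatch(switch(object$model,
    LR = as.numeric(predict(fit, newx = x, type = "response")),
    LDA = as.numeric(predict(fit, x)$posterior[, "PD"]),
    SVM = {
      pr <- predict(fit, x, probability = TRUE)
      as.numeric(attr(pr, "probabilities")[, "PD"])
    },
    DT = as.numeric(predict(fit, data.frame(x), type = "prob")[, "PD"]),
    GBT = as.numeric(predict(fit, xgboost::xgb.DMatrix(x, nthread = 1))),
    RF = as.numeric(predict(fit, data = x)$predictions[, "PD"]),
    SGD = as.numeric(plogis(cbind(1, x) %*% fit$coef)),
    GNB = as.numeric(predict(fit, x, type = "raw")[, "PD"]),
    MP = as.numeric(predict(fit, x))
  ), error = function(e) rep(NA_real_, nrow(x)))
  pmin(pmax(out, 0), 1)
}

# Mini-batch stochastic-gradient-descent logistic regression with L2
# penalty: the linear-model-by-SGD member of the grid.
sgd_logistic <- function(x, y01, epochs = 20, lr = 0.05, l2 = 1e-4) {
  xb <- cbind(1, x)
  w <- numeric(ncol(xb))
  n <- nrow(xb)
  for (ep in seq_len(epochs)) {
    for (i in sample.int(n)) {
      p <- plogis(sum(xb[i, ] * w))
      g <- (p - y01[i]) * xb[i, ] + l2 * c(0, w[-1])
      w <- w - lr * g
    }
  }
  list(coef = w)
}

#' Binary classification metrics
#'
#' PD is the positive class: sensitivity = TP/(TP+FN), specificity =
#' TN/(TN+FP); predicted label = score > 0.5. AUC is the Mann-Whitney rank
#' statistic of the scores (ties count one half). Metrics with an
#' undefined denominator (or all-missing scores) are `NA`.
#'
#' @param labels true labels (`"PD"`/`"HC"`)
#' @param scores predicted PD probabilities
#' @param threshold decision threshold on the score
#' @return named vector: accuracy, sensitivity, specificity, auc
#' @export
classification_metrics <- function(labels, scores, threshold = 0.5) {
  pos <- labels == "PD"
  ok <- is.finite(scores)
  if (!any(ok)) {
    return(c(accuracy = NA_real_, sensitivity = NA_real_,
             specificity = NA_real_, auc = NA_real_))
  }
  pos <- pos[ok]; scores <- scores[ok]
  pred <- scores > threshold
  tp <- sum(pred & pos); fn <- sum(!pred & pos)
  tn <- sum(!pred & !pos); fp <- sum(pred & !pos)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  auc <- if (sum(pos) > 0 && sum(!pos) > 0) {
    r <- rank(scores)
    (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) / (sum(pos) * sum(!pos))
  } else NA_real_
  c(accuracy = (tp + tn) / length(pos), sensitivity = sens,
    specificity = spec, auc = auc)
}
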