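#' Classification metrics
#'
#' Accuracy, precision, recall and F1 from one-vs-rest confusion counts,
#' macro-averaged over classes (the unweighted mean, so minority-class
#' failure is not masked by class imbalance), plus the full confusion
#' matrix and optional one-vs-rest ROC points.
#'
#' @name metrics
NULL

#' Mean categorical cross-entropy
#'
#' `-(1/N) sum_i sum_c y_ic log(yhat_ic)`. With `from = "logit"` the loss is
#' computed through a log-sum-exp stabilised softmax; with `from = "prob"`
#' the rows must already be probability distributions.
#'
#' @param scores `(N, M)` matrix of logits or probabilities.
#' @param labels length-N vector of 1-based class indices.
#' @param from `"logit"` (default) or `"prob"`.
#' @return scalar loss.
#' @export
cross_entropy <- function(scores, labels, from = c("logit", "prob")) {
  from <- match.arg(from)
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (length(labels) != n) stop("labels length must match rows of scores")
  if (any(labels < 1L | labels > ncol(scores))) stop("label out of range")
  if (from == "prob") {
    if (any(abs(rowSums(scores) - 1) > 1e-6)) {
      stop("probability rows must sum to 1")
    }
    return(-mean(log(pmax(scores[cbind(seq_len(n), labels)], 1e-300))))
  }
  m <- scores - apply(scores, 1, max)
  mean(log(rowSums(exp(m))) - m[cbind(seq_len(n), labels)])
}

#' Compute the full metrics report
#'
#' @param predictions length-N vector of predicted 1-based class indices.
#' @param labels length-N vector of true 1-based class indices.
#' @param M number of classes.
#' @return list of class `metrics_report`: `accuracy` (trace / total),
#'   macro `precision`, `recall`, `f1`, `per_class` data.frame with
#'   TP/TN/FP/FN and per-class scores (precision is 0 for a class never
#'   predicted), and the `confusion` matrix (rows = truth, cols =
#'   prediction).
#' @export
compute_metrics <- function(predictions, labels, M) {
  n <- length(labels)
  if (n == 0L) stop("empty input")
  if (length(predictions) != n) stop("predictions and labels differ in length")
  if (any(c(predictions, labels) < 1L | c(predictions, labels) > M)) {
    stop("class index out of range 1..", M)
  }
  cm <- matrix(0L, M, M)
  for (i in seq_len(n)) cm[labels[i], predictions[i]] <- cm[labels[i], predictions[i]] + 1L
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  tn <- n - tp - fp - fn
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  rec <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  structure(list(
    accuracy = sum(tp) / n,
    precision = mean(prec),
    recall = mean(rec),
    f1 = mean(f1),
    per_class = data.frame(class = seq_len(M), TP = tp, TN = tn, FP = fp,
                           FN = fn, precision = prec, recall = rec, f1 = f1),
    confusion = cm,
    n = n
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("n = %d  accuracy %.2f%%  precision %.2f%%  recall %.2f%%  F1 %.2f%%\n",
              x$n, 100 * x$accuracy, 100 * x$precision, 100 * x$recall,
              100 * x$f1))
  invisible(x)
}

#' One-vs-rest ROC points for each class
#'
#' @param probs `(N, M)` matrix of class probabilities.
#' @param labels true 1-based class indices.
#' @return list of per-class data.frames with `threshold`, `tpr`, `fpr`
#'   (computed with pROC when installed, otherwise by direct sweep).
#' @export
roc_points <- function(probs, labels) {
  M <- ncol(probs)
  lapply(seq_len(M), function(cls) {
    y <- as.integer(labels == cls)
    s <- probs[, cls]
    if (requireNamespace("pROC", quietly = TRUE) && length(unique(y)) == 2L) {
      r <- pROC::roc(y, s, quiet = TRUE, direction = "<")
      data.frame(threshold = r$thresholds, tpr = r$sensitivities,
                 fpr = 1 - r$specificities)
    } else {
      th <- sort(unique(c(-Inf, s, Inf)))
      do.call(rbind, lapply(th, function(t) {
        pred <- s >= t
        data.frame(threshold = t,
                   tpr = if (sum(y) > 0) sum(pred & y == 1) / sum(y) else NA,
                   fpr = if (sum(1 - y) > 0) sum(pred & y == 0) / sum(1 - y) else NA)
      }))
    }
  })
}
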