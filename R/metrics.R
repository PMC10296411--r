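# Classification metrics: confusion matrix, one-vs-rest precision / recall /
# F1 / accuracy, and rank-statistic AUC averaged over one-vs-rest reductions.

#' Binary confusion-count metrics
#'
#' Precision, recall, accuracy and F1 from raw true/false positive/negative
#' counts. Ratios with zero denominators are defined as 0.
#'
#' @param tp,fp,fn,tn Non-negative counts.
#' @return List with `precision`, `recall`, `accuracy`, `f1`.
#' @export
binary_metrics <- function(tp, fp, fn, tn) {
  sdiv <- function(a, b) if (b > 0) a / b else 0
  precision <- sdiv(tp, tp + fp)
  recall <- sdiv(tp, tp + fn)
  list(
    precision = precision,
    recall = recall,
    accuracy = sdiv(tp + tn, tp + tn + fp + fn),
    f1 = sdiv(2 * precision * recall, precision + recall)
  )
}

#' Rank-statistic AUC for one binary reduction
#'
#' Area under the ROC curve computed as the Mann-Whitney statistic: the
#' probability a positive sample is scored above a negative one, with ties
#' counted one half. Invariant to strictly monotone transformations of the
#' scores.
#'
#' @param scores Numeric scores, higher meaning more positive.
#' @param positive Logical vector marking the positive class.
#' @return AUC in `[0, 1]`, or `NA` if either class is absent.
#' @export
rank_auc <- function(scores, positive) {
  positive <- as.logical(positive)
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)  # average ranks handle ties
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate a classifier's predictions
#'
#' Builds the confusion matrix, reduces it one-vs-rest per class, and reports
#' macro-averaged precision, recall and F1, overall accuracy, and the mean of
#' the per-class one-vs-rest AUCs.
#'
#' @param probs `n x n_classes` matrix of class probabilities (rows sum
#'   to 1).
#' @param y True labels, `1..n_classes` or 0-based.
#' @return Object of class `eval_report`: list with `confusion` (rows =
#'   truth, cols = prediction), `precision`, `recall`, `accuracy`, `f1`,
#'   `auc`, `per_class` (data frame of one-vs-rest counts and metrics) and
#'   `n`.
#' @export
evaluate_predictions <- function(probs, y) {
  if (is.null(dim(probs))) stop("probs must be a matrix of class probabilities")
  K <- ncol(probs)
  if (nrow(probs) == 0L) stop("empty evaluation set")
  y <- .canon_labels(y, K)
  pred <- max.col(probs, ties.method = "first")
  confusion <- matrix(0L, K, K,
                      dimnames = list(truth = seq_len(K) - 1L,
                                      predicted = seq_len(K) - 1L))
  for (i in seq_along(y)) {
    confusion[y[i], pred[i]] <- confusion[y[i], pred[i]] + 1L
  }
  per_class <- do.call(rbind, lapply(seq_len(K), function(k) {
    tp <- confusion[k, k]
    fp <- sum(confusion[-k, k])
    fn <- sum(confusion[k, -k])
    tn <- sum(confusion) - tp - fp - fn
    m <- binary_metrics(tp, fp, fn, tn)
    data.frame(class = k - 1L, tp = tp, fp = fp, fn = fn, tn = tn,
               precision = m$precision, recall = m$recall, f1 = m$f1,
               auc = rank_auc(probs[, k], y == k))
  }))
  macro <- function(v) mean(v)
  structure(
    list(confusion = confusion,
         precision = macro(per_class$precision),
         recall = macro(per_class$recall),
         accuracy = sum(diag(confusion)) / length(y),
         f1 = macro(per_class$f1),
         auc = mean(per_class$auc, na.rm = TRUE),
         per_class = per_class, n = length(y)),
    class = "eval_report"
  )
}

#' Evaluate a trained BiLSTM on labeled data
#'
#' @param model A `bilstm_model`.
#' @param x Samples-by-features matrix or list of fused vectors.
#' @param y True labels.
#' @return An `eval_report`; see [evaluate_predictions()].
#' @export
evaluate_bilstm <- function(model, x, y) {
  evaluate_predictions(predict_bilstm(model, x), y)
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(paste0("Evaluation of %d samples: accuracy %.3f, ",
                     "macro precision %.3f, recall %.3f, F1 %.3f, ",
                     "mean one-vs-rest AUC %.3f\n"),
              x$n, x$accuracy, x$precision, x$recall, x$f1, x$auc))
  print(x$confusion)
  invisible(x)
}
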