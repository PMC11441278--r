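#' Confusion counts at a decision threshold
#'
#' A pair is predicted interacting iff its score is greater than or equal to
#' the threshold (ties count as positive).
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 truth labels of the same length.
#' @param threshold Decision threshold (default 0.5).
#' @return Named integer vector `c(tp, tn, fp, fn)`.
#' @export
confusion_counts <- function(scores, labels, threshold = 0.5) {
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0 or 1")
  pred <- scores >= threshold
  c(tp = sum(pred & labels == 1), tn = sum(!pred & labels == 0),
    fp = sum(pred & labels == 0), fn = sum(!pred & labels == 1))
}

#' Point metrics from confusion counts
#'
#' Standard definitions: accuracy `(TP+TN)/total`, precision `TP/(TP+FP)`,
#' recall `TP/(TP+FN)` (the fraction of genuine positives recovered), and
#' `F1 = 2PR/(P+R)`. A zero denominator yields 0 for that metric.
#'
#' @param tp,tn,fp,fn Nonnegative counts.
#' @return Named numeric vector `c(acc, precision, recall, f1)`.
#' @examples
#' point_metrics(tp = 3, tn = 4, fp = 1, fn = 2)
#' @export
point_metrics <- function(tp, tn, fp, fn) {
  total <- tp + tn + fp + fn
  if (total == 0) stop("all confusion counts are zero")
  safe_div <- function(num, den) if (den == 0) 0 else num / den
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  c(acc = (tp + tn) / total,
    precision = precision,
    recall = recall,
    f1 = safe_div(2 * precision * recall, precision + recall))
}

#' Area under the ROC curve
#'
#' Trapezoidal area under the (FPR, TPR) curve swept over all distinct score
#' thresholds; with ties this equals the Mann-Whitney statistic counting
#' tied positive-negative pairs as one half.
#'
#' @param scores Numeric scores (higher = more likely interacting).
#' @param labels 0/1 labels; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  if (!all(labels %in% c(0, 1))) stop("labels must be 0 or 1")
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  sw <- roc_sweep(scores, labels)
  sum(diff(c(0, sw$fpr)) * (head(c(0, sw$tpr), -1) + sw$tpr) / 2)
}

# Cumulative TP/FP over thresholds descending through the distinct scores
# (tied scores collapse into one threshold step).
roc_sweep <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  last <- !duplicated(s, fromLast = TRUE)  # last index of each tie group
  ctp <- cumsum(y == 1)[last]
  cfp <- cumsum(y == 0)[last]
  list(tpr = ctp / sum(labels == 1), fpr = cfp / sum(labels == 0),
       tp = ctp, fp = cfp, threshold = s[last])
}

#' Area under the precision-recall curve
#'
#' Stepwise accumulation over thresholds sorted by descending score:
#' `sum_i (Recall_i - Recall_{i-1}) * Precision_i` with `Recall_0 = 0`.
#'
#' @inheritParams roc_auc
#' @return AUPR in `[0, 1]`.
#' @export
pr_auc <- function(scores, labels) {
  if (!all(labels %in% c(0, 1))) stop("labels must be 0 or 1")
  n_pos <- sum(labels == 1)
  if (n_pos == 0) stop("no positive labels")
  sw <- roc_sweep(scores, labels)
  recall <- sw$tp / n_pos
  precision <- sw$tp / (sw$tp + sw$fp)
  sum(diff(c(0, recall)) * precision)
}

#' Evaluate a trained model
#'
#' Scores the given pairs (default: the model's balanced validation
#' partition) and assembles threshold-free (AUC, AUPR) and thresholded
#' (accuracy, F1, precision, recall) metrics plus the confusion counts.
#'
#' @param model A trained [lmi_train()] model.
#' @param pairs Data frame with `lncrna_id`, `mirna_id`, `label`; defaults to
#'   the model's validation partition.
#' @param threshold Decision threshold (default from the model config).
#' @return An object of class `lmi_eval`; see [tidy.lmi_eval()],
#'   [glance.lmi_eval()] and [autoplot.lmi_eval()].
#' @export
lmi_evaluate <- function(model, pairs = NULL, threshold = NULL) {
  if (is.null(pairs)) {
    pairs <- model$splits[model$splits$partition == "validation", ]
  }
  if (is.null(threshold)) threshold <- model$config$threshold
  scored <- predict(model, pairs)
  cm <- confusion_counts(scored$score, scored$label, threshold)
  pm <- point_metrics(cm[["tp"]], cm[["tn"]], cm[["fp"]], cm[["fn"]])
  structure(list(
    auc = roc_auc(scored$score, scored$label),
    aupr = pr_auc(scored$score, scored$label),
    acc = pm[["acc"]], f1 = pm[["f1"]],
    precision = pm[["precision"]], recall = pm[["recall"]],
    threshold = threshold, counts = cm,
    scored = scored, config = model$config, seed = model$seed
  ), class = "lmi_eval")
}

#' @export
print.lmi_eval <- function(x, ...) {
  cat(sprintf(paste0("<lmi_eval> AUC %.4f  AUPR %.4f  ACC %.4f  F1 %.4f  ",
                     "Precision %.4f  Recall %.4f (threshold %.2f, n = %d)\n"),
              x$auc, x$aupr, x$acc, x$f1, x$precision, x$recall,
              x$threshold, sum(x$counts)))
  invisible(x)
}

#' Tidy an evaluation report
#'
#' @param x An `lmi_eval` object.
#' @param ... Unused.
#' @return One row per metric with columns `metric` and `value`.
#' @export
tidy.lmi_eval <- function(x, ...) {
  tibble::tibble(metric = c("auc", "aupr", "acc", "f1", "precision", "recall"),
                 value = c(x$auc, x$aupr, x$acc, x$f1, x$precision, x$recall))
}

#' One-row summary of an evaluation report
#'
#' @param x An `lmi_eval` object.
#' @param ... Unused.
#' @export
glance.lmi_eval <- function(x, ...) {
  tibble::tibble(auc = x$auc, aupr = x$aupr, acc = x$acc, f1 = x$f1,
                 precision = x$precision, recall = x$recall,
                 threshold = x$threshold,
                 tp = x$counts[["tp"]], tn = x$counts[["tn"]],
                 fp = x$counts[["fp"]], fn = x$counts[["fn"]],
                 n = sum(x$counts))
}

#' ROC / precision-recall curves of an evaluation
#'
#' @param object An `lmi_eval` object.
#' @param which `"roc"` or `"pr"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lmi_eval <- function(object, which = c("roc", "pr"), ...) {
  which <- match.arg(which)
  df <- curve_points(object$scored$score, object$scored$label)
  if (which == "roc") {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
      ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
      ggplot2::geom_step() +
      ggplot2::labs(x = "False positive rate", y = "True positive rate",
                    title = sprintf("ROC (AUC = %.4f)", object$auc)) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$recall, y = .data$precision)) +
      ggplot2::geom_step(direction = "vh") +
      ggplot2::ylim(0, 1) +
      ggplot2::labs(x = "Recall", y = "Precision",
                    title = sprintf("Precision-recall (AUPR = %.4f)", object$aupr)) +
      ggplot2::theme_minimal()
  }
}

#' @importFrom ggplot2 .data
curve_points <- function(scores, labels) {
  sw <- roc_sweep(scores, labels)
  tibble::tibble(threshold = sw$threshold,
                 fpr = sw$fpr, tpr = sw$tpr,
                 recall = sw$tp / sum(labels == 1),
                 precision = sw$tp / (sw$tp + sw$fp))
}

#' Write an evaluation report to JSON (and optionally curves to TSV)
#'
#' @param eval_report An `lmi_eval` object.
#' @param path Output JSON path.
#' @param curves_path Optional TSV path for the ROC/PR curve points.
#' @export
write_report <- function(eval_report, path, curves_path = NULL) {
  out <- list(metrics = as.list(glance(eval_report)),
              config = unclass(eval_report$config),
              seed = eval_report$seed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(curves_path)) {
    readr::write_tsv(curve_points(eval_report$scored$score,
                                  eval_report$scored$label), curves_path)
  }
  invisible(path)
}
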