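check_label_vector <- function(labels, what = "labels") {
  labels <- as.character(labels)
  if (length(labels) == 0L) stop_validation(what, " must be non-empty")
  if (!all(labels %in% c("positive", "negative"))) {
    stop_validation(what, " must be 'positive' or 'negative'")
  }
  labels
}

#' Confusion counts for binary 6mA predictions
#'
#' Counts are kept in the class-wise form used by the evaluation measures:
#' the class sizes `n_pos` / `n_neg` together with the false negatives
#' (positives predicted negative) and false positives (negatives predicted
#' positive).
#'
#' @param labels True labels, `"positive"` / `"negative"`.
#' @param predictions Predicted labels, same length and coding.
#' @return An object of class `confusion_counts` with fields `n_pos`,
#'   `n_neg`, `fn`, `fp`.
#' @export
confusion_counts <- function(labels, predictions) {
  labels <- check_label_vector(labels, "labels")
  predictions <- check_label_vector(predictions, "predictions")
  if (length(labels) != length(predictions)) {
    stop_validation("labels and predictions differ in length")
  }
  structure(
    list(
      n_pos = sum(labels == "positive"),
      n_neg = sum(labels == "negative"),
      fn = sum(labels == "positive" & predictions == "negative"),
      fp = sum(labels == "negative" & predictions == "positive")
    ),
    class = "confusion_counts"
  )
}

#' Threshold metrics from confusion counts
#'
#' Computes the class-wise measures
#' \deqn{Sn = 1 - FN/N^+,\quad Sp = 1 - FP/N^-,\quad
#'       ACC = 1 - (FN + FP)/(N^+ + N^-)}
#' and the Matthews correlation coefficient in its class-wise form
#' \deqn{MCC = \frac{1 - (FN/N^+ + FP/N^-)}
#'   {\sqrt{(1 + (FP - FN)/N^+)(1 + (FN - FP)/N^-)}}}
#' which is algebraically identical to the usual confusion-matrix MCC.
#' F1 is the harmonic mean of precision and recall with the 6mA (positive)
#' class as the target. An MCC denominator of zero yields MCC = 0 with a
#' message.
#'
#' @param counts A [confusion_counts] object (or a list with the same
#'   fields).
#' @return Named list with `sn`, `sp`, `acc`, `mcc`, `f1`.
#' @export
point_metrics <- function(counts) {
  n_pos <- counts$n_pos
  n_neg <- counts$n_neg
  fn <- counts$fn
  fp <- counts$fp
  if (n_pos < 1L || n_neg < 1L) {
    stop_validation("both classes must be represented to compute Sn/Sp")
  }
  if (fn < 0L || fn > n_pos || fp < 0L || fp > n_neg) {
    stop_validation("counts out of range: need 0 <= fn <= n_pos and 0 <= fp <= n_neg")
  }
  sn <- 1 - fn / n_pos
  sp <- 1 - fp / n_neg
  acc <- 1 - (fn + fp) / (n_pos + n_neg)
  den_sq <- (1 + (fp - fn) / n_pos) * (1 + (fn - fp) / n_neg)
  if (den_sq <= 0) {
    message("point_metrics: MCC denominator is zero; reporting MCC = 0")
    mcc <- 0
  } else {
    mcc <- (1 - (fn / n_pos + fp / n_neg)) / sqrt(den_sq)
  }
  tp <- n_pos - fn
  precision <- if (tp + fp == 0L) 0 else tp / (tp + fp)
  recall <- sn
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  list(sn = sn, sp = sp, acc = acc, mcc = mcc, f1 = f1)
}

score_groups <- function(labels, scores) {
  labels <- check_label_vector(labels)
  if (!is.numeric(scores) || length(scores) != length(labels)) {
    stop_validation("scores must be numeric and match labels in length")
  }
  if (any(!is.finite(scores))) stop_validation("scores must be finite")
  n_pos <- sum(labels == "positive")
  n_neg <- sum(labels == "negative")
  if (n_pos == 0L || n_neg == 0L) {
    stop_validation("both classes must be present for threshold-free curves")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  pos <- labels[ord] == "positive"
  # group tied scores into one threshold step
  last <- cumsum(rle(s)$lengths)
  list(
    cum_tp = cumsum(pos)[last],
    cum_fp = cumsum(!pos)[last],
    n_pos = n_pos,
    n_neg = n_neg
  )
}

#' ROC curve and AUC
#'
#' Sweeps every distinct score as a threshold (ties grouped into a single
#' step) and integrates the ROC curve by the trapezoidal rule; with tied
#' scores this equals the Mann-Whitney U statistic divided by
#' `n_pos * n_neg`, counting ties as half.
#'
#' @param labels True labels.
#' @param scores Numeric scores; larger means more positive-like.
#' @return List with `auc` and `points`, a data.frame of `(fpr, tpr)` from
#'   (0, 0) to (1, 1) with non-decreasing `fpr`.
#' @export
roc_auc <- function(labels, scores) {
  g <- score_groups(labels, scores)
  tpr <- c(0, g$cum_tp / g$n_pos)
  fpr <- c(0, g$cum_fp / g$n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  list(auc = auc, points = data.frame(fpr = fpr, tpr = tpr))
}

#' Precision-recall curve and average precision
#'
#' Average precision is the step-sum
#' `AP = sum_i (R_i - R_{i-1}) * P_i` over descending-score thresholds, with
#' tied scores grouped into one step.
#'
#' @inheritParams roc_auc
#' @return List with `ap` and `points`, a data.frame of
#'   `(recall, precision)` per threshold.
#' @export
average_precision <- function(labels, scores) {
  g <- score_groups(labels, scores)
  recall <- g$cum_tp / g$n_pos
  precision <- g$cum_tp / (g$cum_tp + g$cum_fp)
  ap <- sum(diff(c(0, recall)) * precision)
  list(ap = ap, points = data.frame(recall = recall, precision = precision))
}

#' Full evaluation report for scored predictions
#'
#' Applies the probability cutoff (default 0.5) for the threshold measures
#' and computes the threshold-free ROC/AUC and precision-recall/AP curves.
#'
#' @param labels True labels.
#' @param scores Numeric scores in `[0, 1]`; `score >= cutoff` predicts
#'   positive.
#' @param cutoff Decision cutoff, default 0.5.
#' @return An object of class `evaluation_report`: fields `sn`, `sp`, `acc`,
#'   `mcc`, `f1`, `auc`, `ap`, plus `roc_points` and `pr_points`
#'   data.frames.
#' @export
evaluate_predictions <- function(labels, scores, cutoff = 0.5) {
  labels <- check_label_vector(labels)
  preds <- ifelse(scores >= cutoff, "positive", "negative")
  pm <- point_metrics(confusion_counts(labels, preds))
  roc <- roc_auc(labels, scores)
  pr <- average_precision(labels, scores)
  structure(
    c(pm, list(
      auc = roc$auc, ap = pr$ap,
      roc_points = roc$points, pr_points = pr$points
    )),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "<evaluation_report> Sn=%.3f Sp=%.3f ACC=%.3f MCC=%.3f AUC=%.3f AP=%.3f F1=%.3f\n",
    x$sn, x$sp, x$acc, x$mcc, x$auc, x$ap, x$f1
  ))
  invisible(x)
}

report_scalars <- function(report) {
  unlist(report[c("sn", "sp", "acc", "mcc", "auc", "ap", "f1")])
}

#' Serialize an evaluation report to JSON
#'
#' @param report An [evaluate_predictions()] report.
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @param curves Include the ROC and PR curve points? Default `TRUE`.
#' @return The JSON string (invisibly when written to `path`).
#' @export
report_to_json <- function(report, path = NULL, curves = TRUE) {
  obj <- as.list(report_scalars(report))
  if (curves) {
    obj$roc_points <- report$roc_points
    obj$pr_points <- report$pr_points
  }
  if (is.null(path)) {
    jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  }
}

#' Write ROC / precision-recall curve points as TSV
#'
#' @param report An evaluation report.
#' @param roc_path,pr_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, a character vector of the paths written.
#' @export
write_curves_tsv <- function(report, roc_path = NULL, pr_path = NULL) {
  written <- character(0)
  if (!is.null(roc_path)) {
    utils::write.table(report$roc_points, roc_path,
      sep = "\t", row.names = FALSE, quote = FALSE
    )
    written <- c(written, roc_path)
  }
  if (!is.null(pr_path)) {
    utils::write.table(report$pr_points, pr_path,
      sep = "\t", row.names = FALSE, quote = FALSE
    )
    written <- c(written, pr_path)
  }
  invisible(written)
}
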