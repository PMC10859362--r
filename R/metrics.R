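# Confusion-matrix construction and multiclass evaluation metrics.
#
# Labels are 0-based integers in [0, K) throughout the package (they mirror
# the lexicographic rank of the class folders on disk). Per-class precision,
# recall and F1 come from one-vs-rest reductions of the K x K matrix; macro
# values are unweighted means over classes with defined ratios, and micro
# pooling (which equals overall accuracy for single-label problems) is
# reported alongside for transparency.

#' Confusion matrix from label vectors
#'
#' Entry (r, c) counts samples with true class `r` predicted as class `c`
#' (0-based labels; row/column names carry the class labels or names).
#'
#' @param y_true,y_pred equal-length integer label vectors with values in
#'   `[0, n_classes)`.
#' @param n_classes number of classes `K`.
#' @param class_names optional character vector of length `K`.
#' @return a K x K integer matrix of class `confusion_matrix`.
#' @export
confusion_matrix <- function(y_true, y_pred, n_classes,
                             class_names = NULL) {
  if (length(y_true) != length(y_pred)) {
    stop(sprintf("label vectors differ in length (%d vs %d)",
                 length(y_true), length(y_pred)), call. = FALSE)
  }
  y_true <- as.integer(y_true)
  y_pred <- as.integer(y_pred)
  n_classes <- as.integer(n_classes)
  bad <- which(y_true < 0L | y_true >= n_classes |
                 y_pred < 0L | y_pred >= n_classes)
  if (length(bad) > 0L) {
    stop(sprintf("label out of range [0, %d) at index %d",
                 n_classes, bad[1L]), call. = FALSE)
  }
  cm <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(y_true)) {
    cm[y_true[i] + 1L, y_pred[i] + 1L] <- cm[y_true[i] + 1L, y_pred[i] + 1L] + 1L
  }
  if (is.null(class_names)) class_names <- as.character(seq_len(n_classes) - 1L)
  dimnames(cm) <- list(true = class_names, predicted = class_names)
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

#' One-vs-rest counts for a class
#'
#' Reduces the K x K matrix to the 2 x 2 counts of class `k` treated as
#' positive: TP is the diagonal entry, FP the rest of the predicted column,
#' FN the rest of the true row, and TN the remainder.
#'
#' @param cm a [confusion_matrix()].
#' @param k 0-based class index.
#' @return named integer vector `c(TP, FP, FN, TN)`.
#' @export
one_vs_rest_counts <- function(cm, k) {
  K <- nrow(cm)
  k <- as.integer(k)
  if (k < 0L || k >= K) {
    stop(sprintf("class index k = %d out of range [0, %d)", k, K),
         call. = FALSE)
  }
  i <- k + 1L
  tp <- cm[i, i]
  fp <- sum(cm[, i]) - tp
  fn <- sum(cm[i, ]) - tp
  tn <- sum(cm) - tp - fp - fn
  c(TP = tp, FP = fp, FN = fn, TN = tn)
}

#' Evaluation metrics report
#'
#' Computes per-class precision TP/(TP+FP), recall TP/(TP+FN) and
#' F1 = 2TP/(2TP+FP+FN), their macro (unweighted) means, micro-pooled values,
#' and overall accuracy (trace / total). Classes with a zero denominator get
#' `NA` and are excluded from the macro means; their count is reported.
#'
#' @param cm a [confusion_matrix()].
#' @return a list of class `metrics_report` with elements `per_class`
#'   (data.frame), `accuracy`, `macro_precision`, `macro_recall`, `macro_f1`,
#'   `micro_precision`, `micro_recall`, `micro_f1`, `n_undefined`.
#' @export
metric_report <- function(cm) {
  total <- sum(cm)
  if (total <= 0L) stop("confusion matrix is empty", call. = FALSE)
  K <- nrow(cm)
  counts <- t(vapply(seq_len(K) - 1L, function(k) one_vs_rest_counts(cm, k),
                     numeric(4)))
  tp <- counts[, 1L]; fp <- counts[, 2L]; fn <- counts[, 3L]
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
  f1 <- ifelse(2 * tp + fp + fn > 0, 2 * tp / (2 * tp + fp + fn), NA_real_)
  per_class <- data.frame(class = rownames(cm),
                          support = as.integer(tp + fn),
                          precision = precision, recall = recall, f1 = f1,
                          stringsAsFactors = FALSE)
  structure(list(
    per_class = per_class,
    accuracy = sum(tp) / total,
    macro_precision = mean(precision, na.rm = TRUE),
    macro_recall = mean(recall, na.rm = TRUE),
    macro_f1 = mean(f1, na.rm = TRUE),
    micro_precision = sum(tp) / sum(tp + fp),
    micro_recall = sum(tp) / sum(tp + fn),
    micro_f1 = 2 * sum(tp) / sum(2 * tp + fp + fn),
    n_undefined = sum(is.na(precision) | is.na(recall) | is.na(f1)),
    total = total
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("metrics report (%d samples, %d classes)\n",
              x$total, nrow(x$per_class)))
  cat(sprintf("  accuracy        %6.2f%%\n", 100 * x$accuracy))
  cat(sprintf("  macro precision %6.2f%%\n", 100 * x$macro_precision))
  cat(sprintf("  macro recall    %6.2f%%\n", 100 * x$macro_recall))
  cat(sprintf("  macro F1        %6.2f%%\n", 100 * x$macro_f1))
  if (x$n_undefined > 0L) {
    cat(sprintf("  (%d class(es) with undefined ratios excluded from macro means)\n",
                x$n_undefined))
  }
  invisible(x)
}

#' Write evaluation artifacts
#'
#' Writes the confusion matrix as CSV (with class-name header), the metrics
#' report as JSON, and the per-class table as CSV.
#'
#' @param report a [metric_report()].
#' @param cm the matching [confusion_matrix()].
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_metrics <- function(report, cm, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cm_path <- file.path(dir, "confusion.csv")
  utils::write.csv(as.data.frame(unclass(cm)), cm_path, row.names = TRUE)
  pc_path <- file.path(dir, "per_class.csv")
  utils::write.csv(report$per_class, pc_path, row.names = FALSE)
  js_path <- file.path(dir, "metrics.json")
  jsonlite::write_json(
    list(accuracy = report$accuracy,
         macro_precision = report$macro_precision,
         macro_recall = report$macro_recall,
         macro_f1 = report$macro_f1,
         micro_precision = report$micro_precision,
         micro_recall = report$micro_recall,
         micro_f1 = report$micro_f1,
         n_undefined = report$n_undefined,
         total = report$total),
    js_path, auto_unbox = TRUE, digits = NA)
  invisible(c(cm_path, pc_path, js_path))
}
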