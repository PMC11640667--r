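# Evaluation suite. Identification is a multiclass task scored one-vs-rest:
# for class i, TP_i is the diagonal count, FP_i its column remainder, FN_i
# its row remainder and TN_i the rest; per-class precision, recall and F1
# are macro-averaged over the N classes. Top-1 accuracy is correct/total;
# top-k credits a sample when the true label is among the k most probable.
# Confidence-thresholded accuracy retains only predictions whose top-1
# confidence reaches the threshold and scores accuracy among the retained,
# alongside the retained fraction.

#' Multiclass confusion matrix
#'
#' @param true,predicted Label vectors of equal length; every label must
#'   appear in `label_order`.
#' @param label_order Class labels fixing row/column order (rows = true,
#'   columns = predicted).
#' @return `N x N` integer matrix of class `confusion_matrix`.
#' @export
confusion_matrix <- function(true, predicted, label_order) {
  stopifnot(length(true) == length(predicted))
  if (!all(c(true, predicted) %in% label_order))
    stop("label-mismatch: labels outside label_order", call. = FALSE)
  f <- factor(true, levels = label_order)
  g <- factor(predicted, levels = label_order)
  m <- table(true = f, predicted = g)
  cm <- matrix(as.integer(m), nrow(m), ncol(m),
               dimnames = list(true = label_order, predicted = label_order))
  structure(cm, class = c("confusion_matrix", "matrix"))
}

#' Macro-averaged precision, recall and F1 from a confusion matrix
#'
#' One-vs-rest per class: `precision_i = TP_i / (TP_i + FP_i)`,
#' `recall_i = TP_i / (TP_i + FN_i)`,
#' `F1_i = 2 * precision_i * recall_i / (precision_i + recall_i)`;
#' macro values are their arithmetic means over the N classes. A class
#' with a zero denominator (no predicted or no true positives) scores 0
#' for that metric — a conservative convention that balanced test sets
#' rarely trigger.
#'
#' @param cm A [confusion_matrix()].
#' @return List with `per_class` (`data.frame`: precision, recall, f1 per
#'   class), `mean_precision`, `mean_recall`, `mean_f1`, `top1_acc`
#'   (micro accuracy `sum(diag)/total`) and `N`.
#' @export
macro_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix") || (is.matrix(cm) && nrow(cm) == ncol(cm)))
  total <- sum(cm)
  if (total == 0L) stop("empty confusion matrix", call. = FALSE)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  safe_div <- function(num, den) ifelse(den > 0, num / den, 0)
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  list(per_class = data.frame(class = rownames(cm), precision = precision,
                              recall = recall, f1 = f1, row.names = NULL),
       mean_precision = mean(precision), mean_recall = mean(recall),
       mean_f1 = mean(f1), top1_acc = sum(tp) / total, N = nrow(cm))
}

#' Top-k accuracy of a confidence dump
#'
#' Fraction of samples whose true label is among the `k` highest-
#' probability labels (ties broken by column index). Non-decreasing in `k`
#' and identically 1 at `k = N`.
#'
#' @param dump Confidence dump (see [evaluate_view_model()]).
#' @param k Number of top labels credited.
#' @return Fraction in `[0, 1]`.
#' @export
top_k_accuracy <- function(dump, k) {
  d <- dump_probs(dump)
  if (k < 1 || k > length(d$labels)) stop("invalid-k", call. = FALSE)
  hit <- vapply(seq_len(nrow(d$P)), function(i) {
    d$true[i] %in% topk_labels(d$P[i, ], k, d$labels)
  }, TRUE)
  mean(hit)
}

#' Full metrics report for a confidence dump
#'
#' @param dump Confidence dump.
#' @param top_k Additional top-k level to report (default 5, clamped
#'   to N).
#' @return List with `top1_acc`, `top5_acc`, macro means, `per_class` and
#'   `N` (see [macro_metrics()]).
#' @export
metrics_report <- function(dump, top_k = 5L) {
  d <- dump_probs(dump)
  pred <- d$labels[max.col(d$P, ties.method = "first")]
  mm <- macro_metrics(confusion_matrix(d$true, pred, d$labels))
  mm$top5_acc <- top_k_accuracy(dump, min(top_k, length(d$labels)))
  mm
}

#' Accuracy among confidently retained predictions
#'
#' Retains the samples whose top-1 confidence is at least `tau`, scores
#' top-1 accuracy over the retained only (sub-threshold samples leave both
#' numerator and denominator) and reports the retained fraction. With
#' `tau = 0` this is exactly plain top-1 accuracy at full retention; when
#' nothing is retained the accuracy is `NA`.
#'
#' @param true,predicted Label vectors.
#' @param confidence Top-1 confidences in `[0, 1]`.
#' @param tau Threshold in `[0, 1]`.
#' @return List with `accuracy` (or `NA` if nothing retained),
#'   `retained_fraction` and `n_retained`.
#' @export
thresholded_accuracy <- function(true, predicted, confidence, tau) {
  if (tau < 0 || tau > 1) stop("invalid-threshold: tau must be in [0,1]", call. = FALSE)
  stopifnot(length(true) == length(predicted),
            length(true) == length(confidence),
            all(confidence >= 0 & confidence <= 1))
  keep <- confidence >= tau
  list(accuracy = if (any(keep)) mean(true[keep] == predicted[keep]) else NA_real_,
       retained_fraction = mean(keep), n_retained = sum(keep))
}

#' Accuracy/retention curve over confidence thresholds
#'
#' @param true,predicted,confidence As in [thresholded_accuracy()].
#' @param thresholds Ascending thresholds (default `c(0, .6, .7, .8, .9)`,
#'   the levels conventionally tabulated).
#' @return `data.frame` with `threshold`, `accuracy`, `retained_fraction`;
#'   `retained_fraction` is non-increasing in the threshold.
#' @export
threshold_curve <- function(true, predicted, confidence,
                            thresholds = c(0, 0.6, 0.7, 0.8, 0.9)) {
  stopifnot(!is.unsorted(thresholds))
  rows <- lapply(thresholds, function(tau) {
    r <- thresholded_accuracy(true, predicted, confidence, tau)
    data.frame(threshold = tau, accuracy = r$accuracy,
               retained_fraction = r$retained_fraction)
  })
  do.call(rbind, rows)
}

#' Round half away from zero
#'
#' Rounding convention used when comparing aggregated accuracies against
#' tabulated two-decimal values (base R's `round()` rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Decimal digits.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Aggregate per-model accuracies into group means
#'
#' Averages a table of per-model metric values over a grouping column
#' (backbone, view, or view combination), rounding each mean half-up to
#' two decimals to match conventional table precision.
#'
#' @param df `data.frame` of per-model results.
#' @param by Name of the grouping column.
#' @param value_cols Metric columns to average; defaults to all numeric
#'   columns.
#' @return `data.frame` with one row per group and the rounded group means.
#' @export
aggregate_accuracy_table <- function(df, by, value_cols = NULL) {
  stopifnot(is.data.frame(df), by %in% names(df))
  if (is.null(value_cols))
    value_cols <- names(df)[vapply(df, is.numeric, TRUE)]
  if (!nrow(df)) stop("empty-group: no rows to aggregate", call. = FALSE)
  agg <- aggregate(df[value_cols], by = list(group = df[[by]]), FUN = mean)
  agg[value_cols] <- lapply(agg[value_cols], round_half_up, digits = 2L)
  names(agg)[1] <- by
  agg
}
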