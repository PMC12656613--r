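# Confusion matrices, accuracy / precision / recall / F1 (one-vs-rest with
# macro averaging for the three-grade task), and model comparison tables.

#' Confusion matrix
#'
#' Entry (i, j) counts samples of true class i predicted as class j.
#'
#' @param truth,predicted Equal-length label vectors.
#' @param classes Class order (default the grade levels present).
#' @return K x K integer matrix with dimnames `truth` x `predicted`.
#' @export
confusion_matrix <- function(truth, predicted, classes = NULL) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) != length(predicted))
    stop_plum("plum_label_error", "label vectors must have equal length")
  classes <- classes %||% intersect(PLUM_GRADES, union(truth, predicted))
  if (length(classes) == 0) classes <- sort(union(truth, predicted))
  unknown <- setdiff(union(truth, predicted), classes)
  if (length(unknown))
    stop_plum("plum_label_error", "unknown label(s): %s", paste(unknown, collapse = ", "))
  m <- table(factor(truth, levels = classes), factor(predicted, levels = classes))
  out <- matrix(as.integer(m), nrow = length(classes),
                dimnames = list(truth = classes, predicted = classes))
  out
}

#' Classification metrics from a confusion matrix
#'
#' Per-class one-vs-rest TP/FP/FN/TN and accuracy, precision, recall and F1
#' (harmonic mean of precision and recall); macro metrics are unweighted
#' class means. Ratios with zero denominators are reported as 0 and flagged.
#'
#' @param confusion K x K count matrix (rows = truth).
#' @param model_tag Optional label for reports.
#' @return An `plum_eval_report`: `confusion`, `accuracy`, `per_class` data
#'   frame, `macro_precision`, `macro_recall`, `macro_f1`, `n`,
#'   `undefined_flags`, `model_tag`.
#' @export
classification_metrics <- function(confusion, model_tag = "model") {
  if (is.null(dim(confusion)) || nrow(confusion) != ncol(confusion) ||
      sum(confusion) < 1)
    stop_plum("plum_domain_error", "confusion must be a nonempty square count matrix")
  n <- sum(confusion)
  classes <- rownames(confusion) %||% as.character(seq_len(nrow(confusion)))
  tp <- diag(confusion)
  fp <- colSums(confusion) - tp
  fn <- rowSums(confusion) - tp
  tn <- n - tp - fp - fn
  safe_div <- function(num, den) ifelse(den == 0, 0, num / den)
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  flags <- classes[(tp + fp) == 0 | (tp + fn) == 0 |
                     (precision + recall) == 0]
  structure(list(
    confusion = confusion,
    accuracy = sum(tp) / n,
    per_class = data.frame(class = classes, tp = tp, fp = fp, fn = fn, tn = tn,
                           precision = precision, recall = recall, f1 = f1,
                           row.names = NULL),
    macro_precision = mean(precision),
    macro_recall = mean(recall),
    macro_f1 = mean(f1),
    n = n,
    undefined_flags = flags,
    model_tag = model_tag
  ), class = "plum_eval_report")
}

#' Evaluate predictions against true labels
#'
#' @param truth,predicted Label vectors.
#' @param model_tag Label for the report.
#' @param classes Optional class order.
#' @return An `plum_eval_report`.
#' @export
evaluate_predictions <- function(truth, predicted, model_tag = "model",
                                 classes = NULL) {
  classification_metrics(confusion_matrix(truth, predicted, classes), model_tag)
}

#' @export
print.plum_eval_report <- function(x, ...) {
  cat(sprintf("%s: accuracy %.4f, macro P/R/F1 %.4f/%.4f/%.4f (n = %d)\n",
              x$model_tag, x$accuracy, x$macro_precision, x$macro_recall,
              x$macro_f1, x$n))
  print(x$confusion)
  invisible(x)
}

#' Compare evaluation reports across models
#'
#' Tabulates the headline metrics per model, marks the best model per
#' metric, and lists pairwise accuracy deltas in percentage points.
#'
#' @param reports List of `plum_eval_report`s on the same test set.
#' @return List with `table` (one row per model), `deltas` (pairwise
#'   accuracy differences) and `best` (best model per metric).
#' @export
compare_models <- function(reports) {
  if (length(reports) < 2)
    stop_plum("plum_comparison_error", "need at least two reports to compare")
  ns <- vapply(reports, `[[`, numeric(1), "n")
  if (length(unique(ns)) != 1)
    stop_plum("plum_comparison_error",
              "reports evaluate different test-set sizes: %s",
              paste(ns, collapse = ", "))
  tab <- do.call(rbind, lapply(reports, function(r) {
    data.frame(model = r$model_tag, accuracy = r$accuracy,
               macro_precision = r$macro_precision,
               macro_recall = r$macro_recall, macro_f1 = r$macro_f1)
  }))
  metrics <- c("accuracy", "macro_precision", "macro_recall", "macro_f1")
  best <- vapply(metrics, function(m) tab$model[which.max(tab[[m]])], character(1))
  pairs <- utils::combn(seq_len(nrow(tab)), 2)
  deltas <- data.frame(
    model_a = tab$model[pairs[1, ]], model_b = tab$model[pairs[2, ]],
    accuracy_delta_points = 100 * (tab$accuracy[pairs[1, ]] - tab$accuracy[pairs[2, ]]))
  list(table = tab, deltas = deltas, best = best)
}
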