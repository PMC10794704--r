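#' Confusion matrix
#'
#' `counts[i, j]` is the number of samples with true class `i` predicted as
#' class `j` (0-based labels, 1-based matrix indices).
#'
#' @param y_true,y_pred Integer labels in `0..k-1`.
#' @param k Number of classes.
#' @param class_names Optional class names (row/column labels).
#' @return An object of class `confusion_matrix`: list with `counts`
#'   (K x K integer matrix) and `class_names`.
#' @export
confusion_matrix <- function(y_true, y_pred, k = 4L, class_names = NULL) {
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  stopifnot(length(y_true) == length(y_pred))
  if (any(y_true < 0 | y_true >= k | y_pred < 0 | y_pred >= k))
    stop("labels must lie in [0, k)")
  counts <- matrix(0L, k, k)
  for (i in seq_along(y_true))
    counts[y_true[i] + 1L, y_pred[i] + 1L] <-
      counts[y_true[i] + 1L, y_pred[i] + 1L] + 1L
  if (is.null(class_names)) class_names <- as.character(seq_len(k) - 1L)
  dimnames(counts) <- list(true = class_names, pred = class_names)
  structure(list(counts = counts, class_names = class_names),
            class = "confusion_matrix")
}

cm_counts <- function(cm) {
  if (inherits(cm, "confusion_matrix")) cm$counts else as.matrix(cm)
}

#' Classification metrics from a confusion matrix
#'
#' Per class `c` in one-vs-rest reduction: precision `TP/(TP+FP)`, recall
#' `TP/(TP+FN)`, and F1 as their harmonic mean. Multi-class accuracy is
#' `trace/total`. Aggregates are unweighted macro means. A zero denominator
#' yields 0 with a warning.
#'
#' @param cm A `confusion_matrix` (or bare K x K count matrix).
#' @param average `"macro"` (unweighted mean over classes, the default) or
#'   `"weighted"` (support-weighted mean) for the aggregate
#'   precision/recall/F1.
#' @return An object of class `metric_report`: accuracy, per-class and
#'   aggregate precision/recall/F1, Cohen's kappa, and per-class support.
#' @export
classification_metrics <- function(cm, average = c("macro", "weighted")) {
  average <- match.arg(average)
  m <- cm_counts(cm)
  total <- sum(m)
  if (total == 0) stop("empty confusion matrix")
  k <- nrow(m)
  tp <- diag(m)
  fp <- colSums(m) - tp
  fn <- rowSums(m) - tp
  safe_div <- function(num, den, what) {
    out <- ifelse(den > 0, num / ifelse(den > 0, den, 1), 0)
    if (any(den == 0))
      warning("zero denominator in ", what, " for class(es) ",
              paste(which(den == 0) - 1L, collapse = ", "),
              "; reporting 0")
    out
  }
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  names(precision) <- names(recall) <- names(f1) <- rownames(m)
  w <- if (average == "weighted") rowSums(m) / total else rep(1 / k, k)
  structure(list(
    accuracy = sum(tp) / total,
    precision = precision, recall = recall, f1 = f1,
    macro_precision = sum(w * precision), macro_recall = sum(w * recall),
    macro_f1 = sum(w * f1), average = average,
    kappa = cohen_kappa(m),
    support = rowSums(m)
  ), class = "metric_report")
}

#' Cohen's kappa
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` with
#' observed agreement `p_o = trace/total` and expected agreement
#' `p_e = sum_c row_c * col_c / total^2`.
#'
#' @param cm A `confusion_matrix` or K x K count matrix.
#' @return Kappa in \[-1, 1\].
#' @export
cohen_kappa <- function(cm) {
  m <- cm_counts(cm)
  total <- sum(m)
  if (total == 0) stop("empty confusion matrix")
  po <- sum(diag(m)) / total
  pe <- sum(rowSums(m) * colSums(m)) / total^2
  if (pe >= 1)
    stop("kappa undefined: expected agreement is 1 (degenerate marginals)")
  (po - pe) / (1 - pe)
}

#' Micro-averaged ROC curve and AUC
#'
#' Flattens all `N x K` one-vs-rest (indicator, score) pairs across classes
#' into a single binary problem, sweeps the decision threshold over the
#' unique scores, and reports TPR/FPR at each threshold plus the
#' trapezoidal AUC. Tied scores are grouped, producing the usual diagonal
#' tie segments.
#'
#' @param y_true Integer labels in `0..K-1`.
#' @param probs N x K matrix of class scores (rows need not be normalized).
#' @return An object of class `roc_curve`: `fpr`, `tpr` (monotone, from
#'   (0,0) to (1,1)) and `auc`.
#' @export
micro_roc <- function(y_true, probs) {
  probs <- as.matrix(probs)
  y_true <- as.integer(y_true)
  stopifnot(nrow(probs) == length(y_true))
  k <- ncol(probs)
  truth <- as.vector(vapply(seq_len(k) - 1L, function(cl) y_true == cl,
                            logical(length(y_true))))
  score <- as.vector(probs)
  np <- sum(truth); nn <- sum(!truth)
  if (np == 0 || nn == 0)
    stop("micro ROC undefined: flattened labels are all one class")
  o <- order(score, decreasing = TRUE)
  truth <- truth[o]; score <- score[o]
  tp <- cumsum(truth); fp <- cumsum(!truth)
  keep <- c(score[-1] != score[-length(score)], TRUE)  # last index of each tie
  tpr <- c(0, tp[keep] / np)
  fpr <- c(0, fp[keep] / nn)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  structure(list(fpr = fpr, tpr = tpr, auc = auc), class = "roc_curve")
}

#' Evaluate a model on a labelled image set
#'
#' Predictions are the argmax of the class probabilities (ties broken by
#' the lowest class index). Produces the confusion matrix, the metric
#' report and the micro-averaged ROC.
#'
#' @param model An `nn19_model`.
#' @param images List of preprocessed gray matrices.
#' @param labels Integer labels.
#' @param class_names Class names (default [tumor_classes()]).
#' @return List with `metrics` (`metric_report`), `cm`
#'   (`confusion_matrix`), `roc` (`roc_curve`), `probs` and `preds`.
#' @export
evaluate_model <- function(model, images, labels,
                           class_names = tumor_classes()) {
  probs <- predict_proba(model, images)
  preds <- max.col(probs, ties.method = "first") - 1L
  cm <- confusion_matrix(labels, preds, k = model$config$num_classes,
                         class_names = class_names)
  list(metrics = classification_metrics(cm), cm = cm,
       roc = micro_roc(labels, probs), probs = probs, preds = preds)
}

#' Serialize evaluation artifacts
#'
#' Writes `metrics.json`, `confusion_matrix.csv` (class names as header
#' row/column) and `roc.csv` under `out_dir`.
#'
#' @param evaluation Result of [evaluate_model()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_evaluation <- function(evaluation, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  mr <- evaluation$metrics
  jsonlite::write_json(
    list(accuracy = mr$accuracy, precision = as.list(mr$precision),
         recall = as.list(mr$recall), f1 = as.list(mr$f1),
         macro_precision = mr$macro_precision,
         macro_recall = mr$macro_recall, macro_f1 = mr$macro_f1,
         kappa = mr$kappa, support = as.list(mr$support),
         auc = evaluation$roc$auc),
    file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(evaluation$cm$counts,
                   file.path(out_dir, "confusion_matrix.csv"))
  utils::write.csv(data.frame(fpr = evaluation$roc$fpr,
                              tpr = evaluation$roc$tpr),
                   file.path(out_dir, "roc.csv"), row.names = FALSE)
  invisible(out_dir)
}
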