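# Confusion-matrix metrics (accuracy, sensitivity, specificity in percent)
# and ROC/AUC from continuous discriminant scores.

#' Two-class confusion counts
#'
#' @param labels_true,labels_pred equal-length label vectors over the two
#'   classes of the comparison.
#' @param positive_class the class counted as positive.
#' @return named integer vector `c(tp, fp, tn, fn)`.
#' @export
confusion <- function(labels_true, labels_pred, positive_class) {
  stopifnot(length(labels_true) == length(labels_pred))
  classes <- unique(labels_true)
  if (!positive_class %in% classes)
    stop("positive_class absent from labels_true", call. = FALSE)
  if (length(classes) > 2)
    stop("more than two classes in labels_true", call. = FALSE)
  unknown <- setdiff(unique(labels_pred), classes)
  if (length(unknown))
    stop("unknown predicted label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  pos_t <- labels_true == positive_class
  pos_p <- labels_pred == positive_class
  c(tp = sum(pos_t & pos_p), fp = sum(!pos_t & pos_p),
    tn = sum(!pos_t & !pos_p), fn = sum(pos_t & !pos_p))
}

#' Accuracy, sensitivity and specificity (percent)
#'
#' `accuracy = (tp + tn) / total * 100`,
#' `sensitivity = tp / (tp + fn) * 100`,
#' `specificity = tn / (tn + fp) * 100`.
#' A metric whose denominator is zero is reported as `NA` (undefined), not
#' as 0.
#'
#' @param tp,fp,tn,fn non-negative confusion counts (total > 0).
#' @return list with `accuracy`, `sensitivity`, `specificity`.
#' @export
classification_metrics <- function(tp, fp, tn, fn) {
  total <- tp + fp + tn + fn
  stopifnot(total > 0, tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  list(
    accuracy = (tp + tn) / total * 100,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) * 100 else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) * 100 else NA_real_
  )
}

#' ROC curve and AUC from continuous scores
#'
#' Sweeps the decision threshold over the unique score values (ties grouped
#' into one step), accumulating (false-positive rate, true-positive rate)
#' points from (0, 0) to (1, 1), and integrates by the trapezoidal rule —
#' equivalent to the normalised Mann-Whitney U statistic with the 1/2 tie
#' convention.
#'
#' @param scores numeric; larger means more positive-like.
#' @param labels_true label per score.
#' @param positive_class the class counted as positive.
#' @return list with `roc_points` (data.frame `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(scores, labels_true, positive_class) {
  stopifnot(length(scores) == length(labels_true))
  pos <- labels_true == positive_class
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0)
    stop("both classes must be present to compute a ROC curve", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  # step only where the score value changes (ties grouped)
  last_of_group <- c(s[-1] != s[-length(s)], TRUE)
  tpr <- c(0, cumsum(p)[last_of_group] / n_pos)
  fpr <- c(0, cumsum(!p)[last_of_group] / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(roc_points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Evaluate a classifier's predictions
#'
#' Builds a full evaluation report: confusion counts, percentage metrics
#' and ROC/AUC at spectrum level and — when patient ids are supplied — at
#' patient level, where a patient's label is the majority vote over its
#' replicate spectra (ties go to the positive class) and its score the mean
#' spectrum score.
#'
#' @param labels_true,labels_pred,scores per-spectrum truth, prediction and
#'   continuous score.
#' @param positive_class the class counted as positive.
#' @param patient_ids optional per-spectrum patient ids enabling the
#'   patient-level section.
#' @param dataset_tag `"training"` or `"validation"` (annotation only).
#' @return an object of class `evaluation_report`.
#' @export
evaluate_predictions <- function(labels_true, labels_pred, scores,
                                 positive_class, patient_ids = NULL,
                                 dataset_tag = "validation") {
  cm <- confusion(labels_true, labels_pred, positive_class)
  met <- classification_metrics(cm[["tp"]], cm[["fp"]], cm[["tn"]], cm[["fn"]])
  roc <- if (length(unique(labels_true)) == 2)
    roc_auc(scores, labels_true, positive_class) else NULL
  rep <- list(confusion = cm, accuracy = met$accuracy,
              sensitivity = met$sensitivity, specificity = met$specificity,
              roc_points = roc$roc_points, auc = roc$auc,
              positive_class = positive_class, dataset_tag = dataset_tag)
  if (!is.null(patient_ids)) {
    pats <- unique(patient_ids)
    vote <- function(p) {
      lab <- labels_pred[patient_ids == p]
      n_pos <- sum(lab == positive_class)
      if (n_pos * 2 >= length(lab)) positive_class
      else lab[lab != positive_class][1]
    }
    p_pred <- vapply(pats, vote, character(1))
    p_true <- labels_true[match(pats, patient_ids)]
    p_score <- vapply(pats, function(p) mean(scores[patient_ids == p]),
                      numeric(1))
    cmp <- confusion(p_true, p_pred, positive_class)
    metp <- classification_metrics(cmp[["tp"]], cmp[["fp"]], cmp[["tn"]],
                                   cmp[["fn"]])
    rocp <- if (length(unique(p_true)) == 2)
      roc_auc(p_score, p_true, positive_class) else NULL
    rep$patient_level <- list(confusion = cmp, accuracy = metp$accuracy,
                              sensitivity = metp$sensitivity,
                              specificity = metp$specificity,
                              auc = rocp$auc)
  }
  structure(rep, class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "<evaluation_report> %s (positive = %s): accuracy %.1f%%, sensitivity %.1f%%, specificity %.1f%%",
    x$dataset_tag, x$positive_class, x$accuracy, x$sensitivity,
    x$specificity))
  if (!is.null(x$auc)) cat(sprintf(", AUC %.3f", x$auc))
  cat("\n")
  invisible(x)
}

#' Render evaluation reports as a quality-metrics table
#'
#' Lays out one row per (algorithm, dataset) in the conventional
#' Algorithm / Dataset / Accuracy / Sensitivity / Specificity format.
#'
#' @param reports named list: `reports[[algorithm]][[dataset_tag]]` is an
#'   `evaluation_report`.
#' @param digits rounding applied for presentation (default 0, integers).
#' @return data.frame.
#' @export
metrics_table <- function(reports, digits = 0) {
  rows <- list()
  for (alg in names(reports)) for (tag in names(reports[[alg]])) {
    r <- reports[[alg]][[tag]]
    rows[[length(rows) + 1]] <- data.frame(
      Algorithm = alg, Dataset = tag,
      Accuracy = round(r$accuracy, digits),
      Sensitivity = round(r$sensitivity, digits),
      Specificity = round(r$specificity, digits))
  }
  do.call(rbind, rows)
}
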