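# ---- evaluation: ROC / AUC / per-class diagnostics -----------------------
#
# The minority ("min", lesion-present) class is the positive class throughout.

check_binary_labels <- function(labels) {
  labels <- factor(as.character(labels), levels = c("maj", "min"))
  if (anyNA(labels)) stop("labels must be 'maj' or 'min'")
  if (length(unique(labels)) < 2L)
    stop("both classes must be present in labels")
  labels
}

#' Area under the ROC curve
#'
#' Mann-Whitney concordance form: the probability that a randomly chosen
#' minority sample outscores a randomly chosen majority sample, with ties
#' counting one half. Computed from mid-ranks, so it is exact and O(n log n).
#'
#' @param scores numeric minority-class scores, higher = more minority-like.
#' @param labels true labels (`"maj"`/`"min"`), both classes present.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  labels <- check_binary_labels(labels)
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  pos <- labels == "min"
  n1 <- sum(pos)
  n0 <- sum(!pos)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' Thresholds swept over the unique scores (classify as minority when
#' score >= threshold). The first point is (0, 0) and the last (1, 1); the
#' trapezoidal area over the returned points equals [auc()] exactly.
#'
#' @inheritParams auc
#' @return data frame with columns `threshold`, `fpr`, `tpr`, ordered by
#'   increasing `fpr`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- check_binary_labels(labels)
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  pos <- labels == "min"
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores[pos] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1))
  data.frame(threshold = c(Inf, thr),
             fpr = c(0, fpr),
             tpr = c(0, tpr))
}

trapezoid_area <- function(fpr, tpr) {
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Per-class recall and balanced accuracy
#'
#' @param pred_labels,true_labels vectors of `"maj"`/`"min"` labels.
#' @return list with `recall_maj`, `recall_min`, `balanced_accuracy`, `n`.
#' @export
classification_report <- function(pred_labels, true_labels) {
  stopifnot(length(pred_labels) == length(true_labels),
            length(true_labels) > 0L)
  pred <- factor(as.character(pred_labels), levels = c("maj", "min"))
  true <- factor(as.character(true_labels), levels = c("maj", "min"))
  if (anyNA(pred) || anyNA(true)) stop("labels must be 'maj' or 'min'")
  rec <- function(cls) {
    n <- sum(true == cls)
    if (n == 0L) NA_real_ else sum(pred == cls & true == cls) / n
  }
  r_maj <- rec("maj")
  r_min <- rec("min")
  list(recall_maj = r_maj, recall_min = r_min,
       balanced_accuracy = mean(c(r_maj, r_min), na.rm = TRUE),
       n = length(true))
}

#' Evaluate a trained model on a labelled image set
#'
#' Scores every image with the minority-class probability of the classifier
#' head over the feature generator, then reports AUC, ROC points and
#' per-class recall.
#'
#' @param state a trained `dttl_cda_state` (see [train_cda()]).
#' @param X n x p pixel matrix.
#' @param labels true labels, both classes present.
#' @return list of class `dttl_eval` with `auc`, `roc_points`,
#'   `per_class_recall`, `balanced_accuracy`, `n_eval`.
#' @export
evaluate_model <- function(state, X, labels) {
  labels <- check_binary_labels(labels)
  p <- predict_proba(state, X)
  scores <- p[, 2L]
  pred <- ifelse(p[, 2L] > p[, 1L], "min", "maj")
  rep <- classification_report(pred, labels)
  structure(list(auc = auc(scores, labels),
                 roc_points = roc_curve(scores, labels),
                 per_class_recall = c(maj = rep$recall_maj,
                                      min = rep$recall_min),
                 balanced_accuracy = rep$balanced_accuracy,
                 n_eval = length(labels)),
            class = "dttl_eval")
}

#' @export
print.dttl_eval <- function(x, ...) {
  cat(sprintf("<dttl_eval> n = %d, AUC = %.4f, recall(maj) = %.3f, recall(min) = %.3f\n",
              x$n_eval, x$auc, x$per_class_recall["maj"],
              x$per_class_recall["min"]))
  invisible(x)
}
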