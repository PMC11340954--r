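check_labels_probs <- function(labels, probs) {
  if (length(labels) == 0L) stop("empty input")
  if (length(labels) != length(probs)) stop("labels and probs differ in length")
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    stop("probabilities must lie in [0, 1]")
  invisible(TRUE)
}

#' Threshold-dependent confusion metrics
#'
#' Calls a peptide positive when its probability is at least `threshold`
#' and reports sensitivity, specificity, precision, accuracy and the
#' Matthews correlation coefficient together with the confusion counts.
#' MCC is defined as 0 when any marginal of the confusion table is empty;
#' an undefined precision (no positive calls) is reported as 0 with the
#' flag `pre_undefined`.
#'
#' @param labels 0/1 vector.
#' @param probs Probabilities in `[0, 1]`.
#' @param threshold Decision threshold.
#' @return List with `SEN`, `SPE`, `PRE`, `ACC`, `MCC`, counts `TP`, `FP`,
#'   `TN`, `FN`, `threshold` and `pre_undefined`.
#' @export
confusion_metrics <- function(labels, probs, threshold = 0.5) {
  check_labels_probs(labels, probs)
  pred <- as.integer(probs >= threshold)
  TP <- sum(pred == 1L & labels == 1L)
  FP <- sum(pred == 1L & labels == 0L)
  TN <- sum(pred == 0L & labels == 0L)
  FN <- sum(pred == 0L & labels == 1L)
  den <- as.numeric(TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  mcc <- if (den == 0) 0 else (as.numeric(TP) * TN - as.numeric(FP) * FN) / sqrt(den)
  pre_undef <- (TP + FP) == 0L
  list(
    SEN = if (TP + FN > 0L) TP / (TP + FN) else 0,
    SPE = if (TN + FP > 0L) TN / (TN + FP) else 0,
    PRE = if (pre_undef) 0 else TP / (TP + FP),
    ACC = (TP + TN) / length(labels),
    MCC = mcc,
    TP = TP, FP = FP, TN = TN, FN = FN,
    threshold = threshold, pre_undefined = pre_undef
  )
}

#' Area under the ROC curve
#'
#' Computed from the rank statistic (equivalent to the Mann-Whitney U):
#' tied probabilities contribute one half.
#'
#' @param labels 0/1 vector containing both classes.
#' @param probs Probabilities (any monotone score works).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(labels, probs) {
  check_labels_probs(labels, probs)
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) stop("both classes required for AUC")
  r <- rank(probs)
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve
#'
#' Step integration over descending score thresholds (average-precision
#' form): each increment of recall contributes the precision at that
#' threshold. Tied scores are grouped.
#'
#' @inheritParams roc_auc
#' @return AUPRC in `[0, 1]`.
#' @export
pr_auc <- function(labels, probs) {
  check_labels_probs(labels, probs)
  n_pos <- sum(labels == 1L)
  if (n_pos == 0L || sum(labels == 0L) == 0L) stop("both classes required for AUPRC")
  ord <- order(probs, decreasing = TRUE)
  lab <- labels[ord]; pr <- probs[ord]
  grp_end <- cumsum(rle(pr)$lengths)  # last index of each tied score group
  tp <- cumsum(lab)[grp_end]
  np <- grp_end
  precision <- tp / np
  recall <- tp / n_pos
  sum(diff(c(0, recall)) * precision)
}

#' MCC-maximizing decision threshold
#'
#' Scans every distinct probability value (plus 0 and 1) as a candidate
#' threshold and returns the smallest candidate maximizing the Matthews
#' correlation coefficient.
#'
#' @inheritParams roc_auc
#' @return The optimal threshold.
#' @export
mcc_optimal_threshold <- function(labels, probs) {
  check_labels_probs(labels, probs)
  if (sum(labels == 1L) == 0L || sum(labels == 0L) == 0L)
    stop("both classes required to tune a threshold")
  cand <- sort(unique(c(0, probs, 1)))
  mccs <- vapply(cand, function(th) confusion_metrics(labels, probs, th)$MCC, 0)
  cand[which.max(mccs)]  # which.max takes the first (smallest) maximizer
}

#' Full evaluation report at an MCC-optimal or given threshold
#'
#' @inheritParams roc_auc
#' @param threshold Decision threshold; if `NULL` (default), the
#'   MCC-maximizing threshold is derived from these labels/probabilities.
#' @return A `metrics_report` list: SEN, SPE, PRE, ACC, MCC, AUC, AUPRC,
#'   threshold and confusion counts.
#' @export
evaluate_probs <- function(labels, probs, threshold = NULL) {
  if (is.null(threshold)) threshold <- mcc_optimal_threshold(labels, probs)
  rep <- confusion_metrics(labels, probs, threshold)
  rep$AUC <- roc_auc(labels, probs)
  rep$AUPRC <- pr_auc(labels, probs)
  class(rep) <- "metrics_report"
  rep
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("SEN %.3f  SPE %.3f  PRE %.3f  ACC %.3f  MCC %.3f  AUC %.3f  AUPRC %.3f (threshold %.4f)\n",
              x$SEN, x$SPE, x$PRE, x$ACC, x$MCC, x$AUC, x$AUPRC, x$threshold))
  invisible(x)
}
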