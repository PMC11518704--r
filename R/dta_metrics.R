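# Threshold-free and thresholded evaluation of binary interaction scores.

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) computation; tied scores contribute 1/2.
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 labels; both classes must be present.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  np <- sum(labels == 1); nn <- sum(labels == 0)
  if (np == 0 || nn == 0) stop("AUROC undefined: test set has a single class")
  r <- rank(scores)
  (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' Area under the precision-recall curve
#'
#' Average precision: the precision-recall curve is evaluated at every
#' distinct score threshold (descending) and integrated as
#' `sum((R_k - R_{k-1}) * P_k)`, the step-wise integral that does not
#' interpolate between operating points. A random scorer converges to the
#' positive-class prevalence.
#'
#' @inheritParams auroc
#' @return AUPRC in \[0, 1\].
#' @export
auprc <- function(scores, labels) {
  labels <- as.integer(labels)
  np <- sum(labels == 1)
  if (np == 0 || sum(labels == 0) == 0) {
    stop("AUPRC undefined: test set has a single class")
  }
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  keep <- !duplicated(s, fromLast = TRUE)  # last index of each tied block
  tp <- tp[keep]; fp <- fp[keep]
  recall <- tp / np
  precision <- tp / (tp + fp)
  sum(diff(c(0, recall)) * precision)
}

#' Thresholded metrics at the F1-optimal operating point
#'
#' Scans every distinct score as a candidate threshold (predict positive at
#' `score >= threshold`), selects the threshold maximising F1 (ties broken
#' toward the higher threshold), and reports sensitivity, specificity and
#' accuracy there.
#'
#' @inheritParams auroc
#' @return List: `f1`, `sensitivity`, `specificity`, `accuracy`,
#'   `threshold`.
#' @export
f1_point <- function(scores, labels) {
  labels <- as.integer(labels)
  np <- sum(labels == 1); nn <- sum(labels == 0)
  if (np == 0 || nn == 0) stop("F1 point undefined: single-class labels")
  thr <- sort(unique(scores), decreasing = TRUE)
  best <- list(f1 = -1, threshold = NA_real_)
  for (t in thr) {
    pred <- as.integer(scores >= t)
    tp <- sum(pred == 1 & labels == 1)
    fp <- sum(pred == 1 & labels == 0)
    fn <- np - tp
    f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    if (f1 > best$f1) {
      tn <- nn - fp
      best <- list(f1 = f1, sensitivity = tp / np, specificity = tn / nn,
                   accuracy = (tp + tn) / (np + nn), threshold = t)
    }
  }
  best
}

#' Evaluate a trained model on labelled records
#'
#' @param model A `dta_model`.
#' @param records Data frame with `smiles`, `sequence`, `label`.
#' @return List with `auroc`, `auprc`, `f1`, `sensitivity`, `specificity`,
#'   `accuracy`, `threshold` and the score vector.
#' @export
evaluate_dta <- function(model, records) {
  scores <- predict_dta(model, records)
  labels <- records$label
  pt <- f1_point(scores, labels)
  c(list(auroc = auroc(scores, labels), auprc = auprc(scores, labels)),
    pt, list(scores = scores))
}
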