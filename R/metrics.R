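#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUROC with midrank tie handling.
#'
#' @param scores numeric predictions (higher = more likely positive).
#' @param labels logical (or 0/1) ground-truth positives.
#' @return AUROC in [0, 1].
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  npos <- sum(labels); nneg <- sum(!labels)
  if (npos == 0 || nneg == 0)
    stop("degenerate labeling: need both positive and negative examples")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Area under the precision-recall curve
#'
#' Average-precision form: descending unique score thresholds, with
#' `AUPRC = sum_k (R_k - R_{k-1}) P_k`. Tied scores enter as one threshold,
#' so a constant predictor scores exactly the positive prevalence.
#'
#' @inheritParams auroc
#' @return AUPRC in (0, 1].
#' @export
auprc <- function(scores, labels) {
  labels <- as.logical(labels)
  npos <- sum(labels); nneg <- sum(!labels)
  if (npos == 0 || nneg == 0)
    stop("degenerate labeling: need both positive and negative examples")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  tp <- cumsum(y); fp <- cumsum(!y)
  keep <- c(s[-1] != s[-length(s)], TRUE)  # last index of each tie group
  tp <- tp[keep]; fp <- fp[keep]
  prec <- tp / (tp + fp)
  rec <- tp / npos
  sum(diff(c(0, rec)) * prec)
}
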