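#' Normalize a matrix to the [-1, 1] range
#'
#' Element-wise division by the maximum absolute entry; sign pattern is
#' preserved.
#'
#' @param M numeric matrix with at least one nonzero entry.
#' @return The normalized matrix.
#' @export
normalize_matrix <- function(M) {
  M <- unclass(as.matrix(M))
  mx <- max(abs(M))
  if (mx == 0) stop("degenerate: all-zero matrix cannot be normalized")
  M / mx
}

#' Total absolute difference between normalized matrices
#'
#' Both matrices are first normalized to [-1, 1] (see [normalize_matrix()]);
#' the statistic is the element-wise sum `sum |J_true - J_inf|`.
#'
#' @param J_true,J_inf matrices of identical shape.
#' @return Non-negative scalar; 0 iff the normalized matrices are equal.
#' @export
abs_difference <- function(J_true, J_inf) {
  J_true <- unclass(as.matrix(J_true)); J_inf <- unclass(as.matrix(J_inf))
  if (!all(dim(J_true) == dim(J_inf)))
    stop("shape mismatch between J_true and J_inf")
  sum(abs(normalize_matrix(J_true) - normalize_matrix(J_inf)))
}

#' Fraction of correctly signed entries
#'
#' Over the entries where the normalized ground truth exceeds `zero_tol` in
#' magnitude, the fraction whose sign matches in the inferred matrix
#' (entries of `J_inf` that are exactly zero never match).
#'
#' @param J_true,J_inf matrices of identical shape.
#' @param zero_tol magnitude threshold on the normalized truth below which
#'   entries are ignored (default 1e-10).
#' @return Fraction in [0, 1].
#' @export
sign_agreement <- function(J_true, J_inf, zero_tol = 1e-10) {
  J_true <- unclass(as.matrix(J_true)); J_inf <- unclass(as.matrix(J_inf))
  if (!all(dim(J_true) == dim(J_inf)))
    stop("shape mismatch between J_true and J_inf")
  Tn <- normalize_matrix(J_true)
  keep <- abs(Tn) > zero_tol
  if (!any(keep))
    stop("undefined metric: no ground-truth entries above zero_tol")
  mean(sign(Tn[keep]) == sign(J_inf[keep]))
}

#' Edge-recovery AUROC/AUPRC against a ground-truth topology
#'
#' Positives are the nonzero off-diagonal entries of the (binary or ternary)
#' truth; scores are the absolute inferred weights. `auprc_ratio` divides
#' the AUPRC by `baseline` (default: the positive prevalence, i.e. the
#' random-classifier AUPRC).
#'
#' @param J_true ground-truth topology matrix (entries in `{-1, 0, 1}` or
#'   any weights whose nonzero pattern defines the positives). Only the
#'   interaction (off-diagonal) pattern is used.
#' @param J_inf inferred matrix of the same shape.
#' @param baseline denominator for `auprc_ratio` (default prevalence).
#' @return List with `auroc`, `auprc`, `auprc_ratio`.
#' @export
grn_recovery_auprc <- function(J_true, J_inf, baseline = NULL) {
  J_true <- unclass(as.matrix(J_true)); J_inf <- unclass(as.matrix(J_inf))
  if (!all(dim(J_true) == dim(J_inf)))
    stop("shape mismatch between J_true and J_inf")
  off <- row(J_true) != col(J_true)
  labels <- J_true[off] != 0
  scores <- abs(J_inf)[off]
  if (all(labels) || !any(labels))
    stop("degenerate labeling: truth topology has no negatives or no positives")
  if (is.null(baseline)) baseline <- mean(labels)
  pr <- auprc(scores, labels)
  list(auroc = auroc(scores, labels), auprc = pr,
       auprc_ratio = pr / baseline)
}

#' Full comparison report between ground-truth and inferred matrices
#'
#' @param J_true,J_inf matrices of identical shape (typically the analytic
#'   and inferred interaction matrices or Jacobians).
#' @param zero_tol passed to [sign_agreement()].
#' @return A `comparison_report` list: `absolute_difference`,
#'   `sign_fraction_correct`, `auroc`, `auprc`, `auprc_ratio`.
#' @export
comparison_report <- function(J_true, J_inf, zero_tol = 1e-10) {
  rec <- grn_recovery_auprc(J_true, J_inf)
  structure(list(absolute_difference = abs_difference(J_true, J_inf),
                 sign_fraction_correct = sign_agreement(J_true, J_inf,
                                                        zero_tol),
                 auroc = rec$auroc, auprc = rec$auprc,
                 auprc_ratio = rec$auprc_ratio),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("comparison_report:\n")
  cat(sprintf("  absolute difference     %.4f\n", x$absolute_difference))
  cat(sprintf("  sign fraction correct   %.4f\n", x$sign_fraction_correct))
  cat(sprintf("  AUROC / AUPRC / ratio   %.4f / %.4f / %.4f\n",
              x$auroc, x$auprc, x$auprc_ratio))
  invisible(x)
}
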