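#' Sorted eigen-decomposition of a splicing Jacobian
#'
#' Eigenvalues are ordered by descending real part (ties: descending
#' imaginary part, then original index); eigenvectors are scaled to unit
#' L2 norm.
#'
#' @param J a `splicing_jacobian` or any square numeric matrix.
#' @return An `eigen_decomposition`: list with complex `values` (length 2N),
#'   `vectors` (2N x 2N, columns matching `values`) and `gene_names`.
#' @export
eigen_decompose <- function(J) {
  if (!all(is.finite(as.numeric(J)))) stop("J contains non-finite entries")
  e <- eigen(unclass(J))
  ord <- order(-Re(e$values), -Im(e$values), seq_along(e$values))
  vals <- e$values[ord]
  vecs <- e$vectors[, ord, drop = FALSE]
  nrm <- sqrt(colSums(Mod(vecs)^2))
  vecs <- sweep(vecs, 2, nrm, "/")
  gn <- attr(J, "gene_names")
  if (is.null(gn)) gn <- paste0("gene", seq_len(nrow(J) / 2))
  structure(list(values = vals, vectors = vecs, gene_names = gn),
            class = "eigen_decomposition")
}

#' @export
print.eigen_decomposition <- function(x, ...) {
  cat("eigen_decomposition:", length(x$values), "eigenvalues, leading Re =",
      format(Re(x$values[1]), digits = 4), "\n")
  invisible(x)
}

#' Classify the local stability of a state
#'
#' @param decomp an [eigen_decompose()] result.
#' @param tol tolerance on the leading real part; default
#'   `1e-6 * max(|eigenvalues|)` (relative to the spectral radius).
#' @return `"unstable"` if `Re(lambda_1) > tol`, `"marginal"` if
#'   `|Re(lambda_1)| <= tol`, else `"stable"`.
#' @export
stability_report <- function(decomp, tol = NULL) {
  if (is.null(tol)) tol <- 1e-6 * max(Mod(decomp$values))
  lead <- Re(decomp$values[1])
  if (lead > tol) "unstable" else if (abs(lead) <= tol) "marginal" else "stable"
}

#' Displacement vector between two state centroids
#'
#' `dx = centroid(end) - centroid(start)` in concatenated
#' (unspliced, spliced) coordinates, assuming the two states are connected
#' by a straight path in gene space.
#'
#' @param ds a `splice_dataset`.
#' @param start,end state labels.
#' @return Numeric vector of length 2N.
#' @export
transition_displacement <- function(ds, start, end) {
  state_centroid(ds, end) - state_centroid(ds, start)
}

#' Per-gene instability scores for a state transition
#'
#' Projects the displacement `dx` (normalized to unit length) onto the
#' `n_top` leading eigenvectors of the start state's Jacobian, giving
#' projection coefficients `k_m = <dx, v_m>`. The raw score of gene j sums
#' the squared loadings of its unspliced and spliced coordinates weighted by
#' `|k_m|^2`:
#' \deqn{raw_j = \sum_{m=1}^{n} |k_m|^2 (|v_{m,j}|^2 + |v_{m,j+N}|^2)}
#' Scores are reported as `IS_j = raw_j / max_j raw_j`, bounded in [0, 1].
#' Complex conjugate pairs are handled through squared moduli, so scores are
#' always real.
#'
#' @param decomp [eigen_decompose()] of the start state's Jacobian.
#' @param dx displacement vector of length 2N (any overall scale;
#'   see [transition_displacement()]).
#' @param n_top number of leading eigenvectors to use (default 10, clipped
#'   to 2N).
#' @param start,end optional state labels recorded in the result.
#' @return A `transition_analysis`: list with `start`, `end`, `dx`,
#'   `n_top`, `k` (projection coefficients), `raw`, and `IS` (named per-gene
#'   scores). If `dx` is orthogonal to all selected eigenvectors the scores
#'   are all zero and a warning is raised.
#' @export
instability_scores <- function(decomp, dx, n_top = 10,
                               start = NULL, end = NULL) {
  n2 <- length(decomp$values)
  N <- n2 / 2
  if (length(dx) != n2)
    stop("dx must have length ", n2)
  nd <- sqrt(sum(dx^2))
  if (nd == 0) stop("degenerate transition: zero displacement vector")
  dxu <- dx / nd
  n_top <- min(as.integer(n_top), n2)
  if (n_top < 1) stop("n_top must be >= 1")
  V <- decomp$vectors[, seq_len(n_top), drop = FALSE]
  k <- as.vector(crossprod(Conj(V), dxu))         # k_m = <dx, v_m>
  w <- Mod(k)^2
  load <- Mod(V[seq_len(N), , drop = FALSE])^2 +
          Mod(V[N + seq_len(N), , drop = FALSE])^2
  raw <- as.vector(load %*% w)
  names(raw) <- decomp$gene_names
  if (max(raw) <= 1e-24) {  # |k_m| ~ 1e-12 on a unit dx: numerically zero
    warning("displacement is orthogonal to all selected eigenvectors; ",
            "all instability scores are zero")
    IS <- raw
  } else {
    IS <- raw / max(raw)
  }
  structure(list(start = start, end = end, dx = dx, n_top = n_top,
                 k = k, raw = raw, IS = IS),
            class = "transition_analysis")
}

#' @export
print.transition_analysis <- function(x, ...) {
  cat("transition_analysis",
      if (!is.null(x$start)) paste0(x$start, " -> ", x$end) else "",
      ": ", length(x$IS), " genes, n_top = ", x$n_top, "\n", sep = "")
  top <- utils::head(sort(x$IS, decreasing = TRUE), 5)
  cat("  top genes:", paste0(names(top), " (", format(top, digits = 2), ")",
                             collapse = ", "), "\n")
  invisible(x)
}

#' Run the full transition analysis for one start -> end pair
#'
#' Convenience wrapper: assembles the start state's Jacobian from a fitted
#' model, decomposes it, forms the displacement from the dataset centroids
#' and computes instability scores.
#'
#' @param fit a [splice_fit()] containing a model for `start`.
#' @param ds the `splice_dataset` (for the centroids).
#' @param start,end state labels; must differ.
#' @param n_top leading eigenvectors to project on (default 10).
#' @return A `transition_analysis` (see [instability_scores()]).
#' @export
transition_analysis <- function(fit, ds, start, end, n_top = 10) {
  if (identical(start, end))
    stop("degenerate transition: start and end states are identical")
  decomp <- eigen_decompose(assemble_jacobian(fit, start))
  dx <- transition_displacement(ds, start, end)
  instability_scores(decomp, dx, n_top = n_top, start = start, end = end)
}

#' Rank genes of a transition by instability score
#'
#' @param ta a `transition_analysis`.
#' @param top_k number of genes to keep (default: all).
#' @return A data.frame with columns `gene`, `raw`, `IS`, `rank`, sorted by
#'   descending score; ties broken alphabetically by gene name.
#' @export
rank_transition_genes <- function(ta, top_k = length(ta$IS)) {
  ord <- order(-ta$IS, names(ta$IS))
  ord <- ord[seq_len(min(top_k, length(ord)))]
  data.frame(gene = names(ta$IS)[ord],
             raw = unname(ta$raw[ord]),
             IS = unname(ta$IS[ord]),
             rank = seq_along(ord),
             stringsAsFactors = FALSE)
}

#' Partition transition genes across branches sharing a start state
#'
#' Takes several transition analyses starting from the same state, extracts
#' each branch's top `top_k` genes, and partitions their union by the exact
#' set of branches a gene appears in.
#'
#' @param analyses named list of `transition_analysis` objects with a common
#'   `start`; names (or `end` labels) identify the branches.
#' @param top_k genes per branch (default 10).
#' @return List with `top` (per-branch top gene vectors) and `partition`
#'   (named list: one element per observed branch combination, names built
#'   by joining branch names with `+`).
#' @export
compare_branches <- function(analyses, top_k = 10) {
  if (length(analyses) < 2) stop("need >= 2 transition analyses")
  starts <- unique(lapply(analyses, function(a) a$start))
  if (length(starts) != 1)
    stop("analyses do not share a start state")
  nm <- names(analyses)
  if (is.null(nm)) nm <- vapply(analyses, function(a) a$end %||% "", "")
  if (any(nm == "")) nm <- paste0("branch", seq_along(analyses))
  tops <- lapply(analyses, function(a)
    rank_transition_genes(a, top_k = top_k)$gene)
  names(tops) <- nm
  genes <- sort(unique(unlist(tops)))
  member <- vapply(tops, function(tg) genes %in% tg,
                   logical(length(genes)))
  member <- matrix(member, nrow = length(genes),
                   dimnames = list(genes, nm))
  key <- apply(member, 1, function(r) paste(nm[r], collapse = "+"))
  list(top = tops, partition = split(genes, key))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
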