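#' Paired unspliced/spliced count dataset with cell-state annotations
#'
#' Bundles an unspliced and a spliced count matrix (cells x genes) together
#' with gene names, cell identifiers and a per-cell state label. This is the
#' input container for [splice_fit()] and all downstream analyses.
#'
#' @param U numeric matrix of unspliced counts, cells x genes. May be a dense
#'   matrix or a sparse `Matrix` object; sparse input is kept sparse and
#'   densified per state at fit time.
#' @param S numeric matrix of spliced counts, same dimensions as `U`.
#' @param states character or factor of length `nrow(U)` assigning each cell
#'   to a state (cluster).
#' @param gene_names optional character vector of gene identifiers; defaults
#'   to `colnames(S)` (or `gene1..geneN`).
#' @param cell_ids optional character vector of cell identifiers; defaults to
#'   `rownames(S)` (or `cell1..cellC`).
#'
#' @return An object of class `splice_dataset`: a list with elements `U`,
#'   `S`, `gene_names`, `cell_ids` and `states` (a factor).
#'
#' @details Both matrices must be finite and non-negative, gene names must be
#'   unique, and every state must contain at least two cells. Counts are used
#'   as provided: no normalization, log-transform or smoothing is applied
#'   (see [splice_fit()] for the optional library-size flag).
#'
#' @examples
#' U <- matrix(rpois(60, 4), 20, 3)
#' S <- matrix(rpois(60, 8), 20, 3)
#' ds <- splice_dataset(U, S, states = rep(c("A", "B"), each = 10))
#' ds
#' @export
splice_dataset <- function(U, S, states, gene_names = NULL, cell_ids = NULL) {
  if (is.null(dim(U)) || is.null(dim(S)))
    stop("U and S must be matrices (cells x genes)")
  if (!all(dim(U) == dim(S)))
    stop("shape mismatch: U is ", nrow(U), "x", ncol(U),
         " but S is ", nrow(S), "x", ncol(S))
  if (length(states) != nrow(U))
    stop("length(states) [", length(states), "] != number of cells [", nrow(U), "]")
  .check_counts(U, "U")
  .check_counts(S, "S")

  if (is.null(gene_names)) gene_names <- colnames(S)
  if (is.null(gene_names)) gene_names <- paste0("gene", seq_len(ncol(S)))
  if (anyDuplicated(gene_names))
    stop("duplicated gene names: ",
         paste(unique(gene_names[duplicated(gene_names)]), collapse = ", "))
  if (length(gene_names) != ncol(S))
    stop("gene_names has length ", length(gene_names), ", expected ", ncol(S))

  if (is.null(cell_ids)) cell_ids <- rownames(S)
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(nrow(S)))
  if (anyDuplicated(cell_ids)) stop("duplicated cell ids")

  states <- factor(as.character(states))
  tab <- table(states)
  if (any(tab < 2))
    stop("each state needs >= 2 cells; offending: ",
         paste(names(tab)[tab < 2], collapse = ", "))

  dimnames(U) <- dimnames(S) <- list(cell_ids, gene_names)
  structure(list(U = U, S = S, gene_names = gene_names,
                 cell_ids = cell_ids, states = states),
            class = "splice_dataset")
}

.check_counts <- function(M, nm) {
  v <- if (inherits(M, "sparseMatrix")) M@x else M
  if (length(v) && (any(!is.finite(v)) || any(v < 0)))
    stop(nm, " must contain finite, non-negative values")
  invisible(TRUE)
}

#' @export
print.splice_dataset <- function(x, ...) {
  tab <- table(x$states)
  cat("splice_dataset: ", length(x$cell_ids), " cells x ", length(x$gene_names),
      " genes, ", nlevels(x$states), " states\n", sep = "")
  cat("  states:", paste0(names(tab), " (", tab, ")", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.splice_dataset <- function(x) c(length(x$cell_ids), length(x$gene_names))

#' Subset a splice_dataset by cells and/or genes
#'
#' Row (cell) and column (gene) subsetting applied identically to both count
#' layers, preserving the unspliced/spliced pairing.
#'
#' @param x a `splice_dataset`.
#' @param i cell index (integer, logical or cell id).
#' @param j gene index (integer, logical or gene name).
#' @param ... ignored.
#' @return A `splice_dataset`. Subsets with fewer than 2 cells per remaining
#'   state are rejected by the constructor.
#' @export
`[.splice_dataset` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_along(x$cell_ids)
  if (missing(j)) j <- seq_along(x$gene_names)
  if (is.character(j)) {
    jj <- match(j, x$gene_names)
    if (anyNA(jj))
      stop("unknown gene(s): ", paste(j[is.na(jj)], collapse = ", "))
    j <- jj
  }
  if (is.character(i)) {
    ii <- match(i, x$cell_ids)
    if (anyNA(ii)) stop("unknown cell id(s)")
    i <- ii
  }
  splice_dataset(x$U[i, j, drop = FALSE], x$S[i, j, drop = FALSE],
                 states = x$states[i],
                 gene_names = x$gene_names[j], cell_ids = x$cell_ids[i])
}

#' Restrict a dataset to the cells of one state
#'
#' @param ds a `splice_dataset`.
#' @param state a state label present in `levels(ds$states)`.
#' @return A `splice_dataset` holding only that state's cells.
#' @export
subset_state <- function(ds, state) {
  .check_state(ds, state)
  ds[ds$states == state, ]
}

.check_state <- function(ds, state) {
  bad <- setdiff(state, levels(ds$states))
  if (length(bad))
    stop("unknown state(s): ", paste(bad, collapse = ", "),
         "; available: ", paste(levels(ds$states), collapse = ", "))
  invisible(TRUE)
}

#' Gene selection by expression or explicit list
#'
#' `mode = "top_expressed"` ranks genes by mean spliced expression over all
#' cells (descending, ties broken by input order) and keeps the top `n`;
#' `mode = "user_list"` keeps the named genes in the requested order.
#'
#' @param ds a `splice_dataset`.
#' @param mode `"top_expressed"` or `"user_list"`.
#' @param n_or_list integer `n` for `top_expressed`; character vector of gene
#'   names for `user_list`.
#' @return The gene-subsetted `splice_dataset`.
#' @export
select_genes <- function(ds, mode = c("top_expressed", "user_list"), n_or_list) {
  mode <- match.arg(mode)
  if (mode == "top_expressed") {
    n <- as.integer(n_or_list)
    if (n < 1 || n > length(ds$gene_names))
      stop("n must be in [1, ", length(ds$gene_names), "]")
    mu <- Matrix::colMeans(ds$S)
    ord <- order(mu, decreasing = TRUE)  # stable sort: ties keep input order
    ds[, ord[seq_len(n)]]
  } else {
    genes <- as.character(n_or_list)
    missing <- setdiff(genes, ds$gene_names)
    if (length(missing))
      stop("unknown gene(s): ", paste(missing, collapse = ", "))
    ds[, genes]
  }
}

#' Maximum number of genes supported by the smallest state
#'
#' The per-gene regression needs at least as many cells as genes; with
#' bootstrap subsampling at fraction `frac`, the smallest state's effective
#' cell count bounds the gene set. Returns `floor(frac * n_min)` where
#' `n_min` is the size of the smallest state.
#'
#' @param ds a `splice_dataset`.
#' @param frac bootstrap subsample fraction in (0, 1].
#' @return Integer gene-count ceiling.
#' @examples
#' # 70-cell smallest state at frac = 0.9 allows at most 63 genes
#' @export
max_genes_checkpoint <- function(ds, frac = 0.9) {
  if (!is.numeric(frac) || frac <= 0 || frac > 1)
    stop("frac must be in (0, 1]")
  tab <- table(ds$states)
  if (any(tab == 0)) stop("empty state: ", names(tab)[tab == 0][1])
  as.integer(floor(frac * min(tab)))
}

#' Centroid of a state in concatenated (unspliced, spliced) coordinates
#'
#' @param ds a `splice_dataset`.
#' @param state state label.
#' @return Numeric vector of length `2 * N`: per-gene mean unspliced counts
#'   followed by per-gene mean spliced counts over the state's cells, in
#'   dataset gene order.
#' @export
state_centroid <- function(ds, state) {
  .check_state(ds, state)
  idx <- ds$states == state
  ctr <- c(Matrix::colMeans(ds$U[idx, , drop = FALSE]),
           Matrix::colMeans(ds$S[idx, , drop = FALSE]))
  names(ctr) <- c(paste0(ds$gene_names, "_u"), paste0(ds$gene_names, "_s"))
  ctr
}
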