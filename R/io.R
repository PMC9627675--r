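#' Read a paired-count dataset from disk
#'
#' Supported on-disk layouts, both under a single directory:
#' \describe{
#'   \item{`csv`}{`unspliced.csv` and `spliced.csv` (numeric tables with a
#'     header row and row names) plus `cell_labels.csv` with columns
#'     `cell_id` and the cluster key. Matrices may be stored cell x gene or
#'     gene x cell; orientation is auto-detected by matching the label count
#'     and can be forced with `orientation`.}
#'   \item{`mtx`}{`unspliced.mtx` and `spliced.mtx` (MatrixMarket, cells in
#'     rows), `genes.tsv` (one gene id per line) and `cells.tsv`
#'     (tab-separated `cell_id`, cluster key columns with a header).}
#' }
#'
#' @param path directory holding the files above.
#' @param format `"csv"` or `"mtx"`.
#' @param cluster_key name of the label column (default `"clusters"`).
#' @param orientation `"auto"`, `"cells_x_genes"` or `"genes_x_cells"`
#'   (csv only).
#' @return A [splice_dataset()].
#' @seealso [write_splice_dataset()], [as_splice_dataset()]
#' @export
read_splice_dataset <- function(path, format = c("csv", "mtx"),
                                cluster_key = "clusters",
                                orientation = c("auto", "cells_x_genes",
                                                "genes_x_cells")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!dir.exists(path)) stop("no such directory: ", path)
  if (format == "csv") {
    .read_csv_triplet(path, cluster_key, orientation)
  } else {
    .read_mtx_triplet(path, cluster_key)
  }
}

.require_file <- function(path, file) {
  fp <- file.path(path, file)
  if (!file.exists(fp)) stop("missing file '", file, "' in ", path)
  fp
}

.read_csv_triplet <- function(path, cluster_key, orientation) {
  fu <- .require_file(path, "unspliced.csv")
  fs <- .require_file(path, "spliced.csv")
  fl <- .require_file(path, "cell_labels.csv")
  lab <- utils::read.csv(fl, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"cell_id" %in% names(lab))
    stop("cell_labels.csv lacks a 'cell_id' column")
  if (!cluster_key %in% names(lab))
    stop("cell_labels.csv lacks the label column '", cluster_key, "'")
  U <- as.matrix(utils::read.csv(fu, row.names = 1, check.names = FALSE))
  S <- as.matrix(utils::read.csv(fs, row.names = 1, check.names = FALSE))
  ncells <- nrow(lab)
  flip <- switch(orientation,
    cells_x_genes = FALSE,
    genes_x_cells = TRUE,
    auto = if (nrow(U) == ncells) FALSE else if (ncol(U) == ncells) TRUE else
      stop("cannot orient matrices: neither dimension matches the ",
           ncells, " labelled cells"))
  if (flip) { U <- t(U); S <- t(S) }
  if (nrow(U) != ncells)
    stop("matrix has ", nrow(U), " cells but ", ncells, " labels")
  ord <- match(lab$cell_id, rownames(U))
  if (anyNA(ord)) stop("cell ids in labels and matrices disagree")
  splice_dataset(U[ord, , drop = FALSE], S[ord, , drop = FALSE],
                 states = lab[[cluster_key]],
                 gene_names = colnames(S), cell_ids = lab$cell_id)
}

.read_mtx_triplet <- function(path, cluster_key) {
  fu <- .require_file(path, "unspliced.mtx")
  fs <- .require_file(path, "spliced.mtx")
  fg <- .require_file(path, "genes.tsv")
  fc <- .require_file(path, "cells.tsv")
  genes <- readLines(fg)
  cells <- utils::read.delim(fc, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"cell_id" %in% names(cells))
    stop("cells.tsv lacks a 'cell_id' column")
  if (!cluster_key %in% names(cells))
    stop("cells.tsv lacks the label column '", cluster_key, "'")
  U <- methods::as(Matrix::readMM(fu), "CsparseMatrix")
  S <- methods::as(Matrix::readMM(fs), "CsparseMatrix")
  splice_dataset(U, S, states = cells[[cluster_key]],
                 gene_names = genes, cell_ids = cells$cell_id)
}

#' Write a dataset as a CSV triplet
#'
#' Inverse of [read_splice_dataset()] with `format = "csv"`: writes
#' `unspliced.csv`, `spliced.csv` (cells x genes) and `cell_labels.csv`.
#'
#' @param ds a `splice_dataset`.
#' @param path output directory (created if absent).
#' @param cluster_key label column name used in `cell_labels.csv`.
#' @return `path`, invisibly.
#' @export
write_splice_dataset <- function(ds, path, cluster_key = "clusters") {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.matrix(ds$U), file.path(path, "unspliced.csv"))
  utils::write.csv(as.matrix(ds$S), file.path(path, "spliced.csv"))
  lab <- data.frame(cell_id = ds$cell_ids, stringsAsFactors = FALSE)
  lab[[cluster_key]] <- as.character(ds$states)
  utils::write.csv(lab, file.path(path, "cell_labels.csv"), row.names = FALSE)
  invisible(path)
}

#' Build a splice_dataset from a SingleCellExperiment
#'
#' Expects assays named `"unspliced"` and `"spliced"` (gene x cell, the
#' Bioconductor convention; transposed internally) and a `colData` column
#' with the state labels.
#'
#' @param x a `SingleCellExperiment`.
#' @param cluster_key name of the `colData` column holding state labels.
#' @return A [splice_dataset()].
#' @export
as_splice_dataset <- function(x, cluster_key = "clusters") {
  if (!requireNamespace("SummarizedExperiment", quietly = TRUE))
    stop("as_splice_dataset() needs the SummarizedExperiment package")
  an <- SummarizedExperiment::assayNames(x)
  for (layer in c("unspliced", "spliced"))
    if (!layer %in% an)
      stop("missing assay '", layer, "' (found: ",
           paste(an, collapse = ", "), ")")
  cd <- SummarizedExperiment::colData(x)
  if (!cluster_key %in% names(cd))
    stop("missing colData column '", cluster_key, "'")
  U <- Matrix::t(SummarizedExperiment::assay(x, "unspliced"))
  S <- Matrix::t(SummarizedExperiment::assay(x, "spliced"))
  splice_dataset(U, S, states = cd[[cluster_key]],
                 gene_names = rownames(x), cell_ids = colnames(x))
}
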