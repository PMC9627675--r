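#' Incoming, outgoing and total signaling scores
#'
#' For an interaction matrix `A` (entry `A[i, j]` = regulation of gene j on
#' gene i), gene i's incoming score is the absolute row sum
#' `I_i = sum_j |A[i, j]|`, its outgoing score the absolute column sum
#' `O_i = sum_j |A[j, i]|`, and the total score `T = I + O`. Absolute values
#' keep strong activators and repressors from cancelling.
#'
#' @param model a `state_linear_model` (element of `fit$models`) or a bare
#'   interaction matrix.
#' @return A data.frame with columns `gene`, `incoming`, `outgoing`,
#'   `total`.
#' @export
signaling_scores <- function(model) {
  A <- if (inherits(model, "state_linear_model")) model$A else as.matrix(model)
  gn <- rownames(A) %||% paste0("gene", seq_len(nrow(A)))
  data.frame(gene = gn,
             incoming = unname(rowSums(abs(A))),
             outgoing = unname(colSums(abs(A))),
             total = unname(rowSums(abs(A)) + colSums(abs(A))),
             stringsAsFactors = FALSE)
}

#' Threshold an interaction matrix into a directed GRN
#'
#' Keeps the off-diagonal interactions whose absolute weight reaches the
#' `q`-quantile (linear-interpolation quantile, inclusive comparison) of the
#' nonzero absolute off-diagonal weights. Edges run regulator -> target and
#' carry the signed weight plus a `sign` attribute (+1 activation,
#' -1 inhibition).
#'
#' @param model a `state_linear_model` or interaction matrix.
#' @param q quantile in [0, 1); `q = 0` keeps every nonzero edge.
#' @return An `igraph` directed graph with edge attributes `weight` and
#'   `sign`; all genes are kept as vertices. All-zero matrices give an
#'   empty graph with a warning.
#' @export
quantile_grn <- function(model, q = 0.9) {
  A <- if (inherits(model, "state_linear_model")) model$A else as.matrix(model)
  if (q < 0 || q >= 1) stop("q must be in [0, 1)")
  gn <- rownames(A) %||% paste0("gene", seq_len(nrow(A)))
  off <- abs(A); diag(off) <- 0
  w <- off[off > 0]
  g <- igraph::make_empty_graph(n = nrow(A), directed = TRUE)
  g <- igraph::set_vertex_attr(g, "name", value = gn)
  if (!length(w)) {
    warning("all-zero interaction matrix: empty GRN")
    return(g)
  }
  thr <- stats::quantile(w, q, names = FALSE, type = 7)
  keep <- which(off >= thr & off > 0, arr.ind = TRUE)
  if (nrow(keep)) {
    # A[i, j]: regulator j -> target i
    el <- cbind(gn[keep[, "col"]], gn[keep[, "row"]])
    g <- igraph::add_edges(g, t(el))
    g <- igraph::set_edge_attr(g, "weight", value = A[keep])
    g <- igraph::set_edge_attr(g, "sign", value = sign(A[keep]))
  }
  g
}

#' Normalized betweenness centrality of a thresholded GRN
#'
#' Directed betweenness on the unweighted thresholded digraph, normalized
#' by `(n-1)(n-2)` so values lie in [0, 1].
#'
#' @param grn an igraph GRN (see [quantile_grn()]).
#' @return Named numeric vector of per-gene centralities.
#' @export
grn_betweenness <- function(grn) {
  n <- igraph::vcount(grn)
  if (igraph::ecount(grn) == 0) {
    warning("empty GRN: all betweenness centralities are zero")
    return(stats::setNames(numeric(n), igraph::V(grn)$name))
  }
  b <- igraph::betweenness(grn, directed = TRUE, weights = NA)
  if (n > 2) b <- b / ((n - 1) * (n - 2))
  b
}

#' Cross-state variability of gene signaling roles
#'
#' Builds, for each gene, the vector of its signaling-metric values across
#' the K fitted states and summarizes its dispersion.
#'
#' @param fit a [splice_fit()] over K >= 2 states.
#' @param metric `"incoming"`, `"outgoing"`, `"total"` or `"betweenness"`.
#' @param measure `"sd"`, `"range"` or `"iqr"`.
#' @param q GRN quantile used when `metric = "betweenness"`.
#' @return A data.frame (`gene`, `variability`) sorted descending.
#' @export
variability_across_states <- function(fit,
                                      metric = c("incoming", "outgoing",
                                                 "total", "betweenness"),
                                      measure = c("sd", "range", "iqr"),
                                      q = 0.9) {
  metric <- match.arg(metric)
  measure <- match.arg(measure)
  if (length(fit$models) < 2) stop("need >= 2 states")
  vals <- sapply(fit$models, function(m) {
    if (metric == "betweenness") grn_betweenness(quantile_grn(m, q))
    else signaling_scores(m)[[metric]]
  })
  rownames(vals) <- fit$gene_names
  disp <- apply(vals, 1, switch(measure,
    sd = stats::sd,
    range = function(v) diff(range(v)),
    iqr = function(v) stats::IQR(v)))
  out <- data.frame(gene = fit$gene_names, variability = unname(disp),
                    stringsAsFactors = FALSE)
  out[order(-out$variability, out$gene), , drop = FALSE]
}

.edge_table <- function(A) {
  gn <- rownames(A) %||% paste0("gene", seq_len(nrow(A)))
  idx <- which(row(A) != col(A), arr.ind = TRUE)
  data.frame(regulator = gn[idx[, "col"]], target = gn[idx[, "row"]],
             i = idx[, "row"], j = idx[, "col"], stringsAsFactors = FALSE)
}

.pair_matrices <- function(model_a, model_b) {
  Aa <- if (inherits(model_a, "state_linear_model")) model_a$A else as.matrix(model_a)
  Ab <- if (inherits(model_b, "state_linear_model")) model_b$A else as.matrix(model_b)
  if (!all(dim(Aa) == dim(Ab)) ||
      !identical(rownames(Aa) %||% "", rownames(Ab) %||% ""))
    stop("models are defined on different gene sets")
  list(Aa = Aa, Ab = Ab)
}

#' Top differential interactions between two states
#'
#' Ranks directed edges by the absolute change in weight
#' `|A_b[i, j] - A_a[i, j]|`, descending.
#'
#' @param model_a,model_b two `state_linear_model`s (or matrices) on the
#'   same gene set.
#' @param top_k edges to keep (default: all off-diagonal edges).
#' @return A data.frame (`regulator`, `target`, `weight_a`, `weight_b`,
#'   `change`, `rank`).
#' @export
differential_interactions <- function(model_a, model_b, top_k = NULL) {
  p <- .pair_matrices(model_a, model_b)
  et <- .edge_table(p$Aa)
  et$weight_a <- p$Aa[cbind(et$i, et$j)]
  et$weight_b <- p$Ab[cbind(et$i, et$j)]
  et$change <- abs(et$weight_b - et$weight_a)
  et <- et[order(-et$change, et$regulator, et$target), ]
  if (!is.null(top_k)) et <- utils::head(et, top_k)
  et$rank <- seq_len(nrow(et))
  rownames(et) <- NULL
  et[, c("regulator", "target", "weight_a", "weight_b", "change", "rank")]
}

#' Top conserved interactions between two states
#'
#' Among edges nonzero in at least one of the two states, ranks by the
#' absolute change ascending (smallest change = most conserved).
#'
#' @inheritParams differential_interactions
#' @return A data.frame like [differential_interactions()].
#' @export
conserved_interactions <- function(model_a, model_b, top_k = NULL) {
  p <- .pair_matrices(model_a, model_b)
  et <- .edge_table(p$Aa)
  et$weight_a <- p$Aa[cbind(et$i, et$j)]
  et$weight_b <- p$Ab[cbind(et$i, et$j)]
  et <- et[et$weight_a != 0 | et$weight_b != 0, ]
  et$change <- abs(et$weight_b - et$weight_a)
  et <- et[order(et$change, et$regulator, et$target), ]
  if (!is.null(top_k)) et <- utils::head(et, top_k)
  et$rank <- seq_len(nrow(et))
  rownames(et) <- NULL
  et[, c("regulator", "target", "weight_a", "weight_b", "change", "rank")]
}

#' GRN similarity between a predictor and an observed state
#'
#' Binarizes the observed state's GRN at the `q_truth` quantile of its
#' nonzero absolute off-diagonal weights (the retained edges are the
#' positives) and scores the predictor state's absolute weights against that
#' labeling with AUROC and AUPRC. High values mean the predictor state's
#' GRN anticipates the observed state's strong interactions.
#'
#' @param predictor,observed `state_linear_model`s (or matrices) on the same
#'   gene set.
#' @param q_truth binarization quantile for the observed GRN (default 0.9).
#' @return List with `auroc` and `auprc`.
#' @export
grn_similarity <- function(predictor, observed, q_truth = 0.9) {
  p <- .pair_matrices(predictor, observed)
  off <- row(p$Aa) != col(p$Aa)
  obs <- abs(p$Ab)[off]
  nz <- obs[obs > 0]
  if (!length(nz)) stop("observed interaction matrix is all zero")
  thr <- stats::quantile(nz, q_truth, names = FALSE, type = 7)
  labels <- obs >= thr & obs > 0
  scores <- abs(p$Aa)[off]
  list(auroc = auroc(scores, labels), auprc = auprc(scores, labels))
}

#' Pairwise GRN similarity matrix over all fitted states
#'
#' @param fit a [splice_fit()].
#' @param q_truth binarization quantile (see [grn_similarity()]).
#' @param metric `"auprc"` or `"auroc"`.
#' @return K x K matrix; entry (w, k) scores state w's GRN as a predictor of
#'   state k's GRN. Diagonal = 1 by construction.
#' @export
grn_similarity_matrix <- function(fit, q_truth = 0.9,
                                  metric = c("auprc", "auroc")) {
  metric <- match.arg(metric)
  K <- length(fit$models)
  out <- matrix(NA_real_, K, K,
                dimnames = list(names(fit$models), names(fit$models)))
  for (w in seq_len(K)) for (k in seq_len(K))
    out[w, k] <- grn_similarity(fit$models[[w]], fit$models[[k]],
                                q_truth)[[metric]]
  out
}

#' Differential-expression fallback ranking
#'
#' Simple built-in stand-in for an external DEG table: per-gene log2
#' fold-change of mean spliced expression in the state versus all other
#' cells, with a pseudocount of 1.
#'
#' @param ds a `splice_dataset`.
#' @param state state label.
#' @return A data.frame (`gene`, `log2fc`) sorted descending.
#' @export
deg_scores <- function(ds, state) {
  .check_state(ds, state)
  idx <- ds$states == state
  mu_in <- Matrix::colMeans(ds$S[idx, , drop = FALSE])
  mu_out <- Matrix::colMeans(ds$S[!idx, , drop = FALSE])
  lfc <- log2((mu_in + 1) / (mu_out + 1))
  out <- data.frame(gene = ds$gene_names, log2fc = unname(lfc),
                    stringsAsFactors = FALSE)
  out[order(-out$log2fc, out$gene), , drop = FALSE]
}

#' Core GRN on top DEGs and top transition genes
#'
#' Induced subgraph of the start state's thresholded GRN on the union of the
#' top `n_deg` differentially expressed genes and the top `n_tg` transition
#' genes; nodes are tagged by category (`"DEG"`, `"TG"` or `"DEG+TG"`).
#'
#' @param model_start the start state's `state_linear_model`.
#' @param ta a `transition_analysis` from the start state.
#' @param deg_ranking data.frame with a `gene` column ranked best-first
#'   (e.g. [deg_scores()] output, or an external table).
#' @param n_deg,n_tg how many genes of each category to include.
#' @param q GRN quantile threshold.
#' @return An igraph graph with vertex attribute `category`.
#' @export
core_grn <- function(model_start, ta, deg_ranking, n_deg = 10, n_tg = 10,
                     q = 0.9) {
  degs <- utils::head(deg_ranking$gene, n_deg)
  tgs <- utils::head(rank_transition_genes(ta)$gene, n_tg)
  keep <- union(degs, tgs)
  if (!length(keep)) stop("empty DEG/TG union")
  g <- quantile_grn(model_start, q)
  keep <- intersect(igraph::V(g)$name, keep)
  sub <- igraph::induced_subgraph(g, keep)
  cat_of <- function(v) {
    if (v %in% degs && v %in% tgs) "DEG+TG" else if (v %in% degs) "DEG" else "TG"
  }
  igraph::set_vertex_attr(sub, "category",
                          value = vapply(igraph::V(sub)$name, cat_of, ""))
}

#' Write a GRN as GraphML and edge-list TSV
#'
#' @param grn an igraph GRN.
#' @param path output path without extension; writes `<path>.graphml` and
#'   `<path>_edges.tsv` (columns regulator, target, weight, sign).
#' @return `path`, invisibly.
#' @export
write_grn <- function(grn, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  igraph::write_graph(grn, paste0(path, ".graphml"), format = "graphml")
  el <- igraph::as_data_frame(grn, what = "edges")
  if (nrow(el)) {
    names(el)[1:2] <- c("regulator", "target")
  } else {
    el <- data.frame(regulator = character(), target = character(),
                     weight = numeric(), sign = numeric())
  }
  utils::write.table(el, paste0(path, "_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
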