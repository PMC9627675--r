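#' Assemble a reproducible run configuration
#'
#' Collects the input location, fitting hyper-parameters, transition edge
#' list and output directory into a single serializable list. Every
#' `cmd_*` run writes its resolved configuration to
#' `<out>/run_config.json` next to the results.
#'
#' @param input input directory ([read_splice_dataset()] layout) or `NULL`
#'   when a dataset is passed directly to the command.
#' @param format `"csv"` or `"mtx"`.
#' @param cluster_key label column name.
#' @param genes optional gene list; `ngenes` optional top-expressed count.
#' @param method,lambda,nboot,frac,beta,seed fitting parameters
#'   (see [splice_fit()]).
#' @param transitions optional 2-column matrix/data.frame of
#'   (start, end) state pairs.
#' @param quantile GRN threshold quantile.
#' @param n_top leading eigenvectors for instability scores.
#' @param out output directory.
#' @param ... extra named entries stored verbatim.
#' @return A `run_config` list.
#' @export
run_config <- function(input = NULL, format = "csv",
                       cluster_key = "clusters", genes = NULL, ngenes = NULL,
                       method = "ridge", lambda = 1, nboot = 10, frac = 0.9,
                       beta = 1, seed = 0, transitions = NULL,
                       quantile = 0.9, n_top = 10, out = "splicedyn_run",
                       ...) {
  structure(list(input = input, format = format, cluster_key = cluster_key,
                 genes = genes, ngenes = ngenes, method = method,
                 lambda = lambda, nboot = nboot, frac = frac, beta = beta,
                 seed = seed, transitions = transitions, quantile = quantile,
                 n_top = n_top, out = out, ...),
            class = "run_config")
}

.load_input <- function(config, ds = NULL) {
  if (is.null(ds)) {
    if (is.null(config$input)) stop("no input dataset in config")
    ds <- read_splice_dataset(config$input, config$format,
                              config$cluster_key)
  }
  if (!is.null(config$genes))
    ds <- select_genes(ds, "user_list", config$genes)
  else if (!is.null(config$ngenes))
    ds <- select_genes(ds, "top_expressed", config$ngenes)
  ds
}

.write_config <- function(config, out) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  cfg <- unclass(config)
  cfg <- cfg[!vapply(cfg, is.null, TRUE)]
  jsonlite::write_json(cfg, file.path(out, "run_config.json"),
                       auto_unbox = TRUE, digits = NA)
}

#' Fit per-state models and write them to disk
#'
#' Writes, per state under `<out>/<state>/`: the interaction matrix
#' (`A.csv`, gene-name headers), basal and degradation rates
#' (`rates.tsv`), and fit metadata (`meta.json`); plus the resolved run
#' configuration. The gene count is validated against
#' [max_genes_checkpoint()] before anything is written.
#'
#' @param config a [run_config()].
#' @param ds optional in-memory [splice_dataset()] overriding
#'   `config$input`.
#' @return The [splice_fit()] object, invisibly.
#' @export
cmd_infer <- function(config, ds = NULL) {
  ds <- .load_input(config, ds)
  maxg <- max_genes_checkpoint(ds, config$frac)
  if (length(ds$gene_names) > maxg)
    stop("gene count ", length(ds$gene_names), " exceeds the checkpoint of ",
         maxg, " genes (smallest state x frac = ", config$frac,
         "); reduce --ngenes or the gene list")
  fit <- splice_fit(ds, method = config$method, lambda = config$lambda,
                    nboot = config$nboot, frac = config$frac,
                    beta = config$beta, seed = config$seed)
  .write_config(config, config$out)
  for (st in names(fit$models)) {
    m <- fit$models[[st]]
    d <- file.path(config$out, st)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(m$A, file.path(d, "A.csv"))
    utils::write.table(
      data.frame(gene = names(m$A0), A0 = unname(m$A0),
                 gamma = unname(m$gamma)),
      file.path(d, "rates.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    jsonlite::write_json(c(m$meta, list(state = st, beta = m$beta)),
                         file.path(d, "meta.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(fit)
}

#' Transition analysis between two fitted states
#'
#' Writes the instability-score table (`transition_<start>_<end>.tsv`), the
#' start state's eigenvalue spectrum (`spectrum_<start>.csv`) and the core
#' GRN (`core_grn_<start>_<end>.graphml` + edge TSV). With more than one
#' `end`, also writes the shared/exclusive branch partition
#' (`branches_<start>.json`).
#'
#' @param config a [run_config()].
#' @param fit a fitted [splice_fit()].
#' @param ds the dataset used for the fit.
#' @param start start state; `end` one or more end states.
#' @return Named list of `transition_analysis` objects, invisibly.
#' @export
cmd_transition <- function(config, fit, ds, start, end) {
  if (any(end == start)) stop("degenerate transition: start == end")
  .write_config(config, config$out)
  decomp <- eigen_decompose(assemble_jacobian(fit, start))
  utils::write.csv(
    data.frame(rank = seq_along(decomp$values),
               re = Re(decomp$values), im = Im(decomp$values)),
    file.path(config$out, paste0("spectrum_", start, ".csv")),
    row.names = FALSE)
  tas <- lapply(end, function(e) {
    ta <- transition_analysis(fit, ds, start, e, n_top = config$n_top)
    tab <- rank_transition_genes(ta)
    utils::write.table(tab,
      file.path(config$out, paste0("transition_", start, "_", e, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
    cg <- core_grn(fit$models[[.match_model(fit, start)]], ta,
                   deg_scores(ds, start), q = config$quantile)
    write_grn(cg, file.path(config$out, paste0("core_grn_", start, "_", e)))
    ta
  })
  names(tas) <- end
  if (length(end) > 1) {
    part <- compare_branches(tas, top_k = 10)
    jsonlite::write_json(part["partition"],
                         file.path(config$out,
                                   paste0("branches_", start, ".json")),
                         auto_unbox = FALSE)
  }
  invisible(tas)
}

#' Simulate a built-in circuit into an on-disk dataset
#'
#' Writes the pooled perturbation-relaxation dataset as a CSV triplet under
#' `<out>/dataset/`, the circuit definition (`circuit.json`) and the
#' per-attractor ground-truth Jacobians (`jacobian_<state>.csv`).
#'
#' @param config a [run_config()]; `config$seed` seeds the simulation.
#' @param circuit circuit name for [builtin_circuit()] or a `circuit_spec`.
#' @param n_cells cells per attractor.
#' @param ... passed to [simulate.circuit_spec()].
#' @return The simulated [splice_dataset()], invisibly.
#' @export
cmd_simulate <- function(config, circuit = "toggle", n_cells = 200, ...) {
  spec <- if (inherits(circuit, "circuit_spec")) circuit
          else builtin_circuit(circuit)
  ds <- simulate(spec, nsim = n_cells, seed = config$seed, ...)
  .write_config(config, config$out)
  write_splice_dataset(ds, file.path(config$out, "dataset"),
                       cluster_key = config$cluster_key)
  write_circuit_spec(spec, file.path(config$out, "circuit.json"))
  fps <- attr(ds, "fixed_points")
  for (st in names(fps))
    utils::write.csv(unclass(fps[[st]]$jacobian),
                     file.path(config$out, paste0("jacobian_", st, ".csv")))
  invisible(ds)
}

#' Benchmark inferred matrices against ground truth
#'
#' @param config a [run_config()].
#' @param J_true,J_inf matrices (or paths to CSV files written by
#'   [cmd_infer()] / [cmd_simulate()]).
#' @param name row label used in the CSV report.
#' @return The `comparison_report`, invisibly; writes
#'   `benchmark_<name>.json` and appends to `benchmark.csv` under
#'   `config$out`.
#' @export
cmd_benchmark <- function(config, J_true, J_inf, name = "comparison") {
  as_mat <- function(x) if (is.character(x))
    as.matrix(utils::read.csv(x, row.names = 1, check.names = FALSE)) else x
  rep <- comparison_report(as_mat(J_true), as_mat(J_inf))
  .write_config(config, config$out)
  jsonlite::write_json(unclass(rep),
                       file.path(config$out,
                                 paste0("benchmark_", name, ".json")),
                       auto_unbox = TRUE, digits = NA)
  row <- data.frame(name = name, as.data.frame(unclass(rep)))
  csv <- file.path(config$out, "benchmark.csv")
  utils::write.table(row, csv, sep = ",", row.names = FALSE,
                     col.names = !file.exists(csv), append = file.exists(csv),
                     quote = FALSE)
  invisible(rep)
}
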