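#' Shifted Hill function and its derivative
#'
#' `hill_shifted(x) = lam + (1 - lam) / (1 + (x / x0)^n)`: equals 1 at
#' `x = 0` and saturates at `lam`; `lam > 1` encodes activation, `lam < 1`
#' inhibition, `lam = 0` complete repression.
#'
#' @param x regulator level (>= 0).
#' @param x0 half-response threshold (> 0).
#' @param n Hill coefficient (>= 1).
#' @param lam fold change (>= 0).
#' @return Function value (or derivative for `hill_shifted_deriv`).
#' @export
hill_shifted <- function(x, x0, n, lam) lam + (1 - lam) / (1 + (x / x0)^n)

#' @rdname hill_shifted
#' @export
hill_shifted_deriv <- function(x, x0, n, lam) {
  r <- (x / x0)^n
  ifelse(x <= 0, ifelse(n == 1, (lam - 1) / x0, 0),
         (lam - 1) * n * r / (x * (1 + r)^2))
}

#' Define a splicing regulatory circuit
#'
#' Dynamics, for species i with spliced level `S_i` and unspliced `U_i`:
#' \deqn{dU_i/dt = k_i \prod_e H_e(S_{source(e)}) - \beta U_i, \qquad
#'       dS_i/dt = \beta U_i - \gamma_i S_i}
#' where the product runs over the shifted-Hill edges targeting i. An
#' optional inducer species has constant production equal to `inducer`
#' instead of `k_i`.
#'
#' @param species character vector of species names.
#' @param k basal/maximal production rates (> 0), one per species.
#' @param edges data.frame with columns `target`, `source` (names or
#'   indices), `x0` (> 0), `n` (>= 1) and `lam` (>= 0).
#' @param beta splicing rate (> 0).
#' @param gamma degradation rates (> 0), one per species.
#' @param inducer_species optional name/index of the inducer-controlled
#'   species.
#' @param inducer inducer production level (required with
#'   `inducer_species`).
#' @param sigma default noise amplitude for [perturbation_sampling()].
#' @return A `circuit_spec` object.
#' @seealso [builtin_circuit()] for ready-made circuits.
#' @export
circuit_spec <- function(species, k, edges, beta = 1,
                         gamma = rep(1, length(species)),
                         inducer_species = NULL, inducer = NULL,
                         sigma = 0.05) {
  N <- length(species)
  if (anyDuplicated(species)) stop("duplicated species names")
  if (length(k) != N || any(k <= 0)) stop("k must be ", N, " positive rates")
  if (length(gamma) != N || any(gamma <= 0))
    stop("gamma must be ", N, " positive rates")
  if (beta <= 0) stop("beta must be > 0")
  to_idx <- function(v) {
    if (is.character(v)) {
      i <- match(v, species)
      if (anyNA(i)) stop("unknown species: ", paste(v[is.na(i)], collapse = ", "))
      i
    } else as.integer(v)
  }
  edges <- data.frame(target = to_idx(edges$target),
                      source = to_idx(edges$source),
                      x0 = edges$x0, n = edges$n, lam = edges$lam)
  if (any(edges$x0 <= 0)) stop("edge thresholds x0 must be > 0")
  if (any(edges$n < 1)) stop("Hill coefficients must be >= 1")
  if (any(edges$lam < 0)) stop("edge fold changes lam must be >= 0")
  if (!is.null(inducer_species)) {
    inducer_species <- to_idx(inducer_species)
    if (is.null(inducer) || inducer <= 0)
      stop("inducer level must be a positive number")
  }
  structure(list(species = species, N = N, k = k, edges = edges,
                 beta = beta, gamma = gamma,
                 inducer_species = inducer_species, inducer = inducer,
                 sigma = sigma),
            class = "circuit_spec")
}

#' @export
print.circuit_spec <- function(x, ...) {
  cat("circuit_spec: ", x$N, " species (",
      paste(x$species, collapse = ", "), "), ",
      nrow(x$edges), " regulatory edges\n", sep = "")
  if (!is.null(x$inducer_species))
    cat("  inducer on ", x$species[x$inducer_species], " = ", x$inducer,
        "\n", sep = "")
  invisible(x)
}

## S may be a length-N vector or an N x m matrix (m states in parallel)
.production_rates <- function(spec, S) {
  vec <- is.null(dim(S))
  if (vec) S <- matrix(S, ncol = 1)
  f <- matrix(spec$k, nrow = spec$N, ncol = ncol(S))
  if (!is.null(spec$inducer_species)) f[spec$inducer_species, ] <- spec$inducer
  e <- spec$edges
  for (r in seq_len(nrow(e)))
    f[e$target[r], ] <- f[e$target[r], ] *
      hill_shifted(S[e$source[r], ], e$x0[r], e$n[r], e$lam[r])
  if (vec) drop(f) else f
}

#' Time derivative of the circuit state
#'
#' @param spec a `circuit_spec`.
#' @param x state vector of length 2N: unspliced then spliced levels.
#' @return Derivative vector of length 2N.
#' @export
circuit_dynamics <- function(spec, x) {
  N <- spec$N
  U <- x[seq_len(N)]
  S <- x[N + seq_len(N)]
  f <- .production_rates(spec, S)
  c(f - spec$beta * U, spec$beta * U - spec$gamma * S)
}

## 2N x m matrix version used by the vectorized SDE integrator
.circuit_dynamics_mat <- function(spec, X) {
  N <- spec$N
  U <- X[seq_len(N), , drop = FALSE]
  S <- X[N + seq_len(N), , drop = FALSE]
  f <- .production_rates(spec, S)
  rbind(f - spec$beta * U, spec$beta * U - spec$gamma * S)
}

#' Analytic Jacobian of the circuit dynamics
#'
#' Closed-form partial derivatives of the splicing dynamics at a point; the
#' interaction block `dU_i/dS_j` uses exact shifted-Hill derivatives. The
#' result has the standard block layout of [splicing_jacobian()].
#'
#' @param spec a `circuit_spec`.
#' @param point state vector of length 2N in the non-negative orthant.
#' @return A `splicing_jacobian` (2N x 2N).
#' @export
analytic_jacobian <- function(spec, point) {
  N <- spec$N
  S <- point[N + seq_len(N)]
  f <- spec$k
  if (!is.null(spec$inducer_species)) f[spec$inducer_species] <- spec$inducer
  A <- matrix(0, N, N)
  for (i in seq_len(N)) {
    eds <- spec$edges[spec$edges$target == i, , drop = FALSE]
    if (!nrow(eds)) next
    hv <- mapply(function(s, x0, n, lam) hill_shifted(S[s], x0, n, lam),
                 eds$source, eds$x0, eds$n, eds$lam)
    for (e in seq_len(nrow(eds)))
      A[i, eds$source[e]] <- A[i, eds$source[e]] +
        f[i] * prod(hv[-e]) *
        hill_shifted_deriv(S[eds$source[e]], eds$x0[e], eds$n[e], eds$lam[e])
  }
  rownames(A) <- colnames(A) <- spec$species
  splicing_jacobian(A, spec$gamma, spec$beta, gene_names = spec$species)
}

#' Locate fixed points of a circuit
#'
#' Multi-start search: deterministic relaxation (lsoda) from random initial
#' conditions followed by Newton refinement with the analytic Jacobian;
#' Newton is additionally started from midpoints between distinct attractors
#' to pick up the saddles that separate them. Duplicates are merged at
#' relative L-infinity tolerance 1e-3.
#'
#' @param spec a `circuit_spec`.
#' @param n_starts number of random starts (default 40).
#' @param tol residual tolerance `max|dx/dt|` at a reported fixed point.
#' @param seed RNG seed for the random starts.
#' @param t_relax horizon of the relaxation integration.
#' @return List of `fixed_point` objects, each with `location` (length 2N),
#'   `jacobian` (analytic), `eigenvalues`, and `stable` flag; sorted by
#'   total spliced level. Empty (with a warning) if nothing converged.
#' @export
find_fixed_points <- function(spec, n_starts = 40, tol = 1e-8, seed = 1,
                              t_relax = 300) {
  set.seed(seed)
  N <- spec$N
  smax <- spec$k / spec$gamma
  if (!is.null(spec$inducer_species))
    smax[spec$inducer_species] <- spec$inducer / spec$gamma[spec$inducer_species]
  lam_max <- vapply(seq_len(N), function(i) {
    e <- spec$edges[spec$edges$target == i, , drop = FALSE]
    if (nrow(e)) prod(pmax(e$lam, 1)) else 1
  }, 0)
  smax <- smax * lam_max
  pts <- list()
  add_point <- function(x) {
    if (max(abs(circuit_dynamics(spec, x))) > max(tol, 1e-8)) return(FALSE)
    for (p in pts)
      if (max(abs(p - x)) / max(max(abs(x)), 1e-8) < 1e-3) return(FALSE)
    pts[[length(pts) + 1]] <<- x
    TRUE
  }
  relax <- function(x0) {
    out <- try(deSolve::ode(y = x0, times = c(0, t_relax), parms = NULL,
                            func = function(t, y, p)
                              list(circuit_dynamics(spec, y)),
                            method = "lsoda"), silent = TRUE)
    if (inherits(out, "try-error")) return(NULL)
    pmax(as.numeric(out[nrow(out), -1]), 0)
  }
  for (s in seq_len(n_starts)) {
    S0 <- stats::runif(N, 0, 1.5) * smax
    x <- relax(c(S0 * spec$gamma / spec$beta, S0))
    if (is.null(x)) next
    x <- .newton_refine(spec, x, tol)
    if (!is.null(x)) add_point(x)
  }
  # saddle hunt: Newton from midpoints of distinct solutions
  if (length(pts) >= 2) {
    combos <- utils::combn(length(pts), 2)
    for (c_i in seq_len(ncol(combos))) {
      mid <- (pts[[combos[1, c_i]]] + pts[[combos[2, c_i]]]) / 2
      x <- .newton_refine(spec, mid, tol)
      if (!is.null(x)) add_point(x)
    }
  }
  if (!length(pts)) {
    warning("no fixed point converged from any start")
    return(list())
  }
  fps <- lapply(pts, function(x) {
    J <- analytic_jacobian(spec, x)
    ev <- eigen(unclass(J), only.values = TRUE)$values
    structure(list(location = stats::setNames(
                     x, c(paste0(spec$species, "_u"),
                          paste0(spec$species, "_s"))),
                   jacobian = J,
                   eigenvalues = ev[order(-Re(ev))],
                   stable = max(Re(ev)) < 0),
              class = "fixed_point")
  })
  fps[order(vapply(fps, function(p) sum(p$location[N + seq_len(N)]), 0))]
}

.newton_refine <- function(spec, x, tol, max_iter = 80) {
  for (it in seq_len(max_iter)) {
    F <- circuit_dynamics(spec, x)
    if (max(abs(F)) < tol * 1e-2) break
    J <- unclass(analytic_jacobian(spec, x))
    dx <- tryCatch(solve(J, -F), error = function(e) NULL)
    if (is.null(dx)) return(NULL)
    x <- pmax(x + dx, 0)
  }
  if (max(abs(circuit_dynamics(spec, x))) <= max(tol, 1e-8)) x else NULL
}

#' @export
print.fixed_point <- function(x, ...) {
  cat(if (x$stable) "stable" else "unstable",
      " fixed_point, leading Re(eigenvalue) = ",
      format(max(Re(x$eigenvalues)), digits = 4), "\n", sep = "")
  print(x$location, digits = 3)
  invisible(x)
}

#' Sample perturbation-relaxation "cells" around a fixed point
#'
#' Emulates the synthetic single-cell protocol: each trajectory starts
#' exactly on the fixed point, receives a small Gaussian perturbation
#' (standard deviation `eps` relative to the coordinate scale), and is then
#' integrated as an SDE (Euler-Maruyama, additive noise `sigma`, reflection
#' to zero). States are recorded at uniform times up to `t_max` and pooled
#' as cells.
#'
#' @param spec a `circuit_spec`.
#' @param fp a `fixed_point` (or bare length-2N location). Unstable points
#'   are allowed only with `allow_unstable = TRUE`.
#' @param n_cells total cells to sample (default 200).
#' @param eps relative perturbation scale (> 0 unless exactly 0 with
#'   `sigma = 0`).
#' @param dt Euler-Maruyama step.
#' @param t_max trajectory duration.
#' @param sigma additive noise amplitude (default: the spec's).
#' @param samples_per_traj recorded cells per trajectory (default 2;
#'   small values keep the pooled cells close to independent).
#' @param seed RNG seed.
#' @param label state label attached to all sampled cells.
#' @param allow_unstable permit sampling around an unstable point.
#' @return A [splice_dataset()] with `n_cells` cells, genes = species.
#' @export
perturbation_sampling <- function(spec, fp, n_cells = 200, eps = 0.2,
                                  dt = 0.01, t_max = 5, sigma = NULL,
                                  samples_per_traj = 2, seed = 1,
                                  label = "state", allow_unstable = FALSE) {
  if (dt <= 0) stop("dt must be > 0")
  if (t_max <= dt) stop("t_max must exceed dt")
  if (eps < 0) stop("eps must be >= 0")
  if (is.null(sigma)) sigma <- spec$sigma
  x0 <- if (inherits(fp, "fixed_point")) unname(fp$location) else as.numeric(fp)
  if (inherits(fp, "fixed_point") && !fp$stable && !allow_unstable)
    stop("fixed point is unstable; pass allow_unstable = TRUE to sample anyway")
  N <- spec$N
  set.seed(seed)
  n_traj <- ceiling(n_cells / samples_per_traj)
  rec_times <- seq(t_max / samples_per_traj, t_max,
                   length.out = samples_per_traj)
  scale <- pmax(x0, 1e-3)
  nstep <- ceiling(t_max / dt)
  rec_step <- pmin(round(rec_times / dt), nstep)
  # all trajectories advance in lockstep as columns of X
  X <- matrix(x0, 2 * N, n_traj) +
    eps * scale * matrix(stats::rnorm(2 * N * n_traj), 2 * N)
  X <- pmax(X, 0)
  recorded <- vector("list", samples_per_traj)
  nxt <- 1
  sq <- sqrt(dt) * sigma
  for (s in seq_len(nstep)) {
    X <- X + dt * .circuit_dynamics_mat(spec, X) +
      sq * matrix(stats::rnorm(2 * N * n_traj), 2 * N)
    X <- abs(X)  # reflection at zero
    while (nxt <= samples_per_traj && s == rec_step[nxt]) {
      recorded[[nxt]] <- t(X)
      nxt <- nxt + 1
    }
  }
  # cells ordered trajectory-major so truncation drops whole late records
  cells <- do.call(rbind, recorded)
  ord <- order(rep(seq_len(n_traj), samples_per_traj))
  cells <- cells[ord, , drop = FALSE][seq_len(n_cells), , drop = FALSE]
  splice_dataset(cells[, seq_len(N), drop = FALSE],
                 cells[, N + seq_len(N), drop = FALSE],
                 states = rep(label, n_cells),
                 gene_names = spec$species,
                 cell_ids = paste0(label, "_cell", seq_len(n_cells)))
}

#' Simulate a multistable circuit into a labelled dataset
#'
#' Locates the stable fixed points of the circuit and draws
#' perturbation-relaxation samples around each, pooling them into one
#' dataset with one state label per attractor (`state1`, `state2`, ... in
#' ascending total spliced level).
#'
#' @param object a `circuit_spec`.
#' @param nsim cells per attractor (default 200).
#' @param seed RNG seed.
#' @param n_starts passed to [find_fixed_points()].
#' @param ... passed to [perturbation_sampling()] (`eps`, `dt`, `t_max`,
#'   `sigma`, `samples_per_traj`).
#' @return A [splice_dataset()] with attribute `fixed_points` (the stable
#'   `fixed_point` objects, named like the labels).
#' @export
simulate.circuit_spec <- function(object, nsim = 200, seed = 1,
                                  n_starts = 40, ...) {
  fps <- Filter(function(p) p$stable,
                find_fixed_points(object, n_starts = n_starts, seed = seed))
  if (!length(fps)) stop("no stable fixed point found")
  labels <- paste0("state", seq_along(fps))
  parts <- mapply(function(fp, lab, i)
    perturbation_sampling(object, fp, n_cells = nsim, seed = seed + i,
                          label = lab, ...),
    fps, labels, seq_along(fps), SIMPLIFY = FALSE)
  ds <- splice_dataset(
    do.call(rbind, lapply(parts, function(d) as.matrix(d$U))),
    do.call(rbind, lapply(parts, function(d) as.matrix(d$S))),
    states = unlist(lapply(parts, function(d) as.character(d$states))),
    gene_names = object$species,
    cell_ids = unlist(lapply(parts, function(d) d$cell_ids)))
  attr(ds, "fixed_points") <- stats::setNames(fps, labels)
  ds
}

#' Count attractors along a parameter scan
#'
#' Re-locates the fixed points at each parameter value, carrying the
#' previous value's attractors as additional Newton starts (numerical
#' continuation) so folds are tracked reliably.
#'
#' @param spec a `circuit_spec`.
#' @param param_name currently `"inducer"`, or the name of a rate entry
#'   (`"beta"`, `"k<i>"` via index, ...); see Details.
#' @param values numeric parameter values to scan.
#' @param n_starts random starts per value.
#' @param seed RNG seed.
#' @details Supported parameters: `"inducer"` (requires an inducer species)
#'   and `"beta"`. Unknown names raise an error.
#' @return A list with `table` (data.frame `value`, `n_stable`) and
#'   `attractors` (per-value list of stable `fixed_point`s).
#' @export
bifurcation_scan <- function(spec, param_name = "inducer", values,
                             n_starts = 40, seed = 1) {
  if (!param_name %in% c("inducer", "beta"))
    stop("unknown parameter '", param_name, "' (supported: inducer, beta)")
  if (param_name == "inducer" && is.null(spec$inducer_species))
    stop("circuit has no inducer species")
  prev <- list()
  attractors <- vector("list", length(values))
  n_stable <- integer(length(values))
  for (v in seq_along(values)) {
    spec[[param_name]] <- values[v]
    fps <- find_fixed_points(spec, n_starts = n_starts, seed = seed)
    locs <- lapply(fps, function(p) unname(p$location))
    for (p0 in prev) {
      x <- .newton_refine(spec, p0, 1e-8)
      if (is.null(x)) next
      if (!any(vapply(locs, function(q)
            max(abs(q - x)) / max(max(abs(x)), 1e-8) < 1e-3, logical(1)))) {
        J <- analytic_jacobian(spec, x)
        ev <- eigen(unclass(J), only.values = TRUE)$values
        fps[[length(fps) + 1]] <- structure(
          list(location = stats::setNames(
                 x, c(paste0(spec$species, "_u"), paste0(spec$species, "_s"))),
               jacobian = J, eigenvalues = ev[order(-Re(ev))],
               stable = max(Re(ev)) < 0),
          class = "fixed_point")
        locs[[length(locs) + 1]] <- x
      }
    }
    st <- Filter(function(p) p$stable, fps)
    attractors[[v]] <- st
    n_stable[v] <- length(st)
    prev <- lapply(st, function(p) unname(p$location))
  }
  list(table = data.frame(value = values, n_stable = n_stable),
       attractors = attractors)
}

#' Built-in benchmark circuits
#'
#' \describe{
#'   \item{`toggle`}{Two genes X and Y under symmetric mutual Hill
#'     inhibition (`f_X = 1.5 / (1 + S_Y^4)` and vice versa), in the bistable
#'     regime: two symmetric attractors (high X / low Y and its mirror)
#'     separated by a saddle on the diagonal.}
#'   \item{`loop3`}{Three genes activating each other in a cycle
#'     (g1 -> g2 -> g3 -> g1) with basal production; monostable at the
#'     default gentle activation.}
#'   \item{`emt`}{Eight-node epithelial-mesenchymal transition circuit:
#'     miR-34 and miR-200 (epithelial microRNAs), ZEB and SNAIL
#'     (mesenchymal transcription factors), an external TGF-beta inducer,
#'     cellular TGF-beta, and the output markers E-cadherin and N-cadherin
#'     (no outgoing regulation). SNAIL/miR-34 and ZEB/miR-200 form two
#'     mutually inhibitory switches in cascade; raising the inducer moves
#'     the system from a single epithelial attractor, through a window
#'     where epithelial, hybrid E/M and mesenchymal states coexist
#'     (inducer in roughly [0.7, 1.2]; the documented tristable default is
#'     1.0), to a single mesenchymal attractor.}
#' }
#'
#' @param name `"toggle"`, `"loop3"` or `"emt"`.
#' @param inducer inducer level for `emt` (default 1.0, inside the
#'   tristable window).
#' @return A [circuit_spec()].
#' @export
builtin_circuit <- function(name = c("toggle", "loop3", "emt"),
                            inducer = 1.0) {
  name <- match.arg(name)
  switch(name,
    toggle = circuit_spec(
      species = c("X", "Y"),
      k = c(1.5, 1.5),
      edges = data.frame(target = c("X", "Y"), source = c("Y", "X"),
                         x0 = 1, n = 4, lam = 0)),
    loop3 = circuit_spec(
      species = c("g1", "g2", "g3"),
      k = c(0.5, 0.5, 0.5),
      edges = data.frame(target = c("g2", "g3", "g1"),
                         source = c("g1", "g2", "g3"),
                         x0 = 1, n = 2, lam = 5)),
    emt = circuit_spec(
      species = c("miR34", "miR200", "ZEB", "SNAIL", "TGFB_ext", "TGFB",
                  "Ecad", "Ncad"),
      k = c(2.0, 1.5, 0.7, 0.6, 1.0, 1.0, 1.0, 0.5),
      edges = rbind(
        data.frame(target = "miR34", source = "SNAIL",
                   x0 = 0.9, n = 4, lam = 0.1),
        data.frame(target = "miR34", source = "ZEB",
                   x0 = 1.5, n = 1, lam = 0.8),
        data.frame(target = "miR200", source = "ZEB",
                   x0 = 1.0, n = 4, lam = 0.1),
        data.frame(target = "miR200", source = "SNAIL",
                   x0 = 1.5, n = 1, lam = 0.7),
        data.frame(target = "ZEB", source = "SNAIL",
                   x0 = 1.2, n = 4, lam = 3.0),
        data.frame(target = "ZEB", source = "miR200",
                   x0 = 0.8, n = 4, lam = 0.1),
        data.frame(target = "SNAIL", source = "TGFB_ext",
                   x0 = 1.0, n = 2, lam = 4.0),
        data.frame(target = "SNAIL", source = "TGFB",
                   x0 = 1.0, n = 2, lam = 2.0),
        data.frame(target = "SNAIL", source = "miR34",
                   x0 = 1.2, n = 4, lam = 0.1),
        data.frame(target = "TGFB", source = "miR200",
                   x0 = 1.0, n = 1, lam = 0.2),
        data.frame(target = "Ecad", source = "SNAIL",
                   x0 = 1.0, n = 1, lam = 0.3),
        data.frame(target = "Ecad", source = "ZEB",
                   x0 = 1.0, n = 1, lam = 0.3),
        data.frame(target = "Ncad", source = "SNAIL",
                   x0 = 1.0, n = 1, lam = 3.0),
        data.frame(target = "Ncad", source = "ZEB",
                   x0 = 1.0, n = 1, lam = 3.0)),
      inducer_species = "TGFB_ext", inducer = inducer))
}

#' Serialize / restore a circuit spec as JSON
#'
#' @param spec a `circuit_spec`.
#' @param path JSON file path.
#' @return `write_circuit_spec` returns `path` invisibly;
#'   `read_circuit_spec` returns the restored `circuit_spec`.
#' @export
write_circuit_spec <- function(spec, path) {
  x <- unclass(spec)
  x$edges <- as.data.frame(x$edges)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_circuit_spec
#' @export
read_circuit_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  circuit_spec(species = x$species, k = x$k, edges = x$edges,
               beta = x$beta, gamma = x$gamma,
               inducer_species = x$inducer_species, inducer = x$inducer,
               sigma = x$sigma)
}
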