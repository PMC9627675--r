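#' Infer spliced-mRNA degradation rates within one state
#'
#' At steady state the splicing balance `beta * U_i = gamma_i * S_i` gives
#' `gamma_i = beta * mean(U_i) / mean(S_i)` over the state's cells.
#'
#' @param ds_state a `splice_dataset` restricted to a single state
#'   (see [subset_state()]).
#' @param beta splicing rate constant (shared across genes).
#' @return Named numeric vector of per-gene degradation rates.
#' @export
infer_degradation_rates <- function(ds_state, beta = 1) {
  mu_u <- Matrix::colMeans(ds_state$U)
  mu_s <- Matrix::colMeans(ds_state$S)
  if (any(mu_s <= 0))
    stop("degenerate gene(s) with zero mean spliced expression: ",
         paste(ds_state$gene_names[mu_s <= 0], collapse = ", "))
  g <- beta * mu_u / mu_s
  names(g) <- ds_state$gene_names
  g
}

## Single penalized least-squares solve for one gene:
## minimize sum_c (a0 + x_c' b - y_c)^2 + lam * pen(b), intercept unpenalized.
.solve_gene <- function(X, y, method, lam) {
  p <- ncol(X)
  if (method == "linear" || lam == 0) {
    fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X), y)
    cf <- fit$coefficients
    if (anyNA(cf)) {
      warning("collinear predictors: rank-deficient fit; dropped ",
              "coefficients set to zero", call. = FALSE)
      cf[is.na(cf)] <- 0
    }
    cf
  } else if (method == "ridge") {
    Xa <- cbind(1, X)
    D <- diag(c(0, rep(1, p)))
    cf <- drop(solve(crossprod(Xa) + lam * D, crossprod(Xa, y)))
    names(cf) <- c("(Intercept)", colnames(X))
    cf
  } else { # lasso via glmnet; objective (1/2n)RSS + lam_g * |b|_1,
           # so lam_g = lam / (2n) matches RSS + lam * |b|_1
    n <- nrow(X)
    fit <- glmnet::glmnet(X, y, alpha = 1, lambda = lam / (2 * n),
                          standardize = FALSE, intercept = TRUE,
                          thresh = 1e-12)
    cf <- c(fit$a0[1], as.numeric(fit$beta[, 1]))
    names(cf) <- c("(Intercept)", colnames(X))
    cf
  }
}

.fit_interactions_once <- function(U, S, method, lam, beta, standardize) {
  N <- ncol(S)
  A <- matrix(0, N, N, dimnames = list(colnames(S), colnames(S)))
  A0 <- numeric(N)
  for (i in seq_len(N)) {
    X <- S[, -i, drop = FALSE]
    y <- beta * U[, i]
    if (standardize) {
      sds <- apply(X, 2, stats::sd)
      sds[sds == 0] <- 1
      cf <- .solve_gene(sweep(X, 2, sds, "/"), y, method, lam)
      cf[-1] <- cf[-1] / sds
    } else {
      cf <- .solve_gene(X, y, method, lam)
    }
    A0[i] <- cf[1]
    A[i, -i] <- cf[-1]
  }
  list(A = A, A0 = stats::setNames(A0, colnames(S)))
}

#' Fit the state-specific linearized splicing model
#'
#' For every cell state, regresses each gene's unspliced counts on the
#' spliced counts of all other genes (plus an intercept) across the state's
#' cells, solving
#' \deqn{\min_{A_{i0}, A_{ij}} \sum_c \Big(A_{i0} + \sum_{j \ne i} A_{ij}
#'   S_j^c - \beta U_i^c\Big)^2 + \lambda F(A_{ij})}
#' with `F` the ridge or lasso penalty (intercept unpenalized). The
#' self-term `A_ii` is excluded to avoid the collinearity induced by the
#' splicing balance, so the interaction matrix has an exactly zero diagonal.
#' Each state's fit is repeated `nboot` times on random subsamples of a
#' fraction `frac` of its cells (without replacement) and the coefficient
#' matrices are averaged element-wise.
#'
#' @param ds a [splice_dataset()].
#' @param method `"linear"`, `"ridge"` or `"lasso"`.
#' @param lambda penalty strength \eqn{\lambda \ge 0} (ignored for
#'   `"linear"`); default 1 for ridge/lasso.
#' @param nboot number of bootstrap repeats (default 10).
#' @param frac subsample fraction \eqn{\rho} in (0, 1] (default 0.9).
#' @param beta splicing rate constant (default 1).
#' @param seed integer seed making the subsampling reproducible.
#' @param states states to fit (default: all).
#' @param standardize standardize predictors before penalized regression?
#'   Off by default so coefficients stay in count units and signaling
#'   scores remain interpretable.
#' @param normalize_library divide each cell's counts (both layers) by its
#'   total spliced count times the median total, before fitting. Off by
#'   default; counts are otherwise used exactly as provided.
#'
#' @return An object of class `splice_fit`: a list with `models` (one
#'   `state_linear_model` per state, each holding the interaction matrix
#'   `A`, basal rates `A0`, degradation rates `gamma`, `beta` and fit
#'   metadata), `gene_names` and the matched `call`. Methods: `print`,
#'   `summary`, [coef.splice_fit()], [predict.splice_fit()],
#'   [residuals.splice_fit()], [plot.splice_fit()].
#'
#' @details The gene count must not exceed `floor(frac * n_cells)` in any
#'   fitted state ([max_genes_checkpoint()]); otherwise the per-gene systems
#'   are underdetermined and fitting stops with an error.
#' @export
splice_fit <- function(ds, method = c("linear", "ridge", "lasso"),
                       lambda = NULL, nboot = 10, frac = 0.9, beta = 1,
                       seed = NULL, states = levels(ds$states),
                       standardize = FALSE, normalize_library = FALSE) {
  method <- match.arg(method)
  if (is.null(lambda)) lambda <- if (method == "linear") 0 else 1
  if (lambda < 0) stop("lambda must be >= 0")
  if (frac <= 0 || frac > 1) stop("frac must be in (0, 1]")
  if (nboot < 1) stop("nboot must be >= 1")
  if (beta <= 0) stop("beta must be > 0")
  .check_state(ds, states)

  if (normalize_library) ds <- .normalize_library(ds)

  N <- length(ds$gene_names)
  for (st in states) {
    ncell <- sum(ds$states == st)
    if (N > floor(frac * ncell))
      stop("state '", st, "' supports at most ", floor(frac * ncell),
           " genes at frac = ", frac, " (", ncell, " cells; see ",
           "max_genes_checkpoint()), but ", N, " were requested")
  }

  if (!is.null(seed)) set.seed(seed)
  models <- lapply(states, function(st) {
    dss <- subset_state(ds, st)
    U <- as.matrix(dss$U)
    S <- as.matrix(dss$S)
    ncell <- nrow(S)
    nsub <- max(1L, floor(frac * ncell))
    acc_A <- matrix(0, N, N)
    acc_A0 <- numeric(N)
    for (b in seq_len(nboot)) {
      # a full-size subsample is the identity: keeps nboot = 1, frac = 1
      # bit-identical to the plain full-data fit
      idx <- if (nsub == ncell) seq_len(ncell) else sample.int(ncell, nsub)
      one <- .fit_interactions_once(U[idx, , drop = FALSE],
                                    S[idx, , drop = FALSE],
                                    method, lambda, beta, standardize)
      acc_A <- acc_A + one$A
      acc_A0 <- acc_A0 + one$A0
    }
    A <- acc_A / nboot
    dimnames(A) <- list(ds$gene_names, ds$gene_names)
    structure(list(A = A,
                   A0 = stats::setNames(acc_A0 / nboot, ds$gene_names),
                   gamma = infer_degradation_rates(dss, beta),
                   beta = beta, state = st,
                   meta = list(method = method, lambda = lambda,
                               nboot = nboot, frac = frac, seed = seed,
                               n_cells = ncell)),
              class = "state_linear_model")
  })
  names(models) <- states
  structure(list(models = models, gene_names = ds$gene_names,
                 states = states, call = match.call()),
            class = "splice_fit")
}

.normalize_library <- function(ds) {
  tot <- Matrix::rowSums(ds$S)
  if (any(tot <= 0)) stop("cells with zero total spliced counts")
  f <- stats::median(tot) / tot
  ds$U <- ds$U * f
  ds$S <- ds$S * f
  ds
}

#' @export
print.state_linear_model <- function(x, ...) {
  cat("state_linear_model for state '", x$state, "': ", nrow(x$A),
      " genes, method = ", x$meta$method,
      " (lambda = ", x$meta$lambda, ", nboot = ", x$meta$nboot,
      ", frac = ", x$meta$frac, ")\n", sep = "")
  invisible(x)
}

#' @export
print.splice_fit <- function(x, ...) {
  cat("splice_fit: ", length(x$gene_names), " genes, states: ",
      paste(x$states, collapse = ", "), "\n", sep = "")
  m <- x$models[[1]]$meta
  cat("  method = ", x$models[[1]]$meta$method, ", lambda = ", m$lambda,
      ", nboot = ", m$nboot, ", frac = ", m$frac, "\n", sep = "")
  invisible(x)
}

#' Extract interaction matrices from a splice_fit
#'
#' @param object a `splice_fit`.
#' @param state a single state name, or `NULL` for a named list over states.
#' @param ... ignored.
#' @return The N x N interaction matrix `A` (entry `A[i, j]` = effect of
#'   gene j's spliced level on gene i's unspliced production), or a list of
#'   them.
#' @export
coef.splice_fit <- function(object, state = NULL, ...) {
  if (is.null(state)) return(lapply(object$models, function(m) m$A))
  object$models[[.match_model(object, state)]]$A
}

.match_model <- function(fit, state) {
  i <- match(state, names(fit$models))
  if (is.na(i)) stop("no fitted model for state '", state, "'")
  i
}

#' Predicted unspliced counts under the fitted linear model
#'
#' Evaluates `U_hat = (A0 + A S) / beta` for the given state's model.
#'
#' @param object a `splice_fit`.
#' @param state state whose model to use.
#' @param newdata optional spliced-count matrix (cells x genes, dataset gene
#'   order) or a `splice_dataset`; defaults require an explicit matrix.
#' @param ... ignored.
#' @return Matrix of predicted unspliced counts, cells x genes.
#' @export
predict.splice_fit <- function(object, state, newdata, ...) {
  m <- object$models[[.match_model(object, state)]]
  S <- if (inherits(newdata, "splice_dataset")) as.matrix(newdata$S)
       else as.matrix(newdata)
  if (ncol(S) != length(object$gene_names))
    stop("newdata must have ", length(object$gene_names), " gene columns")
  sweep(S %*% t(m$A), 2, m$A0, "+") / m$beta
}

#' Residuals of the state-wise regression
#'
#' @param object a `splice_fit`.
#' @param ds the `splice_dataset` the model was fitted on.
#' @param state state name.
#' @param ... ignored.
#' @return Matrix `U - U_hat` over the state's cells.
#' @export
residuals.splice_fit <- function(object, ds, state, ...) {
  dss <- subset_state(ds, state)
  as.matrix(dss$U) - predict(object, state, newdata = dss)
}

#' @export
summary.splice_fit <- function(object, ...) {
  rows <- lapply(object$models, function(m) {
    J <- assemble_jacobian(m)
    ev <- eigen_decompose(J)
    data.frame(state = m$state, n_cells = m$meta$n_cells,
               max_re_eigenvalue = Re(ev$values[1]),
               stability = stability_report(ev),
               total_abs_weight = sum(abs(m$A)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("summary.splice_fit", "data.frame")
  out
}

#' Eigenvalue spectra of the fitted state Jacobians
#'
#' Plots the real parts of each state's Jacobian eigenvalues in descending
#' rank, one panel series per state, with the zero line marked.
#'
#' @param x a `splice_fit`.
#' @param ... passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.splice_fit <- function(x, ...) {
  sp <- sapply(x$models, function(m)
    Re(eigen_decompose(assemble_jacobian(m))$values))
  graphics::matplot(sp, type = "b", pch = 1, lty = 1,
                    xlab = "eigenvalue rank", ylab = "Re(eigenvalue)", ...)
  graphics::abline(h = 0, lty = 2, col = "grey40")
  graphics::legend("topright", legend = colnames(sp), col = seq_len(ncol(sp)),
                   lty = 1, bty = "n")
  invisible(x)
}

#' Assemble the 2N x 2N splicing Jacobian of a fitted state model
#'
#' Block layout (rows/cols 1..N unspliced, N+1..2N spliced):
#' upper-left `-beta I`, upper-right `A` (zero diagonal), lower-left
#' `+beta I`, lower-right `-diag(gamma)`.
#'
#' @param model a `state_linear_model` (one element of `fit$models`), or a
#'   `splice_fit` together with `state`.
#' @param state state name when `model` is a `splice_fit`.
#' @return A `splicing_jacobian`: the 2N x 2N matrix with coordinate names
#'   `<gene>_u`, `<gene>_s` and attribute `gene_names`.
#' @export
assemble_jacobian <- function(model, state = NULL) {
  if (inherits(model, "splice_fit"))
    model <- model$models[[.match_model(model, state)]]
  if (!inherits(model, "state_linear_model"))
    stop("model must be a state_linear_model or splice_fit")
  splicing_jacobian(model$A, model$gamma, model$beta,
                    gene_names = rownames(model$A))
}

#' Build a splicing Jacobian from its blocks
#'
#' @param A N x N interaction matrix (zero diagonal).
#' @param gamma length-N positive degradation rates.
#' @param beta positive splicing rate.
#' @param gene_names gene identifiers (default from `A`).
#' @return A `splicing_jacobian` matrix (see [assemble_jacobian()]).
#' @export
splicing_jacobian <- function(A, gamma, beta = 1, gene_names = rownames(A)) {
  N <- nrow(A)
  if (ncol(A) != N) stop("A must be square")
  if (any(abs(diag(A)) > 0)) stop("A must have a zero diagonal")
  if (length(gamma) != N || any(gamma <= 0)) stop("gamma must be N positive rates")
  if (beta <= 0) stop("beta must be > 0")
  if (is.null(gene_names)) gene_names <- paste0("gene", seq_len(N))
  J <- rbind(cbind(-beta * diag(N), A),
             cbind(beta * diag(N), -diag(gamma, N)))
  dimnames(J) <- rep(list(c(paste0(gene_names, "_u"),
                            paste0(gene_names, "_s"))), 2)
  structure(J, gene_names = gene_names, class = c("splicing_jacobian", "matrix"))
}

#' @export
print.splicing_jacobian <- function(x, ...) {
  N <- length(attr(x, "gene_names"))
  cat("splicing_jacobian: ", 2 * N, " x ", 2 * N, " (", N, " genes)\n", sep = "")
  print(unclass(x)[seq_len(min(6, 2 * N)), seq_len(min(6, 2 * N))], ...)
  if (2 * N > 6) cat("...\n")
  invisible(x)
}
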