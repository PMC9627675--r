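# Fixtures built in code.

# Cells drawn from the exact linear model U_i = A0_i + sum_{j != i} A*_ij S_j,
# optionally with additive Gaussian noise on U. Spliced counts are positive
# uniform draws so the regression design is well conditioned.
make_linear_dataset <- function(n_cells, A_star, A0 = rep(1, nrow(A_star)),
                                beta = 1, noise_sd = 0, seed = 42,
                                state = "A") {
  set.seed(seed)
  N <- nrow(A_star)
  S <- matrix(stats::runif(n_cells * N, 1, 4), n_cells, N)
  U <- (sweep(S %*% t(A_star), 2, A0, "+") +
          matrix(stats::rnorm(n_cells * N, 0, noise_sd), n_cells, N)) / beta
  U <- pmax(U, 0)
  splice_dataset(U, S, states = rep(state, n_cells),
                 gene_names = paste0("g", seq_len(N)))
}

# Small deterministic two-state dataset for container-level tests.
make_toy_dataset <- function() {
  U <- matrix(c(1, 2, 3,
                2, 3, 4,
                0, 1, 2,
                5, 5, 5,
                4, 4, 4,
                3, 3, 3), nrow = 6, byrow = TRUE)
  S <- U + 1
  splice_dataset(U, S, states = rep(c("A", "B"), each = 3),
                 gene_names = c("gx", "gy", "gz"),
                 cell_ids = paste0("c", 1:6))
}

# Per-gene penalized least-squares oracle used to cross-check splice_fit:
# direct normal-equation solve of min ||a0 + X b - y||^2 + lam ||b||^2.
oracle_gene_fit <- function(S, U, i, beta = 1, lam = 0) {
  X <- cbind(1, S[, -i, drop = FALSE])
  y <- beta * U[, i]
  D <- diag(c(0, rep(1, ncol(X) - 1)))
  drop(solve(crossprod(X) + lam * D, crossprod(X, y)))
}
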