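# Independent high-precision convex-optimization oracle for the
# L1-regularised maxent objective: split lambda = a - b with a, b >= 0 so the
# objective is smooth, and minimise by L-BFGS-B with analytic gradients.
# Shares no code with the package solver.
oracle_maxent <- function(F_bg, fbar, beta) {
  J <- ncol(F_bg)
  lse <- function(x) { mx <- max(x); mx + log(sum(exp(x - mx))) }
  fn <- function(ab) {
    lam <- ab[1:J] - ab[(J + 1):(2 * J)]
    -(sum(lam * fbar) - lse(as.numeric(F_bg %*% lam)) -
        sum(beta * (ab[1:J] + ab[(J + 1):(2 * J)])))
  }
  gr <- function(ab) {
    lam <- ab[1:J] - ab[(J + 1):(2 * J)]
    eta <- as.numeric(F_bg %*% lam)
    w <- exp(eta - lse(eta))
    g <- fbar - as.numeric(crossprod(F_bg, w))
    c(-g + beta, g + beta)
  }
  res <- stats::optim(rep(0, 2 * J), fn, gr, method = "L-BFGS-B",
                      lower = 0, control = list(maxit = 5000, factr = 10))
  res$par[1:J] - res$par[(J + 1):(2 * J)]
}

# single-row grid whose J continuous layers carry arbitrary values
row_stack <- function(values) {
  n <- nrow(values)
  g <- fire_grid(1, n)
  fire_stack(lapply(seq_len(ncol(values)), function(j)
    fire_layer(g, matrix(values[, j], 1), name = paste0("v", j))))
}

# uniform-presence sample over a grid, independent of all covariates
uniform_presences <- function(grid, n, seed) {
  cells <- firemaxent:::with_seed(seed, sample(which(grid$mask), n,
                                               replace = TRUE))
  presence_sample(row = (cells - 1L) %% grid$n_rows + 1L,
                  col = (cells - 1L) %/% grid$n_rows + 1L,
                  year = 2005L, month = 8L)
}

# small landscape for fast end-to-end tests
small_config <- function(seed, n = 60L, ...) {
  landscape_config(n_rows = n, n_cols = n, seed = seed, ...)
}

test_auc_of <- function(model, stack, test) {
  cells <- firemaxent:::presence_cells(test, stack$grid)
  auc(firemaxent:::model_scores(model, stack, cells),
      firemaxent:::model_scores(model, stack, model$background))
}
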