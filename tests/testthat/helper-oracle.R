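# Independent restricted log-likelihood evaluator and grid-search
# maximizer.  Coded from the definition (eigenvalue PD check, dense
# solve, generic determinant) without calling any package internals, so
# it shares no code path with the package's chol-based AI-REML fitter.

# The feasible parameter set mirrors the model definition used by the
# fitter: the residual variance function stays above tau_floor * var(y)
# at every observed covariate value, and every conditional variance
# (squared Cholesky pivot of V) stays above half that floor.  Only the
# feasibility test reuses a Cholesky; the likelihood value itself is
# computed by an independent eigen/solve/determinant route.
oracle_logl <- function(theta, K, c_std, y, tau_floor = 0.01) {
  n <- length(y)
  d_floor <- tau_floor * var(y)
  dres <- theta[4] + 2 * theta[5] * c_std + theta[6] * c_std^2
  if (min(dres) < d_floor) return(-Inf)
  V <- theta[1] * K +
    theta[2] * K * outer(c_std, c_std, `+`) +
    theta[3] * K * outer(c_std, c_std) +
    diag(dres, n)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch) || min(diag(ch))^2 < 0.5 * d_floor) return(-Inf)
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) return(-Inf)
  Vinv <- solve(V)
  X <- matrix(1, n, 1)
  XtViX <- crossprod(X, Vinv %*% X)
  P <- Vinv - (Vinv %*% X) %*% solve(XtViX) %*% crossprod(X, Vinv)
  ld <- determinant(V, logarithm = TRUE)$modulus
  -0.5 * as.numeric(ld + log(XtViX) + crossprod(y, P %*% y))
}

# refining grid search over the free parameters of a model spec: each
# round lays a symmetric grid of the current width around the incumbent,
# evaluates every grid point, moves to the best, then halves the width
oracle_grid_search <- function(K, c_std, y, free, width = 1, rounds = 7,
                               points = 5) {
  par_names <- c("sigma2_a0", "sigma_a01", "sigma2_a1",
                 "sigma2_t0", "sigma_t01", "sigma2_t1")
  theta <- setNames(numeric(6), par_names)
  vy <- var(y)
  theta[c("sigma2_a0", "sigma2_t0")] <- vy / 2
  free_idx <- match(free, par_names)
  best <- oracle_logl(theta, K, c_std, y)
  w <- width * vy
  for (r in seq_len(rounds)) {
    offsets <- seq(-w, w, length.out = points)
    cand <- as.matrix(expand.grid(rep(list(offsets), length(free_idx))))
    center <- theta
    for (row in seq_len(nrow(cand))) {
      th <- center
      th[free_idx] <- center[free_idx] + cand[row, ]
      ll <- oracle_logl(th, K, c_std, y)
      if (ll > best) { best <- ll; theta <- th }
    }
    w <- w / 2
  }
  list(logl = best, theta = theta)
}
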