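# Shared fixtures and independent oracles used across the suite.

table1_nd <- function(...) nondimensionalize(table1_params(), ...)

# Figure-style parameters: dimensional replication rate interpreted per
# cell, which is the convention under which virotherapy clears the tumor
# on the reported time scale.
figure_nd <- function(beta_dim = 1e-6, b = 10)
  nondimensionalize(table1_params(beta = beta_dim, b = b),
                    beta_convention = "per-cell")

# Random admissible nondimensional parameter draw with moderate rates
# (keeps equilibria hyperbolic and integration well-conditioned).
rand_nd <- function(viro_dormant = FALSE) {
  p <- nondim_params(
    alpha  = runif(1, 0.2, 1.5),
    beta   = runif(1, 0.2, 1.5),
    delta0 = runif(1, 0.01, 0.5),
    delta1 = runif(1, 0.01, 0.5),
    b      = runif(1, 2, 12),
    gamma  = runif(1, 0.05, 0.8),
    phi    = runif(1, 0.2, 3),
    psi    = runif(1, 1, 6),
    a      = runif(1, 0.5, 2))
  if (viro_dormant && !(p$b * p$beta > p$beta + p$gamma))
    return(rand_nd(viro_dormant))
  p
}

# High-accuracy reference trajectory from an independent stiff solver.
desolve_oracle <- function(rhs, y0, times, p, spec = NULL,
                           tol = 1e-12) {
  out <- deSolve::ode(
    y = y0, times = times,
    func = function(t, y, parms) list(rhs(t, y, p, spec)),
    parms = NULL, method = "lsoda", rtol = tol, atol = tol)
  unname(out[, -1, drop = FALSE])
}

# Exact solution of the scalar test problem x'(t) = -x(t - tau) with
# constant history 1: on (m-1)tau <= t <= m*tau,
#   x(t) = sum_{k=0}^{m} (-1)^k (t - (k-1)tau)^k / k!
dde_exact_linear <- function(t, tau) {
  vapply(t, function(tt) {
    m <- floor(tt / tau) + 1
    s <- 0
    for (k in 0:m) {
      arg <- tt - (k - 1) * tau
      if (arg < 0) break
      s <- s + (-1)^k * arg^k / factorial(k)
    }
    s
  }, numeric(1))
}

# Central-difference Jacobian, independent of the package's internal one.
fd_jacobian <- function(fn, x, eps = 1e-6) {
  n <- length(x)
  f0 <- fn(x)
  J <- matrix(NA_real_, length(f0), n)
  for (j in seq_len(n)) {
    xp <- x; xp[j] <- xp[j] + eps
    xm <- x; xm[j] <- xm[j] - eps
    J[, j] <- (fn(xp) - fn(xm)) / (2 * eps)
  }
  J
}

# Monic characteristic coefficients from the eigen-decomposition
# (oracle for characteristic_polynomial).
eigen_charpoly <- function(J) {
  ev <- eigen(J, only.values = TRUE)$values
  co <- 1
  for (lam in ev) co <- c(co, 0) - lam * c(0, co)
  Re(co)
}
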