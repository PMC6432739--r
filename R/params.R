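#' Dimensional parameter set for the chemovirotherapy model
#'
#' Bundles the dimensional rates of the tumor--virus--drug system:
#' logistic tumor growth toward a carrying capacity, lysis of infected
#' cells, virus replication and clearance, burst size, drug infusion and
#' decay, and drug-induced kill rates for the two tumor compartments.
#'
#' @param K Tumor carrying capacity (cells). Must be positive.
#' @param alpha Intrinsic tumor growth rate (/day).
#' @param beta Virus replication rate (/day per 10^6 cells or virions).
#' @param delta Infected-cell death (lysis) rate (/day). Must be positive:
#'   it is the time scale of the nondimensionalization.
#' @param gamma Virus clearance rate (/day); virus lifespan is `1/gamma`.
#' @param b Virus burst size (virions released per lysed cell). Values
#'   `b <= 1` are accepted with a warning: the tumor-dormant virotherapy
#'   state requires `b > 1`.
#' @param q Drug infusion rate (concentration/day).
#' @param lambda Drug decay rate (/day).
#' @param delta0,delta1 Drug-induced lysis rates of uninfected and
#'   infected tumor cells (/day per unit drug).
#' @param a Infusion shape constant (/day) for the exponential (bolus
#'   decay rate) and sinusoidal (frequency) schedules.
#' @param U0,I0,V0,C0 Initial concentrations (same units as the
#'   respective compartments).
#'
#' @return An object of class `cv_dim_params` (a named list).
#' @seealso [table1_params()], [nondimensionalize()]
#' @export
dim_params <- function(K = 1e6, alpha = 0.206, beta = 0.001,
                       delta = 0.5115, gamma = 0.001, b = 10,
                       q = 5, lambda = 4.16,
                       delta0 = 0.005, delta1 = 0.006, a = 1,
                       U0 = 1e6, I0 = 0, V0 = 1e5, C0 = 0.1) {
  p <- list(K = K, alpha = alpha, beta = beta, delta = delta,
            gamma = gamma, b = b, q = q, lambda = lambda,
            delta0 = delta0, delta1 = delta1, a = a,
            U0 = U0, I0 = I0, V0 = V0, C0 = C0)
  for (nm in names(p)) {
    x <- p[[nm]]
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop("dim_params: '", nm, "' must be a finite numeric scalar")
  }
  rates <- c("alpha", "beta", "gamma", "b", "q", "lambda",
             "delta0", "delta1", "a")
  if (any(unlist(p[rates]) < 0))
    stop("dim_params: all rates must be nonnegative")
  if (K <= 0) stop("dim_params: carrying capacity K must be positive")
  if (delta <= 0) stop("dim_params: infected-cell death rate delta must be positive")
  if (b <= 1)
    warning("burst size b <= 1: the dormant virotherapy state requires b > 1")
  structure(p, class = "cv_dim_params")
}

#' Reference dimensional parameter values
#'
#' The fitted reference parameter set shipped with the package
#' (carrying capacity 10^6 cells, tumor growth 0.206/day, virus
#' replication 0.001, infected-cell lysis 0.5115/day, virus clearance
#' 0.001/day, burst size 10, drug infusion 5/day, drug decay 4.16/day,
#' drug kill rates 0.005 and 0.006).
#'
#' @param ... Overrides passed on to [dim_params()], e.g. `b = 100`.
#' @return A `cv_dim_params` object.
#' @export
table1_params <- function(...) {
  args <- list(K = 1e6, alpha = 0.206, beta = 0.001, delta = 0.5115,
               gamma = 0.001, b = 10, q = 5, lambda = 4.16,
               delta0 = 0.005, delta1 = 0.006)
  over <- list(...)
  args[names(over)] <- over
  do.call(dim_params, args)
}

#' Nondimensionalize a dimensional parameter set
#'
#' Rescales time by the infected-cell death rate (`t_bar = delta * t`),
#' tumor compartments by the carrying capacity `K`, virus by
#' `virus_scale` (default `K`), and drug by `drug_scale`. The resulting
#' dimensionless parameters drive every model variant:
#' \deqn{\bar\alpha=\alpha/\delta,\quad \bar\delta_0=\delta_0 c_s/\delta,
#'   \quad \bar\delta_1=\delta_1 c_s/\delta,\quad \bar b = bK/v_s,\quad
#'   \bar\gamma=\gamma/\delta,\quad \phi=q/(\delta c_s),\quad
#'   \psi=\lambda/\delta,\quad \bar a=a/\delta,}
#' with \eqn{v_s} = `virus_scale` and \eqn{c_s} = `drug_scale`.
#'
#' The virus replication rate carries an ambiguous unit (per day per
#' 10^6 cells or virions). Under the default convention
#' `"per-1e6-cells"` the state variables are taken to be measured in
#' units of 10^6 cells so that \eqn{\bar\beta=\beta/\delta}; under
#' `"per-cell"` the literal rescaling \eqn{\bar\beta=\beta v_s/\delta}
#' is applied. The second convention is the one that makes the
#' dimensional replication rates quoted for the virotherapy experiments
#' (1e-6, 1e-3) produce tumor clearance on the reported time scale.
#'
#' @param dim A `cv_dim_params` object.
#' @param virus_scale Characteristic virus concentration (default `K`).
#' @param drug_scale Characteristic drug concentration. The source
#'   analysis never fixes the dimensional drug scale; the default 1
#'   gives `phi = q/delta`.
#' @param beta_convention `"per-1e6-cells"` (default) or `"per-cell"`;
#'   see Details.
#' @return An object of class `cv_params`: the dimensionless rates plus
#'   `time_unit_days = 1/delta` (days per nondimensional time unit) and
#'   the scale choices used.
#' @examples
#' p <- nondimensionalize(table1_params())
#' p$alpha                    # ~0.4028
#' p$psi                      # ~8.133
#' p$time_unit_days           # ~1.955 days per unit
#' @export
nondimensionalize <- function(dim, virus_scale = dim$K, drug_scale = 1,
                              beta_convention = c("per-1e6-cells", "per-cell")) {
  if (!inherits(dim, "cv_dim_params"))
    stop("nondimensionalize: 'dim' must be a cv_dim_params object")
  beta_convention <- match.arg(beta_convention)
  if (!is.numeric(virus_scale) || virus_scale <= 0 ||
      !is.numeric(drug_scale) || drug_scale <= 0)
    stop("nondimensionalize: scales must be positive")
  if (dim$delta <= 0) stop("nondimensionalize: delta must be positive")
  d <- dim$delta
  beta_nd <- if (beta_convention == "per-cell")
    dim$beta * virus_scale / d else dim$beta / d
  structure(list(
    alpha  = dim$alpha / d,
    beta   = beta_nd,
    delta0 = dim$delta0 * drug_scale / d,
    delta1 = dim$delta1 * drug_scale / d,
    b      = dim$b * dim$K / virus_scale,
    gamma  = dim$gamma / d,
    phi    = dim$q / (d * drug_scale),
    psi    = dim$lambda / d,
    a      = dim$a / d,
    time_unit_days = 1 / d,
    virus_scale = virus_scale,
    drug_scale = drug_scale,
    beta_convention = beta_convention
  ), class = "cv_params")
}

#' Construct a nondimensional parameter set directly
#'
#' Builds a `cv_params` object from already-dimensionless rates, for
#' analyses that work purely on the rescaled system.
#'
#' @param alpha,beta,delta0,delta1,b,gamma,phi,psi,a Dimensionless
#'   rates (all nonnegative; `psi > 0` wherever the drug equation is
#'   active).
#' @param time_unit_days Days per nondimensional time unit (used only
#'   for reporting metrics in days).
#' @return A `cv_params` object.
#' @export
nondim_params <- function(alpha, beta = 0, delta0 = 0, delta1 = 0,
                          b = 0, gamma = 0, phi = 0, psi = 1, a = 1,
                          time_unit_days = NA_real_) {
  vals <- c(alpha = alpha, beta = beta, delta0 = delta0, delta1 = delta1,
            b = b, gamma = gamma, phi = phi, psi = psi, a = a)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("nondim_params: all rates must be finite and nonnegative")
  structure(c(as.list(vals), list(time_unit_days = time_unit_days,
                                  virus_scale = NA_real_,
                                  drug_scale = NA_real_,
                                  beta_convention = NA_character_)),
            class = "cv_params")
}

#' Recover dimensional parameters from a nondimensional set
#'
#' Inverts [nondimensionalize()] given the time scale and the
#' characteristic concentrations, mainly as a consistency check.
#'
#' @param p A `cv_params` object produced by [nondimensionalize()].
#' @param delta Dimensional infected-cell death rate (/day).
#' @param K Carrying capacity.
#' @return A `cv_dim_params` object.
#' @export
redimensionalize <- function(p, delta, K) {
  stopifnot(inherits(p, "cv_params"), delta > 0, K > 0)
  vs <- p$virus_scale
  cs <- p$drug_scale
  if (!is.finite(vs) || !is.finite(cs))
    stop("redimensionalize: parameter set does not carry its scale choices")
  beta_dim <- if (identical(p$beta_convention, "per-cell"))
    p$beta * delta / vs else p$beta * delta
  suppressWarnings(dim_params(
    K = K, alpha = p$alpha * delta, beta = beta_dim, delta = delta,
    gamma = p$gamma * delta, b = p$b * vs / K,
    q = p$phi * delta * cs, lambda = p$psi * delta,
    delta0 = p$delta0 * delta / cs, delta1 = p$delta1 * delta / cs,
    a = p$a * delta))
}

#' @export
print.cv_dim_params <- function(x, ...) {
  cat("Dimensional chemovirotherapy parameters (rates per day):\n")
  flds <- setdiff(names(x), c("U0", "I0", "V0", "C0"))
  print(unlist(x[flds]))
  cat("initial state: U0 =", x$U0, " I0 =", x$I0,
      " V0 =", x$V0, " C0 =", x$C0, "\n")
  invisible(x)
}

#' @export
print.cv_params <- function(x, ...) {
  cat("Nondimensional chemovirotherapy parameters:\n")
  print(unlist(x[c("alpha", "beta", "delta0", "delta1", "b",
                   "gamma", "phi", "psi", "a")]))
  if (is.finite(x$time_unit_days))
    cat(sprintf("1 time unit = %.4f days\n", x$time_unit_days))
  invisible(x)
}
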