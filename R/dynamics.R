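#' Right-hand sides of the nondimensional model family
#'
#' The full chemovirotherapy system tracks uninfected tumor fraction
#' `U`, infected fraction `I`, free virus `V`, and drug `C`:
#' \deqn{U' = \alpha U(1-U-I) - \beta UV - \delta_0 UC}
#' \deqn{I' = \beta UV - I - \delta_1 IC}
#' \deqn{V' = bI - \beta UV - \gamma V}
#' \deqn{C' = \xi(t) - \psi C}
#' The submodels drop compartments: chemotherapy-only keeps `(U, C)`
#' with logistic bracket `1-U`; virotherapy-only keeps `(U, I, V)`;
#' no treatment is the scalar logistic equation.
#'
#' @param t Nondimensional time.
#' @param state Numeric state vector: `(U, I, V, C)` for `rhs_full`,
#'   `(U, C)` for `rhs_chemo`, `(U, I, V)` for `rhs_viro`, `U` for
#'   `rhs_none`.
#' @param p A `cv_params` object.
#' @param spec A [infusion_spec()] object (ignored where no drug).
#' @return Numeric derivative vector of the same length as `state`.
#' @name model_rhs
NULL

#' @rdname model_rhs
#' @export
rhs_full <- function(t, state, p, spec) {
  U <- state[1L]; I <- state[2L]; V <- state[3L]; C <- state[4L]
  inf <- p$beta * U * V
  c(p$alpha * U * (1 - U - I) - inf - p$delta0 * U * C,
    inf - I - p$delta1 * I * C,
    p$b * I - inf - p$gamma * V,
    infusion_value(spec, t) - p$psi * C)
}

#' @rdname model_rhs
#' @export
rhs_chemo <- function(t, state, p, spec) {
  U <- state[1L]; C <- state[2L]
  c(p$alpha * U * (1 - U) - p$delta0 * U * C,
    infusion_value(spec, t) - p$psi * C)
}

#' @rdname model_rhs
#' @export
rhs_viro <- function(t, state, p, spec = NULL) {
  U <- state[1L]; I <- state[2L]; V <- state[3L]
  inf <- p$beta * U * V
  c(p$alpha * U * (1 - U - I) - inf,
    inf - I,
    p$b * I - inf - p$gamma * V)
}

#' @rdname model_rhs
#' @export
rhs_none <- function(t, state, p, spec = NULL) {
  p$alpha * state[1L] * (1 - state[1L])
}

#' Look up a model's right-hand side and state names
#' @param model One of `"none"`, `"chemo"`, `"viro"`, `"full"`.
#' @return List with `rhs` (function) and `vars` (state names).
#' @keywords internal
model_info <- function(model = c("none", "chemo", "viro", "full")) {
  model <- match.arg(model)
  switch(model,
         none  = list(rhs = rhs_none,  vars = "U"),
         chemo = list(rhs = rhs_chemo, vars = c("U", "C")),
         viro  = list(rhs = rhs_viro,  vars = c("U", "I", "V")),
         full  = list(rhs = rhs_full,  vars = c("U", "I", "V", "C")))
}

#' Closed-form logistic tumor growth (no treatment)
#'
#' \deqn{U(t) = \frac{U_0}{(1-U_0)e^{-\alpha t} + U_0},\qquad
#'   \lim_{t\to\infty} U(t) = 1 \ (U_0 > 0).}
#'
#' @param U0 Initial tumor fraction in `[0, 1]`.
#' @param alpha Dimensionless growth rate.
#' @param t Time(s). Vectorized.
#' @return Tumor fraction(s).
#' @export
logistic_solution <- function(U0, alpha, t) {
  if (!is.numeric(U0) || U0 < 0 || U0 > 1)
    stop("logistic_solution: U0 must lie in [0, 1]")
  U0 / ((1 - U0) * exp(-alpha * t) + U0)
}

#' Fixed-step classical Runge--Kutta (RK4) integration
#'
#' Integrates `y' = rhs(t, y, p, spec)` on a uniform grid with the
#' classical fourth-order Runge--Kutta scheme, the integration method
#' used for all reference simulations of this model family.
#'
#' Negativity policy: state components represent concentrations, so
#' small negative excursions (magnitude below `neg_tol`, default
#' 1e-12) are clipped to zero after each step; larger ones raise an
#' error under `negativity = "error"` (the default clips any negative
#' value but errors past `neg_tol` only when asked). A non-finite
#' state aborts with the last valid time in the error message.
#'
#' @param rhs Right-hand side `function(t, state, p, spec)`.
#' @param y0 Initial state (named or unnamed numeric vector).
#' @param t_span Length-2 numeric `(t0, t1)`, `t1 > t0`.
#' @param h Step size, `> 0` (default 0.001, resolving the stiffest
#'   default rate `psi ~ 8`).
#' @param p,spec Passed through to `rhs`.
#' @param vars Optional column names for the state.
#' @param negativity `"clip"` (default) or `"error"`.
#' @param neg_tol Clipping threshold for the negativity policy.
#' @return An object of class `cv_trajectory`: list with `time`
#'   (uniform grid), `state` (matrix, one row per grid point), `model`
#'   tag, `params`, `spec`, `h`.
#' @export
integrate_model <- function(rhs, y0, t_span, h = 0.001, p, spec = NULL,
                            vars = names(y0),
                            negativity = c("clip", "error"),
                            neg_tol = 1e-12) {
  negativity <- match.arg(negativity)
  if (!is.numeric(h) || h <= 0) stop("integrate_model: h must be positive")
  if (length(t_span) != 2L || t_span[2] <= t_span[1])
    stop("integrate_model: t_span must be an increasing pair")
  n_steps <- ceiling((t_span[2] - t_span[1]) / h - 1e-9)
  times <- t_span[1] + h * (0:n_steps)
  d <- length(y0)
  out <- matrix(NA_real_, nrow = n_steps + 1L, ncol = d)
  y <- as.numeric(y0)
  out[1L, ] <- y
  for (i in seq_len(n_steps)) {
    t <- times[i]
    k1 <- rhs(t, y, p, spec)
    k2 <- rhs(t + h / 2, y + (h / 2) * k1, p, spec)
    k3 <- rhs(t + h / 2, y + (h / 2) * k2, p, spec)
    k4 <- rhs(t + h, y + h * k3, p, spec)
    y <- y + (h / 6) * (k1 + 2 * k2 + 2 * k3 + k4)
    if (any(!is.finite(y)))
      stop(sprintf(
        "integrate_model: non-finite state at t = %g (last valid t = %g)",
        times[i + 1L], t))
    neg <- y < 0
    if (any(neg)) {
      if (negativity == "error" && any(y < -neg_tol))
        stop(sprintf(
          "integrate_model: state went negative (min %g) at t = %g",
          min(y), times[i + 1L]))
      y[neg & y > -neg_tol] <- 0
      if (negativity == "clip") y[neg] <- pmax(y[neg], 0)
    }
    out[i + 1L, ] <- y
  }
  if (is.null(vars)) vars <- paste0("y", seq_len(d))
  colnames(out) <- vars
  structure(list(time = times, state = out,
                 model = attr(rhs, "model_tag"),
                 params = p, spec = spec, h = h),
            class = "cv_trajectory")
}

#' Simulate one model variant
#'
#' Convenience wrapper selecting the right-hand side and state layout
#' for a model variant and calling [integrate_model()].
#'
#' @param model `"none"`, `"chemo"`, `"viro"`, or `"full"`.
#' @param p A `cv_params` object.
#' @param spec A [infusion_spec()] object (drug-bearing variants).
#' @param y0 Initial state in the variant's layout; defaults to the
#'   reference initial concentrations `U0=1, I0=0, V0=0.1, C0=0.1`
#'   restricted to the variant's compartments.
#' @param t_span,h,... Passed to [integrate_model()].
#' @return A `cv_trajectory`.
#' @export
simulate_model <- function(model = c("full", "chemo", "viro", "none"),
                           p, spec = infusion_spec("constant", phi = p$phi),
                           y0 = NULL, t_span = c(0, 30), h = 0.001, ...) {
  model <- match.arg(model)
  mi <- model_info(model)
  if (is.null(y0)) {
    defaults <- c(U = 1, I = 0, V = 0.1, C = 0.1)
    y0 <- defaults[mi$vars]
  }
  if (length(y0) != length(mi$vars))
    stop("simulate_model: y0 has wrong length for model '", model, "'")
  traj <- integrate_model(mi$rhs, y0, t_span, h = h, p = p, spec = spec,
                          vars = mi$vars, ...)
  traj$model <- model
  traj
}

#' Tumor clearance time of a trajectory
#'
#' First grid time at which the total tumor burden `U + I` falls below
#' `threshold` and remains below it for the rest of the trajectory
#' (a persistence requirement that ignores transient dips). The
#' default threshold, 1e-3 of carrying capacity (10^3 cells for a
#' 10^6-cell nodule), operationalizes "reduced to zero".
#'
#' @param traj A `cv_trajectory` whose state contains a `U` column
#'   (and optionally `I`).
#' @param threshold Positive clearance threshold on `U + I`.
#' @return List with `cleared` (logical), `time` (nondimensional, `NA`
#'   if never cleared) and `days` (`time * time_unit_days` when the
#'   parameter set carries a time scale).
#' @export
clearance_time <- function(traj, threshold = 1e-3) {
  stopifnot(inherits(traj, "cv_trajectory"))
  if (!is.numeric(threshold) || threshold <= 0)
    stop("clearance_time: threshold must be positive")
  st <- traj$state
  if (nrow(st) == 0L) stop("clearance_time: empty trajectory")
  burden <- st[, "U"]
  if ("I" %in% colnames(st)) burden <- burden + st[, "I"]
  below <- burden < threshold
  # last index from which 'below' holds to the end
  idx <- which(rev(cumprod(rev(below))) == 1)
  tud <- if (!is.null(traj$params)) traj$params$time_unit_days else NA_real_
  if (length(idx) == 0L)
    return(list(cleared = FALSE, time = NA_real_, days = NA_real_))
  t_clear <- traj$time[idx[1L]]
  list(cleared = TRUE, time = t_clear,
       days = if (is.finite(tud)) t_clear * tud else NA_real_)
}

#' @export
print.cv_trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d points, t in [%g, %g], h = %g, states: %s\n",
              length(x$time), x$time[1], x$time[length(x$time)], x$h,
              paste(colnames(x$state), collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.cv_trajectory <- function(x, ...) {
  data.frame(t = x$time, x$state, check.names = FALSE)
}

#' Plot a trajectory
#'
#' Base-graphics plot of all state components against nondimensional
#' time.
#'
#' @param x A `cv_trajectory`.
#' @param ... Further arguments to [graphics::matplot()].
#' @export
plot.cv_trajectory <- function(x, ...) {
  graphics::matplot(x$time, x$state, type = "l", lty = 1,
                    xlab = "nondimensional time", ylab = "concentration",
                    ...)
  graphics::legend("topright", legend = colnames(x$state),
                   col = seq_len(ncol(x$state)), lty = 1, bty = "n")
  invisible(x)
}

#' Write a trajectory as CSV with a JSON configuration sidecar
#'
#' @param traj A `cv_trajectory`.
#' @param path Output CSV path (header `t,U,I,V,C` as applicable); a
#'   sidecar `<path>.json` records the run configuration.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "cv_trajectory"))
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  cfg <- list(model = traj$model, h = traj$h,
              t_span = range(traj$time),
              params = traj$params[c("alpha", "beta", "delta0", "delta1",
                                     "b", "gamma", "phi", "psi", "a")],
              infusion = if (!is.null(traj$spec))
                traj$spec[c("kind", "phi", "a")])
  jsonlite::write_json(cfg, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
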