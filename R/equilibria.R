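#' Steady-state object
#'
#' Internal constructor for a catalogued equilibrium.
#' @keywords internal
steady_state <- function(coords, label, model, schedule,
                         exists = TRUE, condition = "always",
                         provenance = "closed-form", residual = NA_real_) {
  structure(list(coords = coords, label = label, model = model,
                 schedule = schedule, exists = exists,
                 condition = condition, provenance = provenance,
                 residual = residual),
            class = "cv_steady_state")
}

#' Autonomized right-hand side at frozen forcing
#'
#' Builds the residual function used to verify equilibria. For the
#' constant schedule (and `"none"`) this is the model right-hand side
#' itself. For the exponential schedule the infusion is autonomized as
#' an extra state `W = phi * exp(-a t)` with `W' = -aW` and the drug
#' equation driven by `W`. For the sinusoidal schedule the analogous
#' substitution `W = phi * sin^2(at)` is non-smooth and is used only to
#' catalogue equilibria: `W` enters as a frozen forcing level (`W'`
#' identically 0 in the residual), and stability is assessed on the
#' drug-bearing core at that forcing level.
#'
#' @param model `"chemo"`, `"viro"`, `"full"`, or `"none"`.
#' @param p A `cv_params` object.
#' @param spec A [infusion_spec()] object (or `NULL` for `viro`/`none`).
#' @return List with `fn` (`function(x)` returning the derivative
#'   vector) and `vars` (state names, including `"W"` where
#'   autonomized).
#' @export
autonomized_rhs <- function(model, p, spec = NULL) {
  mi <- model_info(model)
  kind <- if (is.null(spec)) "none" else spec$kind
  if (model %in% c("viro", "none") || kind %in% c("none", "constant")) {
    sp <- if (is.null(spec)) infusion_spec("none") else spec
    return(list(fn = function(x) mi$rhs(0, x, p, sp), vars = mi$vars))
  }
  nc <- length(mi$vars)          # core dimension; drug is last core var
  a <- spec$a
  wprime <- if (kind == "exponential") function(W) -a * W else function(W) 0
  fn <- function(x) {
    W <- x[nc + 1L]
    sp <- infusion_spec("constant", phi = W)
    c(mi$rhs(0, x[seq_len(nc)], p, sp), wprime(W))
  }
  list(fn = fn, vars = c(mi$vars, "W"))
}

#' Damped-Newton refinement of a steady-state candidate
#'
#' Polishes a closed-form candidate against the (autonomized) model
#' right-hand side by damped Newton iteration with a finite-difference
#' Jacobian, guarding against transcription errors in printed
#' formulas: refinement that moves any coordinate by more than 10%
#' (relative to `max(1e-6, |coordinate|)`) raises an error.
#'
#' @param state A `cv_steady_state`.
#' @param fn Residual function `function(x) -> derivative vector`
#'   (e.g. from [autonomized_rhs()]).
#' @param tol Residual infinity-norm target (default 1e-12).
#' @param max_iter Newton iteration cap.
#' @return The refined `cv_steady_state` with updated `residual` and
#'   `provenance = "numeric-refined"` (unchanged provenance if the
#'   candidate was already exact to `tol`).
#' @export
refine_steady_state <- function(state, fn, tol = 1e-12, max_iter = 50L) {
  stopifnot(inherits(state, "cv_steady_state"))
  x0 <- state$coords
  x <- as.numeric(x0)
  r <- fn(x)
  if (max(abs(r)) <= tol) {
    state$residual <- max(abs(r))
    return(state)
  }
  for (it in seq_len(max_iter)) {
    J <- numeric_jacobian(fn, x)
    step <- tryCatch(solve(J, -r), error = function(e) NULL)
    if (is.null(step))
      stop("refine_steady_state: singular Jacobian during refinement")
    lam <- 1
    repeat {
      xn <- x + lam * step
      rn <- fn(xn)
      if (all(is.finite(rn)) && max(abs(rn)) < max(abs(r))) break
      lam <- lam / 2
      if (lam < 1e-8)
        stop("refine_steady_state: refinement diverged (no descent)")
    }
    x <- xn; r <- rn
    if (max(abs(r)) <= tol) break
  }
  if (max(abs(r)) > 1e-9)
    stop(sprintf(
      "refine_steady_state: residual %.3g did not reach tolerance", max(abs(r))))
  move <- abs(x - as.numeric(x0)) / pmax(1e-6, abs(as.numeric(x0)))
  if (any(move > 0.10))
    stop(sprintf(
      paste0("refine_steady_state: coordinate '%s' moved %.1f%% - the ",
             "closed-form candidate looks wrong"),
      names(x0)[which.max(move)], 100 * max(move)))
  state$coords[] <- x
  state$residual <- max(abs(r))
  state$provenance <- "numeric-refined"
  state
}

#' Finite-difference Jacobian (central differences)
#' @keywords internal
numeric_jacobian <- function(fn, x, eps = 1e-7) {
  n <- length(x)
  f0 <- fn(x)
  J <- matrix(NA_real_, length(f0), n)
  for (j in seq_len(n)) {
    hj <- eps * max(1, abs(x[j]))
    xp <- x; xp[j] <- xp[j] + hj
    xm <- x; xm[j] <- xm[j] - hj
    J[, j] <- (fn(xp) - fn(xm)) / (2 * hj)
  }
  J
}

with_residual <- function(st, fn, refine = TRUE) {
  r <- fn(as.numeric(st$coords))
  st$residual <- max(abs(r))
  if (refine && st$exists && st$residual > 1e-12)
    st <- refine_steady_state(st, fn)
  st
}

#' Steady states of the chemotherapy-only model
#'
#' Catalogue of equilibria of the planar `(U, C)` system for each
#' schedule. Constant infusion: the tumor-free state `(0, phi/psi)`
#' and the tumor-dormant state `(1 - delta0*phi/(alpha*psi), phi/psi)`
#' (the drug coordinate follows from `C' = phi - psi C = 0`; a printed
#' `C = 0` there cannot be stationary for `phi > 0`). Exponential and
#' sinusoidal schedules are catalogued on the autonomized `(U, C, W)`
#' system; states printed with a nonzero drug level at `W = 0` are
#' corrected to `C = 0` (noted in the condition string).
#'
#' @param p A `cv_params` object.
#' @param spec A [infusion_spec()] object.
#' @return List of `cv_steady_state` objects, residual-verified (and
#'   numerically refined where nontrivial).
#' @export
equilibria_chemo <- function(p, spec) {
  stopifnot(inherits(p, "cv_params"), inherits(spec, "cv_infusion"))
  ar <- autonomized_rhs("chemo", p, spec)
  phi <- spec$phi; a <- spec$a
  al <- p$alpha; d0 <- p$delta0; psi <- p$psi
  mk <- function(coords, ...) {
    st <- steady_state(stats::setNames(coords, ar$vars), ...,
                       model = "chemo", schedule = spec$kind)
    with_residual(st, ar$fn)
  }
  switch(spec$kind,
    none = ,
    constant = {
      if (spec$kind == "none") phi <- 0
      Ud <- 1 - d0 * phi / (al * psi)
      list(
        mk(c(0, phi / psi), label = "tumor-free"),
        mk(c(max(Ud, 0), phi / psi), label = "tumor-dormant",
           exists = Ud >= 0,
           condition = "alpha*psi >= delta0*phi (U* >= 0)"))
    },
    exponential = list(
      mk(c(0, 0, 0), label = "tumor-free"),
      mk(c(1, 0, 0), label = "carrying-capacity")),
    sinusoidal = {
      Ce <- phi / (a * psi); We <- phi / a
      Ud <- 1 - d0 * phi / (a * al * psi)
      list(
        mk(c(0, 0, 0), label = "tumor-free"),
        mk(c(1, 0, 0), label = "carrying-capacity",
           condition = "printed drug level 1 corrected to 0 (W=0 forces C=0)"),
        mk(c(0, Ce, We), label = "tumor-free-drug"),
        mk(c(max(Ud, 0), Ce, We), label = "tumor-dormant",
           exists = Ud >= 0,
           condition = "a*alpha*psi >= delta0*phi (U* >= 0)"))
    })
}

#' Steady states of the virotherapy-only model
#'
#' The `(U, I, V)` system has the extinction state `(0,0,0)`, the
#' infection-free carrying-capacity state `(1,0,0)`, and - when
#' `b > 1` and `b*beta > beta + gamma` - a tumor-dormant state with
#' \deqn{U^* = \frac{\gamma}{\beta(b-1)},\quad
#'   I^* = \frac{\alpha U^*(1-U^*)}{1+\alpha U^*},\quad
#'   V^* = \frac{\alpha(1-U^*-I^*)}{\beta}.}
#' `U*` is decreasing in both the replication rate and the burst size:
#' aggressive viruses push the dormant tumor load toward zero.
#'
#' @param p A `cv_params` object.
#' @return List of `cv_steady_state` objects.
#' @export
equilibria_viro <- function(p) {
  stopifnot(inherits(p, "cv_params"))
  ar <- autonomized_rhs("viro", p)
  mk <- function(coords, ...) {
    st <- steady_state(stats::setNames(coords, ar$vars), ...,
                       model = "viro", schedule = "none")
    with_residual(st, ar$fn)
  }
  out <- list(
    mk(c(0, 0, 0), label = "tumor-free"),
    mk(c(1, 0, 0), label = "infected-tumor-free"))
  ok <- p$b > 1 && p$b * p$beta > p$beta + p$gamma
  dorm <- viro_dormant_coords(p)
  out[[3L]] <- mk(dorm, label = "tumor-dormant", exists = ok,
                  condition = "b > 1 and b*beta > beta + gamma")
  out
}

viro_dormant_coords <- function(p) {
  U <- if (p$b > 1 && p$beta > 0) p$gamma / (p$beta * (p$b - 1)) else NA_real_
  if (!is.finite(U)) return(c(NA_real_, NA_real_, NA_real_))
  I <- p$alpha * U * (1 - U) / (1 + p$alpha * U)
  V <- if (p$beta > 0) p$alpha * (1 - U - I) / p$beta else NA_real_
  c(U, I, V)
}

# Tumor-dormant coordinates of the full model at constant effective
# drug level Ceff (= phi/psi for constant infusion, phi/(a*psi) for the
# sinusoidal autonomization). Derived from the stationarity conditions:
#   beta*U*V = I*(1 + delta1*Ceff)
#   b*I = I*(1 + delta1*Ceff) + gamma*V
#   alpha*(1-U-I) = beta*V + delta0*Ceff
full_dormant_coords <- function(p, Ceff) {
  E <- 1 + p$delta1 * Ceff
  den <- p$beta * (p$b - E)
  U <- if (den > 0) p$gamma * E / den else NA_real_
  if (!is.finite(U) || U <= 0)
    return(list(coords = c(NA, NA, NA), exists = FALSE))
  I <- (p$alpha * (1 - U) - p$delta0 * Ceff) / (p$alpha + E / U)
  V <- I * E / (p$beta * U)
  list(coords = c(U, I, V),
       exists = is.finite(I) && I > 0 && U < 1)
}

#' Steady states of the full chemovirotherapy model
#'
#' Catalogue for the four-compartment system under each schedule.
#' Constant infusion: tumor-free `(0,0,0,phi/psi)`, infected-tumor-free
#' `(1 - delta0*phi/(alpha*psi), 0, 0, phi/psi)`, and a tumor-dormant
#' state (closed form derived from the stationarity conditions and then
#' numerically refined). Exponential infusion is catalogued on the
#' autonomized five-state system (`W' = -aW`): the infusion dies out,
#' leaving the virotherapy-only catalogue with `C = W = 0`. Sinusoidal
#' infusion (frozen-forcing autonomization) carries six states,
#' including drug-bearing analogues with effective forcing `W* = phi/a`
#' and drug level `phi/(a*psi)`.
#'
#' With `phi = 0` every drug-bearing state collapses onto the
#' virotherapy-only catalogue with `C* = 0`.
#'
#' @param p A `cv_params` object.
#' @param spec A [infusion_spec()] object.
#' @return List of `cv_steady_state` objects.
#' @export
equilibria_full <- function(p, spec) {
  stopifnot(inherits(p, "cv_params"), inherits(spec, "cv_infusion"))
  ar <- autonomized_rhs("full", p, spec)
  phi <- spec$phi; a <- spec$a
  al <- p$alpha; d0 <- p$delta0; psi <- p$psi
  mk <- function(coords, ...) {
    st <- steady_state(stats::setNames(coords, ar$vars), ...,
                       model = "full", schedule = spec$kind)
    with_residual(st, ar$fn)
  }
  switch(spec$kind,
    none = ,
    constant = {
      if (spec$kind == "none") phi <- 0
      Cs <- phi / psi
      Uitf <- 1 - d0 * phi / (al * psi)
      dorm <- full_dormant_coords(p, Cs)
      list(
        mk(c(0, 0, 0, Cs), label = "tumor-free"),
        mk(c(max(Uitf, 0), 0, 0, Cs), label = "infected-tumor-free",
           exists = Uitf >= 0,
           condition = "alpha*psi >= delta0*phi (U* >= 0)"),
        mk(c(if (dorm$exists) dorm$coords else c(0, 0, 0), Cs),
           label = "tumor-dormant", exists = dorm$exists,
           condition = "psi*(b-1) > delta1*phi and alpha*(1-U*) > delta0*phi/psi"))
    },
    exponential = {
      dorm <- viro_dormant_coords(p)
      ok <- p$b > 1 && p$b * p$beta > p$beta + p$gamma
      list(
        mk(c(0, 0, 0, 0, 0), label = "tumor-free"),
        mk(c(1, 0, 0, 0, 0), label = "infected-tumor-free"),
        mk(c(if (ok) dorm else c(0, 0, 0), 0, 0), label = "drug-free-dormant",
           exists = ok, condition = "b > 1 and b*beta > beta + gamma"))
    },
    sinusoidal = {
      Ce <- phi / (a * psi); We <- phi / a
      Uitf <- 1 - d0 * phi / (a * al * psi)
      dormv <- viro_dormant_coords(p)
      okv <- p$b > 1 && p$b * p$beta > p$beta + p$gamma
      dorm <- full_dormant_coords(p, Ce)
      list(
        mk(c(0, 0, 0, 0, 0), label = "tumor-free"),
        mk(c(1, 0, 0, 0, 0), label = "infected-tumor-free",
           condition = "printed drug level 1 corrected to 0 (W=0 forces C=0)"),
        mk(c(0, 0, 0, Ce, We), label = "tumor-free-drug"),
        mk(c(max(Uitf, 0), 0, 0, Ce, We), label = "infected-tumor-free-drug",
           exists = Uitf >= 0,
           condition = "a*alpha*psi >= delta0*phi (U* >= 0)"),
        mk(c(if (okv) dormv else c(0, 0, 0), 0, 0), label = "drug-free-dormant",
           exists = okv, condition = "b > 1 and b*beta > beta + gamma"),
        mk(c(if (dorm$exists) dorm$coords else c(0, 0, 0), Ce, We),
           label = "tumor-dormant", exists = dorm$exists,
           condition = "dormant coordinates positive at effective drug phi/(a*psi)"))
    })
}

#' Catalogue equilibria for any model variant
#'
#' @param model `"chemo"`, `"viro"`, or `"full"`.
#' @param p A `cv_params` object.
#' @param spec A [infusion_spec()] object (ignored for `"viro"`).
#' @return List of `cv_steady_state` objects.
#' @export
equilibria <- function(model = c("full", "chemo", "viro"), p,
                       spec = infusion_spec("constant", phi = p$phi)) {
  model <- match.arg(model)
  switch(model,
         chemo = equilibria_chemo(p, spec),
         viro  = equilibria_viro(p),
         full  = equilibria_full(p, spec))
}

#' @export
print.cv_steady_state <- function(x, ...) {
  cat(sprintf("<%s / %s> %s%s\n", x$model, x$schedule, x$label,
              if (x$exists) "" else "  (does not exist at these parameters)"))
  print(round(x$coords, 6))
  cat(sprintf("  condition: %s | residual: %.2e | %s\n",
              x$condition, x$residual, x$provenance))
  invisible(x)
}

#' Serialize an equilibrium catalogue to a JSON-ready list
#' @param states List of `cv_steady_state` objects.
#' @return A list suitable for `jsonlite::write_json`.
#' @export
equilibria_report <- function(states) {
  lapply(states, function(s)
    list(model = s$model, schedule = s$schedule, label = s$label,
         coordinates = as.list(s$coords), exists = s$exists,
         condition = s$condition, residual = s$residual,
         provenance = s$provenance))
}
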