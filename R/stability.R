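#' Analytic Jacobian of a model variant
#'
#' Jacobian of the (frozen-forcing) right-hand side with respect to
#' the state. The infusion term enters no state derivative, so the
#' same matrix serves every schedule at a given drug level; the
#' autonomized exponential system appends the infusion state `W`
#' (`dW'/dW = -a`, `dC'/dW = 1`).
#'
#' @param model `"none"`, `"chemo"`, `"viro"`, or `"full"`.
#' @param state State vector in the variant's layout (append `W` with
#'   `autonomized = TRUE`).
#' @param p A `cv_params` object.
#' @param autonomized If `TRUE`, return the augmented matrix of the
#'   exponential-infusion autonomization.
#' @return A square matrix with row/column names.
#' @export
model_jacobian <- function(model, state, p, autonomized = FALSE) {
  mi <- model_info(model)
  s <- as.numeric(state)
  al <- p$alpha
  J <- switch(model,
    none = matrix(al * (1 - 2 * s[1L]), 1, 1),
    chemo = {
      U <- s[1L]; C <- s[2L]
      matrix(c(al * (1 - 2 * U) - p$delta0 * C, -p$delta0 * U,
               0, -p$psi), 2, 2, byrow = TRUE)
    },
    viro = {
      U <- s[1L]; I <- s[2L]; V <- s[3L]
      matrix(c(al * (1 - 2 * U - I) - p$beta * V, -al * U, -p$beta * U,
               p$beta * V, -1, p$beta * U,
               -p$beta * V, p$b, -p$beta * U - p$gamma),
             3, 3, byrow = TRUE)
    },
    full = {
      U <- s[1L]; I <- s[2L]; V <- s[3L]; C <- s[4L]
      matrix(c(
        al * (1 - 2 * U - I) - p$beta * V - p$delta0 * C,
        -al * U, -p$beta * U, -p$delta0 * U,
        p$beta * V, -1 - p$delta1 * C, p$beta * U, -p$delta1 * I,
        -p$beta * V, p$b, -p$beta * U - p$gamma, 0,
        0, 0, 0, -p$psi), 4, 4, byrow = TRUE)
    })
  vars <- mi$vars
  if (autonomized) {
    if (!model %in% c("chemo", "full"))
      stop("model_jacobian: only drug-bearing variants autonomize")
    n <- nrow(J)
    Ja <- rbind(cbind(J, 0), 0)
    Ja[n, n + 1L] <- 1          # dC'/dW
    Ja[n + 1L, n + 1L] <- -p$a  # dW'/dW
    J <- Ja
    vars <- c(vars, "W")
  }
  dimnames(J) <- list(vars, vars)
  J
}

#' Monic characteristic polynomial of a matrix
#'
#' Coefficients of `det(lambda I - J)` in descending degree (leading
#' coefficient 1), computed by the Faddeev--LeVerrier recursion.
#'
#' @param J A square numeric matrix.
#' @return Numeric vector of length `nrow(J) + 1`. For a cubic the
#'   tail entries are the Routh--Hurwitz coefficients
#'   `(a2, a1, a0)`.
#' @export
characteristic_polynomial <- function(J) {
  if (!is.matrix(J) || nrow(J) != ncol(J))
    stop("characteristic_polynomial: J must be a square matrix")
  as.numeric(pracma::charpoly(J))
}

#' Routh--Hurwitz test for a monic cubic
#'
#' For `lambda^3 + a2 lambda^2 + a1 lambda + a0`, all roots have
#' negative real part iff `a0, a1, a2 > 0` and `a1 * a2 > a0`.
#' Equalities within `tol` are reported as `"marginal"`.
#'
#' @param a2,a1,a0 Cubic coefficients (descending, monic implied).
#' @param tol Equality band (default 1e-12).
#' @return `"stable"`, `"unstable"`, or `"marginal"`.
#' @export
routh_hurwitz_cubic <- function(a2, a1, a0, tol = 1e-12) {
  vals <- c(a0, a1, a2, a1 * a2 - a0)
  if (any(abs(vals) <= tol)) return("marginal")
  if (all(vals > 0)) "stable" else "unstable"
}

#' Classify the local stability of an equilibrium
#'
#' Computes the Jacobian spectrum at a catalogued steady state and
#' classifies it as stable (all real parts `< -tol`), unstable (some
#' real part `> tol`), or marginal. The numeric spectrum is the
#' primary verdict; closed-form stability conditions for the state
#' are evaluated alongside it, and for three-dimensional blocks the
#' Routh--Hurwitz test of the characteristic cubic is reported.
#'
#' Schedules: the constant schedule uses the plain model Jacobian.
#' The exponential schedule uses the autonomized matrix (extra
#' eigenvalue `-a`). The sinusoidal schedule is assessed on the
#' drug-bearing core at the frozen forcing level `W*` (the
#' autonomizing substitution is non-smooth, so its `W` direction has
#' no meaningful linearization).
#'
#' @param state A `cv_steady_state` (from the equilibria catalogue).
#' @param p A `cv_params` object.
#' @param spec The [infusion_spec()] the state was catalogued under.
#' @param tol Marginality band on eigenvalue real parts (default 1e-9).
#' @return An object of class `cv_stability`: `eigenvalues` (complex),
#'   `classification`, `char_poly`, `routh_hurwitz` (or `NA`),
#'   `conditions` (named list of evaluated closed-form conditions),
#'   plus the equilibrium reference.
#' @export
classify <- function(state, p, spec = NULL, tol = 1e-9) {
  stopifnot(inherits(state, "cv_steady_state"))
  if (!state$exists)
    stop("classify: state '", state$label,
         "' does not exist at these parameters")
  model <- state$model
  kind <- state$schedule
  coords <- state$coords
  core_n <- length(model_info(model)$vars)
  J <- if (kind == "exponential") {
    model_jacobian(model, coords, p, autonomized = TRUE)
  } else {
    # constant / none / sinusoidal-frozen: core Jacobian at the state
    model_jacobian(model, coords[seq_len(core_n)], p)
  }
  ev <- eigen(J, only.values = TRUE)$values
  ev <- ev[order(-Re(ev))]
  mre <- max(Re(ev))
  cls <- if (mre < -tol) "stable" else if (mre > tol) "unstable" else "marginal"
  cp <- characteristic_polynomial(J)
  rh <- if (nrow(J) == 3L)
    routh_hurwitz_cubic(cp[2L], cp[3L], cp[4L]) else NA_character_
  conds <- stability_conditions(state, p, spec)
  structure(list(state = state, eigenvalues = ev, classification = cls,
                 char_poly = cp, routh_hurwitz = rh, conditions = conds,
                 max_re = mre),
            class = "cv_stability")
}

# Closed-form stability conditions printed for specific states,
# evaluated at the parameters (reported beside the numeric spectrum,
# never in place of it).
stability_conditions <- function(state, p, spec) {
  phi <- if (!is.null(spec)) spec$phi else p$phi
  a <- if (!is.null(spec)) spec$a else p$a
  out <- list()
  key <- paste(state$model, state$schedule, state$label, sep = "/")
  add <- function(desc, val) out[[desc]] <<- val
  if (state$label == "tumor-free" &&
      state$schedule %in% c("constant", "none") &&
      state$model %in% c("chemo", "full"))
    add("delta0*phi > alpha*psi (stability of the tumor-free state)",
        p$delta0 * phi > p$alpha * p$psi)
  if (state$model == "chemo" && state$schedule == "constant" &&
      state$label == "tumor-dormant")
    add("delta0*phi + alpha*psi > 2*delta0*phi*psi^2 (printed dormant condition)",
        p$delta0 * phi + p$alpha * p$psi > 2 * p$delta0 * phi * p$psi^2)
  if (state$model %in% c("viro", "full") &&
      state$label %in% c("infected-tumor-free", "tumor-dormant",
                         "drug-free-dormant"))
    add("b*beta > beta + gamma (virus invades the carrying-capacity state)",
        p$b * p$beta > p$beta + p$gamma)
  if (state$schedule == "sinusoidal" &&
      state$label %in% c("tumor-free-drug"))
    add("delta0*phi > a*alpha*psi and phi < 1 (printed sinusoidal condition)",
        p$delta0 * phi > a * p$alpha * p$psi && phi < 1)
  out
}

#' Dulac weighted divergence for the chemotherapy-only system
#'
#' With weight `g(U, C) = 1/(UC)` the divergence of the weighted
#' constant-infusion field is
#' \deqn{\nabla\cdot(g f) = -\frac{\alpha}{C} - \frac{\phi}{UC^2},}
#' strictly negative on the open positive quadrant, so the planar
#' chemotherapy system admits no periodic orbits there.
#'
#' @param U,C Positive coordinates (vectorized).
#' @param p A `cv_params` object.
#' @param spec A constant [infusion_spec()].
#' @return The weighted divergence (negative on the domain).
#' @export
dulac_divergence <- function(U, C, p, spec) {
  stopifnot(inherits(spec, "cv_infusion"))
  if (spec$kind != "constant")
    stop("dulac_divergence: defined for the constant schedule")
  if (any(U <= 0) || any(C <= 0))
    stop("dulac_divergence: U and C must be positive")
  -p$alpha / C - spec$phi / (U * C^2)
}

#' Check a stability verdict by perturbation simulation
#'
#' Perturbs the equilibrium by `eps` in random directions (projected
#' onto the nonnegative orthant), integrates the frozen-forcing model,
#' and checks that trajectories contract toward a stable state and
#' depart from an unstable one. Near-marginal equilibria
#' (`|max Re lambda| <= 1e-6`) are skipped with a message.
#'
#' @param report A `cv_stability` from [classify()].
#' @param p A `cv_params` object.
#' @param spec The schedule the state was catalogued under.
#' @param eps Perturbation size (default 1e-4).
#' @param n_dir Number of random directions (default 3; uses the
#'   current RNG stream).
#' @param t_chunk,t_max,h Integration controls.
#' @return List with `agrees` (logical, `NA` if skipped) and `detail`.
#' @export
verify_by_simulation <- function(report, p, spec = NULL, eps = 1e-4,
                                 n_dir = 3L, t_chunk = 10, t_max = 200,
                                 h = 0.02) {
  stopifnot(inherits(report, "cv_stability"))
  if (abs(report$max_re) <= 1e-6) {
    message("verify_by_simulation: near-marginal equilibrium, skipped")
    return(list(agrees = NA, detail = "skipped: |max Re| <= 1e-6"))
  }
  st <- report$state
  model <- st$model
  core_n <- length(model_info(model)$vars)
  x_star <- as.numeric(st$coords)[seq_len(core_n)]
  # frozen forcing level for the drug equation
  frozen <- if (is.null(spec) || st$schedule %in% c("none")) {
    infusion_spec("none")
  } else if (st$schedule == "constant") {
    spec
  } else {
    W <- if (length(st$coords) > core_n) st$coords[[core_n + 1L]] else 0
    infusion_spec("constant", phi = W)
  }
  mi <- model_info(model)
  stable <- report$classification == "stable"
  escape_radius <- max(1000 * eps, 0.1 * (1 + sqrt(sum(x_star^2))))
  returns_to <- function(y0) {
    dist0 <- sqrt(sum((y0 - x_star)^2))
    if (dist0 == 0) return(NA)
    t0 <- 0; y <- y0
    ts <- numeric(0); ds <- numeric(0)
    while (t0 < t_max) {
      traj <- integrate_model(mi$rhs, y, c(t0, t0 + t_chunk), h = h,
                              p = p, spec = frozen, vars = mi$vars)
      y <- traj$state[nrow(traj$state), ]
      t0 <- t0 + t_chunk
      d <- sqrt(sum((y - x_star)^2))
      if (d > escape_radius) return(FALSE)  # departed for good
      if (d < 0.02 * dist0) return(TRUE)    # contracted back
      ts <- c(ts, t0); ds <- c(ds, d)
    }
    # asymptotic trend: sign of the fitted exponential rate over the
    # second half of the horizon (robust to non-normal transients and
    # to spiral oscillation)
    tail_idx <- ts >= t_max / 2 & ds > 0
    if (sum(tail_idx) >= 3) {
      rate <- stats::coef(stats::lm(log(ds[tail_idx]) ~ ts[tail_idx]))[2]
      return(unname(rate) < 0)
    }
    sqrt(sum((y - x_star)^2)) < dist0
  }
  if (stable) {
    # every admissible perturbation direction must contract back
    ok <- logical(n_dir)
    for (k in seq_len(n_dir)) {
      dir <- stats::rnorm(core_n)
      y0 <- pmax(x_star + eps * dir / sqrt(sum(dir^2)), 0)
      r <- returns_to(y0)
      ok[k] <- is.na(r) || isTRUE(r)
    }
    agrees <- all(ok)
    detail <- sprintf("%d/%d directions contract back", sum(ok), n_dir)
  } else {
    # perturb along the unstable eigendirection (random directions can
    # land in the stable manifold, e.g. on an invariant boundary face)
    Jc <- model_jacobian(model, x_star, p)
    ed <- eigen(Jc)
    v <- Re(ed$vectors[, which.max(Re(ed$values))])
    v <- v / sqrt(sum(v^2))
    departed <- FALSE
    for (sgn in c(1, -1)) {
      y0 <- pmax(x_star + sgn * eps * v, 0)
      if (sqrt(sum((y0 - x_star)^2)) < eps / 2) next  # clipped away
      if (isFALSE(returns_to(y0))) { departed <- TRUE; break }
    }
    agrees <- departed
    detail <- if (departed) "departure detected along unstable direction"
              else "no departure detected"
  }
  list(agrees = agrees, detail = detail)
}

#' @export
print.cv_stability <- function(x, ...) {
  cat(sprintf("Stability of <%s / %s> %s: %s\n", x$state$model,
              x$state$schedule, x$state$label, x$classification))
  cat("  eigenvalues:",
      paste(sprintf("%.4g%+.4gi", Re(x$eigenvalues), Im(x$eigenvalues)),
            collapse = ", "), "\n")
  if (!is.na(x$routh_hurwitz))
    cat("  Routh-Hurwitz:", x$routh_hurwitz, "\n")
  for (nm in names(x$conditions))
    cat(sprintf("  condition [%s]: %s\n", nm, x$conditions[[nm]]))
  invisible(x)
}

#' Serialize stability reports to a JSON-ready list
#' @param reports List of `cv_stability` objects.
#' @return A list suitable for `jsonlite::write_json`.
#' @export
stability_report <- function(reports) {
  lapply(reports, function(r)
    list(label = r$state$label, model = r$state$model,
         schedule = r$state$schedule,
         coordinates = as.list(r$state$coords),
         eigenvalues = lapply(r$eigenvalues, function(z)
           list(re = Re(z), im = Im(z))),
         classification = r$classification,
         routh_hurwitz = r$routh_hurwitz,
         conditions = r$conditions))
}
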