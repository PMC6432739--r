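#' Drug infusion schedule
#'
#' The three clinically motivated delivery schedules for the
#' chemotherapeutic drug, as dimensionless forcing functions
#' \eqn{\xi(t)} in the drug equation \eqn{C' = \xi(t) - \psi C}:
#' constant (protracted intravenous infusion, \eqn{\xi=\phi}),
#' exponential (single bolus that decays, \eqn{\xi=\phi e^{-at}}), and
#' sinusoidal (periodic clinic visits, \eqn{\xi=\phi\sin^2(at)}).
#'
#' @param kind One of `"constant"`, `"exponential"`, `"sinusoidal"`,
#'   `"none"` (no drug: forces `xi = 0`).
#' @param phi Dimensionless infusion rate, `>= 0`.
#' @param a Dimensionless shape constant (`> 0` required for the
#'   exponential and sinusoidal schedules; decay rate resp. frequency).
#' @return An object of class `cv_infusion`.
#' @export
infusion_spec <- function(kind = c("constant", "exponential",
                                   "sinusoidal", "none"),
                          phi = 1, a = 1) {
  kind <- match.arg(kind)
  if (!is.numeric(phi) || phi < 0 || !is.finite(phi))
    stop("infusion_spec: phi must be a finite nonnegative number")
  if (kind %in% c("exponential", "sinusoidal") &&
      (!is.numeric(a) || a <= 0 || !is.finite(a)))
    stop("infusion_spec: a must be positive for ", kind, " infusion")
  if (kind == "none") phi <- 0
  structure(list(kind = kind, phi = phi, a = a), class = "cv_infusion")
}

#' Evaluate an infusion schedule
#'
#' @param spec A [infusion_spec()] object.
#' @param t Nondimensional time(s), `>= 0`. Vectorized.
#' @return The infusion rate \eqn{\xi(t)}.
#' @export
infusion_value <- function(spec, t) {
  stopifnot(inherits(spec, "cv_infusion"))
  if (any(t < 0)) stop("infusion_value: t must be nonnegative")
  switch(spec$kind,
         constant    = rep(spec$phi, length(t)),
         exponential = spec$phi * exp(-spec$a * t),
         sinusoidal  = spec$phi * sin(spec$a * t)^2,
         none        = rep(0, length(t)))
}

#' Closed-form drug level under a given schedule
#'
#' Solves the linear drug equation \eqn{C' = \xi(t) - \psi C},
#' \eqn{C(0)=C_0}, exactly for each schedule:
#' \itemize{
#' \item constant: \eqn{C(t) = (C_0-\phi/\psi)e^{-\psi t} + \phi/\psi};
#' \item exponential: \eqn{C(t) = \frac{\phi}{\psi-a}e^{-at}
#'   + (C_0 - \frac{\phi}{\psi-a})e^{-\psi t}}, with the degenerate
#'   limit \eqn{(C_0+\phi t)e^{-\psi t}} when `a == psi`;
#' \item sinusoidal: homogeneous decay plus the particular periodic
#'   response \eqn{C_p(t) = \frac{\phi}{2\psi} -
#'   \frac{\phi}{2}\frac{\psi\cos 2at + 2a\sin 2at}{\psi^2+4a^2}}.
#' }
#' The sinusoidal particular solution is derived directly from the
#' ODE (the printed reference form is typeset-damaged) and is verified
#' against numerical quadrature in the test suite.
#'
#' @param spec A [infusion_spec()] object.
#' @param C0 Initial drug level.
#' @param psi Dimensionless drug decay rate, `> 0`.
#' @param t Nondimensional time(s). Vectorized.
#' @return Drug level(s) `C(t)`; `C(0)` equals `C0` exactly.
#' @export
drug_solution <- function(spec, C0, psi, t) {
  stopifnot(inherits(spec, "cv_infusion"))
  if (!is.numeric(psi) || psi <= 0)
    stop("drug_solution: psi must be positive")
  phi <- spec$phi
  a <- spec$a
  switch(spec$kind,
    none = C0 * exp(-psi * t),
    constant = (C0 - phi / psi) * exp(-psi * t) + phi / psi,
    exponential = {
      if (isTRUE(all.equal(a, psi, tolerance = 1e-12))) {
        (C0 + phi * t) * exp(-psi * t)
      } else {
        cp <- phi / (psi - a)
        cp * exp(-a * t) + (C0 - cp) * exp(-psi * t)
      }
    },
    sinusoidal = {
      den <- psi^2 + 4 * a^2
      part <- phi / (2 * psi) -
        (phi / 2) * (psi * cos(2 * a * t) + 2 * a * sin(2 * a * t)) / den
      part0 <- phi / (2 * psi) - (phi / 2) * psi / den
      part + (C0 - part0) * exp(-psi * t)
    })
}

#' Long-time drug level under a given schedule
#'
#' Describes the attractor of \eqn{C' = \xi(t) - \psi C}: a fixed
#' point \eqn{\phi/\psi} for constant infusion, extinction (0) for the
#' single bolus, and for the sinusoidal schedule a periodic attractor
#' with mean \eqn{\phi/(2\psi)}, amplitude
#' \eqn{\phi/(2\sqrt{\psi^2+4a^2})} and period \eqn{\pi/a} (the
#' pointwise limit asserted in the source analysis does not exist; the
#' orbit-level description is reported instead).
#'
#' @param spec A [infusion_spec()] object.
#' @param psi Dimensionless drug decay rate, `> 0`.
#' @return An object of class `cv_drug_limit` with fields `type`
#'   (`"fixed-point"` or `"periodic"`), `value` (fixed point or mean),
#'   and for the periodic case `amplitude` and `period`.
#' @export
drug_limit <- function(spec, psi) {
  stopifnot(inherits(spec, "cv_infusion"))
  if (!is.numeric(psi) || psi <= 0) stop("drug_limit: psi must be positive")
  out <- switch(spec$kind,
    none = list(type = "fixed-point", value = 0),
    constant = list(type = "fixed-point", value = spec$phi / psi),
    exponential = list(type = "fixed-point", value = 0),
    sinusoidal = list(type = "periodic",
                      value = spec$phi / (2 * psi),
                      amplitude = spec$phi / (2 * sqrt(psi^2 + 4 * spec$a^2)),
                      period = pi / spec$a))
  structure(out, class = "cv_drug_limit")
}

#' @export
print.cv_infusion <- function(x, ...) {
  cat(sprintf("Infusion schedule: %s (phi = %g, a = %g)\n",
              x$kind, x$phi, x$a))
  invisible(x)
}

#' @export
print.cv_drug_limit <- function(x, ...) {
  if (x$type == "fixed-point") {
    cat(sprintf("Drug limit: fixed point C* = %g\n", x$value))
  } else {
    cat(sprintf(
      "Drug limit: periodic attractor, mean %g, amplitude %g, period %g\n",
      x$value, x$amplitude, x$period))
  }
  invisible(x)
}
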