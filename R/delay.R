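#' Delay specification
#'
#' @param tau1 Virus-infection response delay (nondimensional, `>= 0`):
#'   the lag between virus--cell encounter and productive infection.
#' @param tau2 Drug-response delay (nondimensional, `>= 0`): the lag
#'   between drug exposure and cell kill.
#' @return An object of class `cv_delay`.
#' @export
delay_spec <- function(tau1 = 0, tau2 = 0) {
  if (!is.numeric(tau1) || !is.numeric(tau2) || tau1 < 0 || tau2 < 0)
    stop("delay_spec: delays must be nonnegative")
  structure(list(tau1 = tau1, tau2 = tau2), class = "cv_delay")
}

# Delayed right-hand sides. `lag` is a list of state vectors, one per
# delay, evaluated at t - tau_j.
dde_rhs_full <- function(t, y, lag, p, spec) {
  y1 <- lag[[1L]]; y2 <- lag[[2L]]
  infd <- p$beta * y1[1L] * y1[3L]
  c(p$alpha * y[1L] * (1 - y[1L] - y[2L]) - infd -
      p$delta0 * y2[1L] * y2[4L],
    infd - y[2L] - p$delta1 * y2[2L] * y2[4L],
    p$b * y[2L] - infd - p$gamma * y[3L],
    infusion_value(spec, max(t, 0)) - p$psi * y[4L])
}

dde_rhs_chemo <- function(t, y, lag, p, spec) {
  y2 <- lag[[1L]]
  c(p$alpha * y[1L] * (1 - y[1L]) - p$delta0 * y2[1L] * y2[2L],
    infusion_value(spec, max(t, 0)) - p$psi * y[2L])
}

dde_rhs_viro <- function(t, y, lag, p, spec) {
  y1 <- lag[[1L]]
  infd <- p$beta * y1[1L] * y1[3L]
  c(p$alpha * y[1L] * (1 - y[1L] - y[2L]) - infd,
    infd - y[2L],
    p$b * y[2L] - infd - p$gamma * y[3L])
}

#' Method-of-steps RK4 integration of a delay system
#'
#' Integrates `y'(t) = rhs(t, y(t), {y(t - tau_j)}, p, spec)` with a
#' constant history equal to `y0` on `[-max(tau), 0]`. Each classical
#' RK4 stage evaluates the delayed state by cubic Hermite
#' interpolation of the already-computed solution (node values and
#' node derivatives), preserving fourth-order accuracy. The step size
#' is capped at half the smallest positive delay so that delayed
#' arguments never fall inside the step being computed; zero delays
#' are evaluated at the current stage state, so `tau = 0` reproduces
#' the plain RK4 path exactly.
#'
#' @param rhs `function(t, y, lag, p, spec)` where `lag` is a list of
#'   delayed state vectors, one per entry of `delays`.
#' @param y0 Initial state; also the constant history.
#' @param delays Numeric vector of delays `tau_j >= 0`.
#' @param t_span Length-2 increasing numeric vector.
#' @param h Requested step size (reduced to `min(tau>0)/2` if larger).
#' @param p,spec Passed through to `rhs`.
#' @param vars Optional state names.
#' @return A `cv_trajectory`.
#' @export
integrate_dde <- function(rhs, y0, delays, t_span, h = 0.001, p = NULL,
                          spec = NULL, vars = names(y0)) {
  if (length(t_span) != 2L || t_span[2] <= t_span[1])
    stop("integrate_dde: t_span must be an increasing pair")
  if (any(delays < 0)) stop("integrate_dde: delays must be nonnegative")
  pos <- delays[delays > 0]
  if (length(pos) && h > min(pos) / 2) {
    h <- min(pos) / 2
  }
  t0 <- t_span[1]
  n_steps <- ceiling((t_span[2] - t0) / h - 1e-9)
  d <- length(y0)
  Y <- matrix(NA_real_, n_steps + 1L, d)
  Fd <- matrix(NA_real_, n_steps + 1L, d)   # node derivatives
  times <- t0 + h * (0:n_steps)
  y <- as.numeric(y0)
  Y[1L, ] <- y

  # Hermite lookup of the stored solution at time td <= current node
  lookup <- function(td, i_max) {
    if (td <= t0) return(as.numeric(y0))      # constant history
    s <- (td - t0) / h
    i <- min(floor(s), i_max - 1L)
    u <- s - i
    if (u < 1e-13) return(Y[i + 1L, ])
    h00 <- (1 + 2 * u) * (1 - u)^2
    h10 <- u * (1 - u)^2
    h01 <- u^2 * (3 - 2 * u)
    h11 <- u^2 * (u - 1)
    h00 * Y[i + 1L, ] + h10 * h * Fd[i + 1L, ] +
      h01 * Y[i + 2L, ] + h11 * h * Fd[i + 2L, ]
  }

  eval_rhs <- function(t, ystage, i_max) {
    lag <- lapply(delays, function(tau)
      if (tau == 0) ystage else lookup(t - tau, i_max))
    rhs(t, ystage, lag, p, spec)
  }

  Fd[1L, ] <- eval_rhs(t0, y, 0L)
  for (i in seq_len(n_steps)) {
    t <- times[i]
    k1 <- Fd[i, ]
    k2 <- eval_rhs(t + h / 2, y + (h / 2) * k1, i - 1L)
    k3 <- eval_rhs(t + h / 2, y + (h / 2) * k2, i - 1L)
    k4 <- eval_rhs(t + h, y + h * k3, i - 1L)
    y <- y + (h / 6) * (k1 + 2 * k2 + 2 * k3 + k4)
    if (any(!is.finite(y)))
      stop(sprintf("integrate_dde: non-finite state at t = %g", t + h))
    y[y < 0 & y > -1e-12] <- 0
    Y[i + 1L, ] <- y
    Fd[i + 1L, ] <- eval_rhs(t + h, y, i)
  }
  if (is.null(vars)) vars <- paste0("y", seq_len(d))
  colnames(Y) <- vars
  structure(list(time = times, state = Y, model = "dde",
                 params = p, spec = spec, h = h, delays = delays),
            class = "cv_trajectory")
}

#' Simulate a delayed model variant
#'
#' Wrapper over [integrate_dde()] for the delayed chemovirotherapy
#' family: the full four-compartment system (delays `tau1` on the
#' infection term, `tau2` on both drug-kill terms), the
#' chemotherapy-only system (`tau2`), and the virotherapy-only system
#' (`tau1`). The history is constant and equal to the initial state.
#'
#' @param model `"full"`, `"chemo"`, or `"viro"`.
#' @param p A `cv_params` object.
#' @param spec A [infusion_spec()] object.
#' @param delays A [delay_spec()] object.
#' @param y0 Initial state (defaults to `U=1, I=0, V=0.1, C=0.1`
#'   restricted to the variant).
#' @param t_span,h Passed to [integrate_dde()].
#' @return A `cv_trajectory`.
#' @export
simulate_dde <- function(model = c("full", "chemo", "viro"), p,
                         spec = infusion_spec("constant", phi = p$phi),
                         delays = delay_spec(), y0 = NULL,
                         t_span = c(0, 30), h = 0.001) {
  model <- match.arg(model)
  mi <- model_info(model)
  if (is.null(y0)) {
    defaults <- c(U = 1, I = 0, V = 0.1, C = 0.1)
    y0 <- defaults[mi$vars]
  }
  cfg <- switch(model,
    full  = list(rhs = dde_rhs_full,  d = c(delays$tau1, delays$tau2)),
    chemo = list(rhs = dde_rhs_chemo, d = delays$tau2),
    viro  = list(rhs = dde_rhs_viro,  d = delays$tau1))
  traj <- integrate_dde(cfg$rhs, y0, cfg$d, t_span, h = h, p = p,
                        spec = spec, vars = mi$vars)
  traj$model <- paste0(model, "-dde")
  traj
}

#' Transcendental characteristic function, chemotherapy-delay model
#'
#' Linearizing the delayed chemotherapy-only system about its
#' tumor-free state `(0, phi/psi)` gives
#' \deqn{f(\lambda) = (\lambda+\psi)\left(\lambda - \alpha +
#'   e^{-\lambda\tau_2}\,\frac{\delta_0\phi}{\psi}\right) = 0,}
#' with the explicit root `-psi` and, at `tau2 = 0`, the quadratic of
#' the undelayed analysis.
#'
#' @param p A `cv_params` object.
#' @param tau2 Drug-response delay.
#' @param phi Infusion rate (default `p$phi`).
#' @return An object of class `cv_char_function`: `fn(lambda)` (the
#'   full factorized function), `reduced(lambda)` (the nontrivial
#'   factor), `tau`, `model`.
#' @export
char_chemo_delay <- function(p, tau2 = 0, phi = p$phi) {
  k <- p$delta0 * phi / p$psi
  al <- p$alpha; psi <- p$psi
  reduced <- function(lambda) lambda - al + exp(-lambda * tau2) * k
  structure(list(
    fn = function(lambda) (lambda + psi) * reduced(lambda),
    reduced = reduced, tau = tau2, model = "chemo-delay",
    params = list(alpha = al, psi = psi, delta0_phi_over_psi = k)),
    class = "cv_char_function")
}

#' Transcendental characteristic function, virotherapy-delay model
#'
#' Linearizing the delayed virotherapy-only system about the
#' carrying-capacity state `(1, 0, 0)` gives
#' \deqn{f(\lambda) = (\lambda+\alpha)\left[(\lambda+1)
#'   (\lambda+\gamma+\beta e^{-\lambda\tau_1}) -
#'   b\beta e^{-\lambda\tau_1}\right] = 0,}
#' which at `tau1 = 0` reduces to the undelayed cubic
#' `(lambda+alpha)(lambda^2 + (1+beta+gamma) lambda + beta+gamma-b beta)`.
#'
#' @param p A `cv_params` object.
#' @param tau1 Virus-infection delay.
#' @return A `cv_char_function` (fields as in [char_chemo_delay()]).
#' @export
char_viro_delay <- function(p, tau1 = 0) {
  al <- p$alpha; be <- p$beta; ga <- p$gamma; b <- p$b
  reduced <- function(lambda) {
    e <- exp(-lambda * tau1)
    (lambda + 1) * (lambda + ga + be * e) - b * be * e
  }
  structure(list(
    fn = function(lambda) (lambda + al) * reduced(lambda),
    reduced = reduced, tau = tau1, model = "viro-delay",
    params = list(alpha = al, beta = be, gamma = ga, b = b)),
    class = "cv_char_function")
}

#' Hopf-type crossing frequency and critical delays
#'
#' For the tumor-free state of the delayed chemotherapy model, purely
#' imaginary roots `+-i omega` of the nontrivial characteristic factor
#' exist iff `delta0*phi/psi > alpha`, with
#' \deqn{\omega = \sqrt{(\delta_0\phi/\psi)^2 - \alpha^2},\qquad
#'   \tau_{2k} = \frac{\arccos(\alpha\psi/(\delta_0\phi)) + 2k\pi}
#'   {\omega},\quad k = 0, 1, 2, \dots}
#' (the crossing form; each pair `(omega, tau_2k)` is validated by
#' direct substitution). At equality the frequency degenerates to 0
#' and the result is flagged as a boundary case.
#'
#' @param p A `cv_params` object.
#' @param phi Infusion rate (default `p$phi`).
#' @param k_max Number of critical delays to return (k = 0, ...,
#'   `k_max - 1`).
#' @return An object of class `cv_hopf`: `exists`, `boundary`,
#'   `omega`, `tau2k` (numeric vector), `condition`.
#' @export
hopf_frequency <- function(p, phi = p$phi, k_max = 3L) {
  if (p$psi <= 0) stop("hopf_frequency: psi must be positive")
  kk <- p$delta0 * phi / p$psi
  cond <- sprintf("delta0*phi/psi = %.6g vs alpha = %.6g", kk, p$alpha)
  if (kk < p$alpha)
    return(structure(list(exists = FALSE, boundary = FALSE,
                          omega = NA_real_, tau2k = numeric(0),
                          condition = cond), class = "cv_hopf"))
  if (isTRUE(all.equal(kk, p$alpha, tolerance = 1e-12)))
    return(structure(list(exists = FALSE, boundary = TRUE, omega = 0,
                          tau2k = numeric(0), condition = cond),
                     class = "cv_hopf"))
  omega <- sqrt(kk^2 - p$alpha^2)
  ks <- 0:(k_max - 1L)
  tau2k <- (acos(p$alpha / kk) + 2 * pi * ks) / omega
  structure(list(exists = TRUE, boundary = FALSE, omega = omega,
                 tau2k = tau2k, condition = cond), class = "cv_hopf")
}

#' Locate characteristic roots in a complex window
#'
#' Counts zeros of an analytic characteristic function inside a
#' rectangle by the argument principle (adaptive phase tracking along
#' the contour), bisects until each sub-box isolates one root, then
#' polishes with complex Newton iteration. If the contour passes too
#' close to a root the window is jittered slightly with a message.
#'
#' @param cf A `cv_char_function`, or a plain function of one complex
#'   argument.
#' @param re_window,im_window Length-2 real intervals bounding the
#'   search rectangle.
#' @param grid Number of contour samples per box side (default 64).
#' @param tol Residual target `|f(root)|` (default 1e-9).
#' @return Complex vector of roots sorted by decreasing real part.
#' @export
rightmost_root_scan <- function(cf, re_window = c(-10, 5),
                                im_window = c(-25, 25), grid = 64L,
                                tol = 1e-9) {
  f <- if (inherits(cf, "cv_char_function")) cf$fn else cf
  if (!is.function(f)) stop("rightmost_root_scan: need a function")
  if (any(!is.finite(c(re_window, im_window))))
    stop("rightmost_root_scan: windows must be finite")

  fprime <- function(z, hh = 1e-7) (f(z + hh) - f(z - hh)) / (2 * hh)

  newton <- function(z) {
    for (it in 1:100) {
      fz <- f(z)
      if (abs(fz) < tol * 1e-2) return(z)
      dz <- fz / fprime(z)
      if (!is.finite(dz)) return(NA_complex_)
      # damped step to stay well-behaved for transcendental f
      if (abs(dz) > 1) dz <- dz / abs(dz)
      z <- z - dz
    }
    if (abs(f(z)) < tol) z else NA_complex_
  }

  # total argument change of f along the segment z1 -> z2, adaptively
  arg_change <- function(z1, z2, f1, f2, depth = 0L) {
    d <- Arg(f2 / f1)
    if (abs(d) < pi / 2 || depth > 40L) return(d)
    zm <- (z1 + z2) / 2
    fm <- f(zm)
    if (abs(fm) == 0) stop("root-on-contour")
    arg_change(z1, zm, f1, fm, depth + 1L) +
      arg_change(zm, z2, fm, f2, depth + 1L)
  }

  count_zeros <- function(x1, x2, y1, y2, n) {
    corners <- c(complex(real = x1, imaginary = y1),
                 complex(real = x2, imaginary = y1),
                 complex(real = x2, imaginary = y2),
                 complex(real = x1, imaginary = y2))
    pts <- unlist(lapply(1:4, function(i) {
      z1 <- corners[i]; z2 <- corners[if (i == 4) 1 else i + 1]
      z1 + (z2 - z1) * (0:(n - 1)) / n
    }))
    fv <- vapply(pts, f, complex(1))
    scale <- stats::median(abs(fv))
    if (any(abs(fv) < 1e-10 * max(1, scale))) stop("root-on-contour")
    total <- 0
    np <- length(pts)
    for (i in seq_len(np)) {
      j <- if (i == np) 1L else i + 1L
      total <- total + arg_change(pts[i], pts[j], fv[i], fv[j])
    }
    round(total / (2 * pi))
  }

  roots <- complex(0)
  boxes <- list(c(re_window[1], re_window[2], im_window[1], im_window[2]))
  guard <- 0L
  while (length(boxes) && guard < 500L) {
    guard <- guard + 1L
    bx <- boxes[[1L]]; boxes <- boxes[-1L]
    n <- tryCatch(count_zeros(bx[1], bx[2], bx[3], bx[4], grid),
                  error = function(e) {
                    if (conditionMessage(e) == "root-on-contour") -1
                    else stop(e)
                  })
    if (n < 0) {
      message("rightmost_root_scan: contour near a root; jittering window")
      eps <- 1e-4 * max(bx[2] - bx[1], bx[4] - bx[3], 1e-3)
      boxes <- c(boxes, list(bx + c(-eps, eps, -eps * 1.3, eps * 1.3)))
      next
    }
    if (n == 0) next
    small <- (bx[2] - bx[1] < 1e-3) && (bx[4] - bx[3] < 1e-3)
    if (n == 1 || small) {
      z0 <- complex(real = mean(bx[1:2]), imaginary = mean(bx[3:4]))
      z <- newton(z0)
      if (!is.na(z) && abs(f(z)) < tol) {
        roots <- c(roots, z)
      } else if (!small) {
        boxes <- c(boxes, split_box(bx))
      }
    } else {
      boxes <- c(boxes, split_box(bx))
    }
  }
  # dedupe
  if (length(roots) > 1) {
    keep <- rep(TRUE, length(roots))
    for (i in seq_along(roots))
      if (keep[i])
        for (j in seq_along(roots))
          if (j > i && keep[j] && abs(roots[i] - roots[j]) < 1e-6)
            keep[j] <- FALSE
    roots <- roots[keep]
  }
  roots <- roots[Re(roots) >= re_window[1] - 1e-8 &
                 Re(roots) <= re_window[2] + 1e-8 &
                 Im(roots) >= im_window[1] - 1e-8 &
                 Im(roots) <= im_window[2] + 1e-8]
  roots[order(-Re(roots))]
}

split_box <- function(bx) {
  w <- bx[2] - bx[1]; hgt <- bx[4] - bx[3]
  if (w >= hgt) {
    xm <- mean(bx[1:2]) + 1e-9 * w  # asymmetric split avoids axis roots
    list(c(bx[1], xm, bx[3], bx[4]), c(xm, bx[2], bx[3], bx[4]))
  } else {
    ym <- mean(bx[3:4]) + 1e-9 * hgt
    list(c(bx[1], bx[2], bx[3], ym), c(bx[1], bx[2], ym, bx[4]))
  }
}

#' @export
print.cv_hopf <- function(x, ...) {
  if (x$exists) {
    cat(sprintf("Hopf-type crossing: omega = %.6g, tau2k = %s\n",
                x$omega, paste(signif(x$tau2k, 6), collapse = ", ")))
  } else if (isTRUE(x$boundary)) {
    cat("Boundary case: omega = 0 (delta0*phi/psi equals alpha)\n")
  } else {
    cat("No purely imaginary crossing (", x$condition, ")\n")
  }
  invisible(x)
}
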