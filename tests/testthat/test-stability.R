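test_that("analytic Jacobians match finite differences and known entries", {
  p <- nondim_params(alpha = 0.7, beta = 0.5, delta0 = 0.1, delta1 = 0.2,
                     b = 8, gamma = 0.3, phi = 1.2, psi = 4, a = 0.9)
  # logistic slope at capacity
  expect_equal(model_jacobian("none", 1, p)[1, 1], -0.7)
  # drug diagonal at the tumor-free state of the full model
  Jtf <- model_jacobian("full", c(0, 0, 0, p$phi / p$psi), p)
  expect_equal(Jtf["C", "C"], -p$psi)
  sp <- infusion_spec("constant", phi = p$phi)
  set.seed(5)
  for (model in c("none", "chemo", "viro", "full")) {
    mi_vars <- switch(model, none = 1, chemo = 2, viro = 3, full = 4)
    x <- runif(mi_vars, 0.1, 1)
    rhs <- switch(model, none = rhs_none, chemo = rhs_chemo,
                  viro = rhs_viro, full = rhs_full)
    J <- model_jacobian(model, x, p)
    Jfd <- fd_jacobian(function(y) rhs(0, y, p, sp), x)
    expect_lt(max(abs(J - Jfd)), 1e-6)
  }
  # autonomized bolus system appends the infusion state
  Ja <- model_jacobian("full", c(0.2, 0.1, 0.3, 0.4, 0.5), p,
                       autonomized = TRUE)
  expect_equal(dim(Ja), c(5L, 5L))
  expect_equal(Ja["W", "W"], -p$a)
  expect_equal(Ja["C", "W"], 1)
})

test_that("characteristic polynomials are monic and match factorizations", {
  expect_equal(characteristic_polynomial(diag(c(-1, -2))), c(1, 3, 2))
  # virotherapy at carrying capacity factors as
  # (lambda + alpha)(lambda^2 + (1+beta+gamma) lambda + beta+gamma-b beta)
  p <- nondim_params(alpha = 0.4, beta = 0.5, b = 10, gamma = 0.1)
  J <- model_jacobian("viro", c(1, 0, 0), p)
  got <- characteristic_polynomial(J)
  al <- 0.4; be <- 0.5; ga <- 0.1; b <- 10
  quad <- c(1, 1 + be + ga, be + ga - b * be)
  expected <- c(quad, 0) + al * c(0, quad)   # multiply by (lambda + alpha)
  expect_equal(got, expected, tolerance = 1e-12)
  # random matrices: coefficients equal the eigenvalue-product expansion
  set.seed(9)
  for (i in 1:5) {
    A <- matrix(rnorm(9), 3, 3)
    expect_equal(characteristic_polynomial(A), eigen_charpoly(A),
                 tolerance = 1e-8)
  }
})

test_that("Routh-Hurwitz verdict matches the root signs", {
  expect_identical(routh_hurwitz_cubic(6, 11, 6), "stable")
  expect_identical(routh_hurwitz_cubic(1, 1, 2), "unstable")
  expect_identical(routh_hurwitz_cubic(0, 1, 1), "marginal")
  set.seed(13)
  for (i in 1:200) {
    co <- rnorm(3, sd = 2)
    roots <- polyroot(rev(c(1, co)))
    verdict <- routh_hurwitz_cubic(co[1], co[2], co[3])
    mre <- max(Re(roots))
    if (abs(mre) > 1e-9)
      expect_identical(verdict, if (mre < 0) "stable" else "unstable")
  }
})

test_that("closed-form spectra are reproduced at anchor equilibria", {
  p <- table1_nd()
  sp <- infusion_spec("constant", phi = p$phi)
  # chemotherapy tumor-free: quadratic
  # lambda^2 + (psi - alpha + delta0 phi/psi) lambda + (delta0 phi - alpha psi)
  eqc <- equilibria_chemo(p, sp)
  rc <- classify(eqc[[1]], p, sp)
  co <- c(1, p$psi - p$alpha + p$delta0 * p$phi / p$psi,
          p$delta0 * p$phi - p$alpha * p$psi)
  closed <- polyroot(rev(co))
  expect_equal(sort(Re(rc$eigenvalues)), sort(Re(closed)), tolerance = 1e-10)
  expect_identical(rc$classification, "unstable")  # weak drug regime
  # virotherapy extinction state: {alpha, -1, -gamma}
  pv <- nondim_params(alpha = 0.4, beta = 0.5, b = 10, gamma = 0.1)
  rv <- classify(equilibria_viro(pv)[[1]], pv)
  expect_equal(sort(Re(rv$eigenvalues)), sort(c(0.4, -1, -0.1)),
               tolerance = 1e-12)
  expect_identical(rv$classification, "unstable")
  # full model tumor-free under constant infusion: four closed forms
  eqf <- equilibria_full(p, sp)
  rf <- classify(eqf[[1]], p, sp)
  closed4 <- c(p$alpha - p$delta0 * p$phi / p$psi,
               -(1 + p$delta1 * p$phi / p$psi),
               -p$gamma, -p$psi)
  expect_equal(sort(Re(rf$eigenvalues)), sort(closed4), tolerance = 1e-10)
})

test_that("the decoupled drug eigenvalue appears in the dormant spectrum", {
  p <- table1_nd()
  sp <- infusion_spec("constant", phi = p$phi)
  eq <- equilibria_full(p, sp)
  labs <- vapply(eq, `[[`, "", "label")
  r <- classify(eq[[which(labs == "tumor-dormant")]], p, sp)
  drug_ev <- Re(r$eigenvalues[which.min(abs(r$eigenvalues + p$psi))])
  expect_equal(drug_ev, -p$psi, tolerance = 1e-10)
})

test_that("Dulac weighted divergence is negative on the positive quadrant", {
  p <- nondim_params(alpha = 1, phi = 1, psi = 1)
  sp <- infusion_spec("constant", phi = 1)
  expect_equal(dulac_divergence(1, 1, p, sp), -2)
  expect_error(dulac_divergence(0, 1, p, sp), "positive")
  expect_error(dulac_divergence(1, 1, p, infusion_spec("sinusoidal", phi = 1)),
               "constant")
  set.seed(3)
  # matches the finite-difference divergence of the weighted field
  for (i in 1:100) {
    pp <- nondim_params(alpha = runif(1, 0.1, 2), delta0 = runif(1, 0.01, 1),
                        phi = runif(1, 0.1, 3), psi = runif(1, 0.5, 5))
    spp <- infusion_spec("constant", phi = pp$phi)
    U <- runif(1, 0.2, 5); C <- runif(1, 0.2, 5)
    g_f <- function(x) {
      d <- rhs_chemo(0, x, pp, spp)
      d / (x[1] * x[2])
    }
    eps <- 1e-5
    div_fd <- (g_f(c(U + eps, C))[1] - g_f(c(U - eps, C))[1]) / (2 * eps) +
      (g_f(c(U, C + eps))[2] - g_f(c(U, C - eps))[2]) / (2 * eps)
    expect_equal(dulac_divergence(U, C, pp, spp), div_fd, tolerance = 1e-5)
    expect_lt(dulac_divergence(U, C, pp, spp), 0)
  }
})

test_that("perturbation simulations confirm the eigenvalue verdicts", {
  set.seed(17)
  # a stable dormant chemotherapy state
  p <- nondim_params(alpha = 0.5, delta0 = 0.2, phi = 1, psi = 2)
  sp <- infusion_spec("constant", phi = 1)
  eq <- equilibria_chemo(p, sp)
  r <- classify(eq[[2]], p, sp)
  expect_identical(r$classification, "stable")
  expect_true(verify_by_simulation(r, p, sp)$agrees)
  # virus invasion of the carrying-capacity state
  pv <- nondim_params(alpha = 0.4, beta = 0.5, b = 10, gamma = 0.1)
  rv <- classify(equilibria_viro(pv)[[2]], pv)
  expect_identical(rv$classification, "unstable")
  expect_true(verify_by_simulation(rv, pv)$agrees)
  # near-marginal equilibria are skipped, not judged
  pm <- nondim_params(alpha = 0, beta = 0.5, b = 10, gamma = 0.1)
  rm_ <- classify(equilibria_viro(pm)[[1]], pm)
  expect_message(out <- verify_by_simulation(rm_, pm), "skipped")
  expect_true(is.na(out$agrees))
})

test_that("verdicts and simulations agree across random admissible draws", {
  set.seed(29)
  for (i in 1:6) {
    p <- rand_nd()
    sp <- infusion_spec("constant", phi = p$phi)
    states <- Filter(function(s) s$exists,
                     c(equilibria_chemo(p, sp), equilibria_viro(p)))
    for (s in states) {
      r <- classify(s, p, sp)
      if (abs(r$max_re) <= 1e-6) next
      v <- verify_by_simulation(r, p, sp, n_dir = 2L, t_max = 120)
      expect_true(v$agrees,
                  label = sprintf("draw %d %s/%s (%s)", i, s$model,
                                  s$label, r$classification))
    }
  }
})
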