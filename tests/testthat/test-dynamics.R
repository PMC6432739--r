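test_that("right-hand sides vanish (or reduce) at their anchor states", {
  p <- nondim_params(alpha = 0.4, beta = 0.5, delta0 = 0.1, delta1 = 0.2,
                     b = 10, gamma = 0.1, phi = 2, psi = 4)
  spc <- infusion_spec("constant", phi = 2)
  # extinction state: only the infusion acts
  expect_equal(rhs_full(0, c(0, 0, 0, 0), p, spc), c(0, 0, 0, 2))
  # carrying capacity with no drug
  expect_equal(rhs_full(0, c(1, 0, 0, 0), p, infusion_spec("none")),
               c(0, 0, 0, 0))
  # tumor-free state under constant infusion is stationary
  expect_equal(rhs_full(0, c(0, 0, 0, 2 / 4), p, spc), c(0, 0, 0, 0))
  # chemotherapy-only anchors
  expect_equal(rhs_chemo(0, c(0, 2 / 4), p, spc), c(0, 0))
  expect_equal(rhs_chemo(0, c(1, 0), p, infusion_spec("none")), c(0, 0))
  expect_equal(rhs_chemo(0, c(0.5, 0), p, infusion_spec("none")),
               c(0.4 * 0.5 * 0.5, 0))
  # virotherapy-only anchors
  expect_equal(rhs_viro(0, c(1, 0, 0), p), c(0, 0, 0))
  expect_equal(rhs_viro(0, c(0, 0, 3), p), c(0, 0, -0.1 * 3))
  # logistic anchors
  expect_equal(rhs_none(0, 0, p), 0)
  expect_equal(rhs_none(0, 1, p), 0)
  expect_equal(rhs_none(0, 0.5, nondim_params(alpha = 1)), 0.25)
})

test_that("the dormant virotherapy state annihilates the right-hand side", {
  p <- nondim_params(alpha = 0.4, beta = 0.5, b = 10, gamma = 0.1)
  st <- equilibria_viro(p)[[3]]
  expect_true(st$exists)
  expect_lt(max(abs(rhs_viro(0, st$coords, p))), 1e-12)
})

test_that("logistic closed form matches its limits and the integrator", {
  expect_equal(logistic_solution(1, 0.7, c(0, 3, 100)), rep(1, 3))
  expect_equal(logistic_solution(0.37, 1.1, 0), 0.37)
  expect_error(logistic_solution(1.2, 1, 0), "U0")
  al <- 0.206 / 0.5115
  tr <- integrate_model(rhs_none, c(U = 0.1), c(0, 50), h = 0.01,
                        p = nondim_params(alpha = al))
  expect_lt(max(abs(tr$state[, 1] -
                      logistic_solution(0.1, al, tr$time))), 1e-8)
})

test_that("RK4 exhibits fourth-order convergence on the logistic equation", {
  p <- nondim_params(alpha = 1)
  errs <- vapply(c(0.2, 0.1, 0.05), function(h) {
    tr <- integrate_model(rhs_none, c(U = 0.5), c(0, 10), h = h, p = p)
    max(abs(tr$state[, 1] - logistic_solution(0.5, 1, tr$time)))
  }, numeric(1))
  ratios <- errs[-3] / errs[-1]
  expect_true(all(ratios > 12 & ratios < 20))
})

test_that("a zero field yields a constant trajectory and grids are uniform", {
  tr <- integrate_model(function(t, y, p, s) c(0, 0), c(a = 1, b = 2),
                        c(0, 1), h = 0.1, p = NULL)
  expect_true(all(tr$state[, 1] == 1) && all(tr$state[, 2] == 2))
  expect_equal(diff(tr$time), rep(0.1, 10))
  expect_error(integrate_model(rhs_none, c(U = 0.5), c(1, 0), h = 0.1,
                               p = nondim_params(alpha = 1)), "t_span")
  expect_error(integrate_model(rhs_none, c(U = 0.5), c(0, 1), h = 0,
                               p = nondim_params(alpha = 1)), "h must")
})

test_that("integration failure reports the last valid time", {
  expl <- function(t, y, p, s) y^2
  expect_error(integrate_model(expl, c(x = 1), c(0, 5), h = 0.01, p = NULL),
               "non-finite state")
})

test_that("drug column of a chemotherapy run matches the closed form", {
  p <- table1_nd()
  for (kind in c("constant", "exponential", "sinusoidal")) {
    sp <- infusion_spec(kind, phi = p$phi, a = p$a)
    tr <- simulate_model("chemo", p, sp, y0 = c(U = 0.8, C = 0.2),
                         t_span = c(0, 5), h = 0.002)
    expect_lt(max(abs(tr$state[, "C"] -
                        drug_solution(sp, 0.2, p$psi, tr$time))), 1e-8)
  }
})

test_that("clearance time handles degenerate, growing, and decaying burdens", {
  mk_traj <- function(time, U, p = NULL) {
    structure(list(time = time, state = cbind(U = U), params = p,
                   h = diff(time)[1]), class = "cv_trajectory")
  }
  t <- seq(0, 10, by = 0.005)
  expect_equal(clearance_time(mk_traj(t, rep(0, length(t))))$time, 0)
  # untreated logistic growth never clears
  p <- nondim_params(alpha = 0.4)
  tr <- simulate_model("none", p, infusion_spec("none"), y0 = c(U = 0.1),
                       t_span = c(0, 30), h = 0.01)
  expect_false(clearance_time(tr)$cleared)
  # exponential decay crosses 0.01 at t = log(100) ~ 4.605
  cl <- clearance_time(mk_traj(t, exp(-t)), threshold = 0.01)
  expect_true(cl$cleared)
  expect_lt(abs(cl$time - log(100)), 0.005 + 1e-9)
  expect_error(clearance_time(mk_traj(t, exp(-t)), threshold = 0), "positive")
})

test_that("transient dips below threshold are not counted as clearance", {
  t <- seq(0, 10, by = 0.01)
  U <- 0.5 * exp(-t) + 1e-4 * (t > 8)      # dips, then sits above 1e-4
  tr <- structure(list(time = t, state = cbind(U = U + 1e-5), params = NULL,
                       h = 0.01), class = "cv_trajectory")
  cl <- clearance_time(tr, threshold = 1e-4)
  expect_false(cl$cleared)
})

test_that("solutions stay nonnegative and the tumor stays within capacity", {
  set.seed(11)
  for (i in 1:6) {
    p <- rand_nd()
    sp <- infusion_spec(sample(c("constant", "exponential", "sinusoidal"), 1),
                        phi = p$phi, a = p$a)
    y0 <- c(U = runif(1, 0.1, 0.9), I = runif(1, 0, 0.1),
            V = runif(1, 0, 0.5), C = runif(1, 0, 0.5))
    y0[2] <- min(y0[2], 1 - y0[1])
    tr <- simulate_model("full", p, sp, y0 = y0, t_span = c(0, 20), h = 0.005)
    expect_gt(min(tr$state), -1e-9)
    expect_lt(max(tr$state[, "U"] + tr$state[, "I"]), 1 + 1e-6)
  }
})

test_that("untreated tumor growth is monotone below capacity", {
  p <- nondim_params(alpha = 0.8)
  tr <- simulate_model("none", p, infusion_spec("none"), y0 = c(U = 0.2),
                       t_span = c(0, 20), h = 0.01)
  expect_true(all(diff(tr$state[, 1]) >= 0))
})

test_that("chemotherapy alone does not clear the reference tumor", {
  p <- table1_nd()
  tr <- simulate_model("chemo", p, infusion_spec("constant", phi = p$phi),
                       y0 = c(U = 1, C = 0.1), t_span = c(0, 30), h = 0.005)
  expect_false(clearance_time(tr)$cleared)
  expect_gt(tr$state[nrow(tr$state), "U"], 0.5)
})

test_that("clearance accelerates with burst size and replication rate", {
  cl_of <- function(p) {
    tr <- simulate_model("viro", p, infusion_spec("none"),
                         y0 = c(U = 1, I = 0, V = 0.1),
                         t_span = c(0, 20), h = 0.005)
    clearance_time(tr)$time
  }
  t_b10 <- cl_of(figure_nd(1e-6, 10))
  t_b100 <- cl_of(figure_nd(1e-6, 100))
  expect_lt(t_b100, t_b10)
  t_lo <- cl_of(figure_nd(1e-6, 10))
  t_hi <- cl_of(figure_nd(1e-5, 10))  # 10x replication rate
  expect_lt(t_hi, t_lo)
})
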