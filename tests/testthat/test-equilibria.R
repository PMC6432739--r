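test_that("chemotherapy-only constant-infusion states are stationary", {
  # delta0*phi = 0.1, alpha = 0.4028, psi = 8.133 -> U* ~ 0.9695
  p <- nondim_params(alpha = 0.4028, delta0 = 0.1, phi = 1, psi = 8.133)
  sp <- infusion_spec("constant", phi = 1)
  eq <- equilibria_chemo(p, sp)
  labs <- vapply(eq, `[[`, "", "label")
  expect_setequal(labs, c("tumor-free", "tumor-dormant"))
  dorm <- eq[[which(labs == "tumor-dormant")]]
  expect_equal(unname(dorm$coords["U"]), 1 - 0.1 / (0.4028 * 8.133),
               tolerance = 1e-9)
  expect_equal(unname(dorm$coords["C"]), 1 / 8.133, tolerance = 1e-12)
  for (s in eq) expect_lt(s$residual, 1e-12)
  # no drug: the dormant state collapses to carrying capacity
  eq0 <- equilibria_chemo(p, infusion_spec("none"))
  d0 <- eq0[[2]]
  expect_equal(unname(d0$coords), c(1, 0))
})

test_that("autonomized sinusoidal chemotherapy states are stationary", {
  p <- nondim_params(alpha = 0.5, delta0 = 0.2, phi = 1.5, psi = 3, a = 0.8)
  sp <- infusion_spec("sinusoidal", phi = 1.5, a = 0.8)
  eq <- equilibria_chemo(p, sp)
  expect_length(eq, 4)
  tfd <- eq[[3]]
  expect_equal(unname(tfd$coords),
               c(0, 1.5 / (0.8 * 3), 1.5 / 0.8), tolerance = 1e-12)
  for (s in Filter(function(x) x$exists, eq))
    expect_lt(s$residual, 1e-9)
})

test_that("virotherapy equilibria: existence, degenerate clearance limits", {
  # gamma = 0 pins the dormant tumor load at zero
  p0 <- nondim_params(alpha = 0.4, beta = 0.5, b = 10, gamma = 0)
  eqs <- equilibria_viro(p0)
  expect_equal(unname(eqs[[3]]$coords["U"]), 0)
  expect_lt(eqs[[3]]$residual, 1e-12)
  # all three states stationary at a generic admissible draw
  p <- nondim_params(alpha = 0.4028, beta = 0.5, b = 10, gamma = 0.1)
  for (s in equilibria_viro(p)) expect_lt(s$residual, 1e-10)
  # dormant tumor load vanishes as replication rate or burst size blow up
  U_of <- function(beta, b) {
    pp <- nondim_params(alpha = 0.4, beta = beta, b = b, gamma = 0.1)
    unname(equilibria_viro(pp)[[3]]$coords["U"])
  }
  expect_lt(U_of(1e6, 10), 1e-7)
  expect_lt(U_of(0.5, 1e7), 1e-6)
})

test_that("dormant tumor load decreases in burst size and replication rate", {
  Us_b <- vapply(c(3, 5, 10, 20, 50), function(b)
    unname(equilibria_viro(nondim_params(alpha = 0.4, beta = 0.5, b = b,
                                         gamma = 0.1))[[3]]$coords["U"]),
    numeric(1))
  expect_true(all(diff(Us_b) < 0))
  Us_beta <- vapply(c(0.2, 0.4, 0.8, 1.6), function(be)
    unname(equilibria_viro(nondim_params(alpha = 0.4, beta = be, b = 10,
                                         gamma = 0.1))[[3]]$coords["U"]),
    numeric(1))
  expect_true(all(diff(Us_beta) < 0))
})

test_that("full-model constant-infusion catalogue is stationary", {
  p <- table1_nd()
  sp <- infusion_spec("constant", phi = p$phi)
  eq <- equilibria_full(p, sp)
  labs <- vapply(eq, `[[`, "", "label")
  expect_setequal(labs, c("tumor-free", "infected-tumor-free",
                          "tumor-dormant"))
  # tumor-free state is stationary exactly, term by term
  tf <- eq[[which(labs == "tumor-free")]]
  expect_identical(tf$residual, 0)
  expect_equal(unname(tf$coords["C"]), p$phi / p$psi)
  dorm <- eq[[which(labs == "tumor-dormant")]]
  expect_true(dorm$exists)
  expect_lt(dorm$residual, 1e-9)
})

test_that("switching off the drug reduces the full catalogue to virotherapy", {
  p <- nondim_params(alpha = 0.4, beta = 0.5, delta0 = 0.1, delta1 = 0.2,
                     b = 10, gamma = 0.1, phi = 0, psi = 4)
  eqf <- equilibria_full(p, infusion_spec("constant", phi = 0))
  eqv <- equilibria_viro(p)
  for (s in eqf) expect_equal(unname(s$coords["C"]), 0)
  # dormant coordinates coincide with the virotherapy dormant state
  df <- eqf[[3]]; dv <- eqv[[3]]
  expect_equal(unname(df$coords[c("U", "I", "V")]),
               unname(dv$coords), tolerance = 1e-9)
})

test_that("autonomized exponential and sinusoidal full catalogues are stationary", {
  p <- nondim_params(alpha = 0.4, beta = 0.5, delta0 = 0.1, delta1 = 0.2,
                     b = 10, gamma = 0.1, phi = 1.5, psi = 4, a = 0.7)
  eqe <- equilibria_full(p, infusion_spec("exponential", phi = 1.5, a = 0.7))
  expect_length(eqe, 3)
  for (s in Filter(function(x) x$exists, eqe)) expect_lt(s$residual, 1e-9)
  eqs <- equilibria_full(p, infusion_spec("sinusoidal", phi = 1.5, a = 0.7))
  expect_length(eqs, 6)
  for (s in Filter(function(x) x$exists, eqs)) expect_lt(s$residual, 1e-9)
  # effective drug level of the drug-bearing states is phi/(a psi)
  tfd <- eqs[[3]]
  expect_equal(unname(tfd$coords["C"]), 1.5 / (0.7 * 4), tolerance = 1e-12)
})

test_that("every existing catalogued state is stationary across random draws", {
  set.seed(23)
  kinds <- c("constant", "exponential", "sinusoidal")
  for (i in 1:20) {
    p <- rand_nd()
    sp <- infusion_spec(kinds[1 + i %% 3], phi = p$phi, a = p$a)
    states <- c(equilibria_chemo(p, sp), equilibria_viro(p),
                equilibria_full(p, sp))
    for (s in Filter(function(x) x$exists, states))
      expect_lt(s$residual, 1e-9)
  }
})

test_that("refinement fixes perturbed candidates and flags wrong ones", {
  p <- nondim_params(alpha = 0.4, beta = 0.5, b = 10, gamma = 0.1)
  ar <- autonomized_rhs("viro", p)
  st <- equilibria_viro(p)[[3]]
  # exact fixed point: unchanged
  out <- refine_steady_state(st, ar$fn)
  expect_equal(out$coords, st$coords, tolerance = 1e-12)
  # small perturbation: converges back to the same point
  pert <- st
  pert$coords <- st$coords * (1 + 1e-4)
  out2 <- refine_steady_state(pert, ar$fn)
  expect_lt(max(abs(out2$coords - st$coords)), 1e-8)
  expect_lt(out2$residual, 1e-12)
  expect_identical(out2$provenance, "numeric-refined")
  # grossly wrong candidate: the 10% guard trips
  wrong <- st
  wrong$coords["U"] <- st$coords["U"] * 2
  expect_error(refine_steady_state(wrong, ar$fn), "moved|diverged")
})
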