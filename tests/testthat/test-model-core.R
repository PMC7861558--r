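test_that("polarity measure is the signed normalized pole difference", {
  expect_equal(polarity(0.6, 0.2), 0.5)
  expect_equal(polarity(0.37, 0.37), 0)
  expect_equal(polarity(0.4, 0), 1)
  # antisymmetry and bounds over random abundances
  set.seed(1)
  s1 <- runif(200); s2 <- runif(200)
  expect_equal(polarity(s1, s2), -polarity(s2, s1))
  expect_true(all(abs(polarity(s1, s2)) <= 1))
  # degenerate denominator reports 0 with a flag
  w <- polarity(c(0, 0.5), c(0, 0.5))
  expect_equal(as.numeric(w), c(0, 0))
  expect_identical(attr(w, "degenerate"), c(TRUE, FALSE))
})

test_that("signal pulses have the prescribed step and gradual profiles", {
  step <- signal_scenario("k_ab", "enhancing", X_max = 5, tau = 3)
  expect_equal(signal_profile(1.5, step), 5)
  expect_equal(signal_profile(c(0, 2.999, 3, 10), step), c(5, 5, 0, 0))
  grad <- signal_scenario("k_ab", "enhancing", X_max = 5, tau = 3, lambda = 4)
  expect_equal(signal_profile(0, grad), 0)
  expect_equal(signal_profile(3 - 1e-12, grad), 5 * (1 - exp(-12)),
               tolerance = 1e-9)
  # continuity at the falling edge
  expect_equal(signal_profile(3, grad), 5 * (1 - exp(-12)), tolerance = 1e-9)
  # exponential decay after withdrawal
  expect_equal(signal_profile(4, grad), 5 * (1 - exp(-12)) * exp(-4))
  expect_error(signal_profile(-0.1, step), "t must be")
})

test_that("regulated rates scale linearly and repression floors at zero", {
  expect_equal(regulated_rate(15, 0.2, "enhancing"), 18)
  expect_equal(regulated_rate(7, 0, "enhancing"), 7)
  expect_equal(regulated_rate(7, 0, "repressive"), 7)
  expect_equal(regulated_rate(3, 1.5, "repressive"), 0)
  expect_equal(regulated_rate(3, 0.5, "repressive"), 1.5)
})

test_that("rhs matches an independent term-by-term evaluation", {
  p <- base_params()
  st <- c(A1 = 0.5, A2 = 0.1, R1 = 0.4, R2 = 0.2, B1 = 0.05, B2 = 0.6,
          X1 = 0, X2 = 0)
  d <- polarity_rhs(st, p)
  # hand evaluation of every flux term at this state
  Acyt <- 1 - 0.5 - 0.1; Rcyt <- 1 - 0.4 - 0.2; Bcyt <- 1 - 0.05 - 0.6
  expect_equal(d[["A1"]], 400 * Acyt * 0.4 - 2 * 0.5 - 400 * 0.5 * 0.05^2)
  expect_equal(d[["A2"]], 400 * Acyt * 0.2 - 2 * 0.1 - 400 * 0.1 * 0.6^2)
  expect_equal(d[["R1"]], Rcyt * (0.1 + 1.5 * 0.05) - 0.4 * 0.4)
  expect_equal(d[["R2"]], Rcyt * (0.1 + 1.5 * 0.6) - 0.4 * 0.2)
  expect_equal(d[["B1"]], Bcyt * (2 + 30 * 0.05) -
                 2.8 * 0.3 * 0.05 / (0.3 + 0.05) - 15 * 0.5 * 0.05^2)
  expect_equal(d[["B2"]], Bcyt * (2 + 30 * 0.6) -
                 2.8 * 0.3 * 0.6 / (0.3 + 0.6) - 15 * 0.1 * 0.6^2)
  expect_equal(d[["X1"]], 0)
  expect_equal(d[["X2"]], 0)
})

test_that("rhs is equivariant under pole exchange and regulation is local", {
  p <- base_params()
  sc <- signal_scenario("k_bB", "repressive", X_max = 2, tau = 1)
  set.seed(4)
  swap <- polswitch:::pole_swap
  for (i in 1:10) {
    st <- polswitch:::random_state(2)
    names(st) <- state_names
    d <- polarity_rhs(st, p, X_t = 2, sc)
    d_sw <- polarity_rhs(setNames(swap(st), state_names), p, X_t = 2, sc)
    expect_equal(unname(d_sw), unname(swap(d)), tolerance = 1e-12)
  }
  # a fully symmetric state has equal derivatives across poles
  st <- c(A1 = 0.2, A2 = 0.2, R1 = 0.3, R2 = 0.3, B1 = 0.25, B2 = 0.25,
          X1 = 0.4, X2 = 0.4)
  d <- polarity_rhs(st, p, X_t = 2, sc)
  expect_equal(d[c("A1", "R1", "B1", "X1")], d[c("A2", "R2", "B2", "X2")],
               ignore_attr = TRUE)
  # regulation uses the local X_i: an asymmetric X splits the B derivatives
  st2 <- st; st2[["X1"]] <- 0.8; st2[["X2"]] <- 0
  d2 <- polarity_rhs(st2, p, X_t = 2, sc)
  expect_false(isTRUE(all.equal(d2[["B1"]], d2[["B2"]])))
})

test_that("adaptive integration agrees with a fixed-step RK4 oracle", {
  p <- base_params()
  # signal on throughout the window: the right-hand side is smooth, which
  # is the regime where a naive fixed-step integrator is a valid oracle
  sc <- signal_scenario("k_ab", "enhancing", X_max = 2, tau = 2.5)
  init <- base_relaxed()
  traj <- integrate_deterministic(init, p, sc, t_span = c(0, 2))
  ref <- rk4_integrate(init, p, sc, c(0, 2), dt = 1e-4)
  end <- as.numeric(traj[nrow(traj), state_names])
  expect_equal(end, unname(ref), tolerance = 1e-4)
})

test_that("a fixed point stays fixed and trajectories conserve mass", {
  p <- base_params()
  init <- base_relaxed()
  expect_lt(max(abs(polarity_rhs(init, p))), 1e-10)
  traj <- integrate_deterministic(init, p, NULL, t_span = c(0, 5))
  expect_lt(max(abs(as.numeric(traj[nrow(traj), state_names]) -
                      unname(init[state_names]))), 1e-6)
  # polar sums never exceed the (unit) species totals beyond tolerance
  for (sp in c("A", "R", "B")) {
    sums <- traj[[paste0(sp, "1")]] + traj[[paste0(sp, "2")]]
    expect_true(all(sums <= 1 + 1e-7))
    expect_true(all(sums >= -1e-7))
  }
})

test_that("pole-exchanged initial conditions give pole-exchanged trajectories", {
  p <- base_params()
  sc <- signal_scenario("k_ba", "enhancing", X_max = 1, tau = 0.5)
  init <- base_relaxed()
  swap <- polswitch:::pole_swap
  tr1 <- integrate_deterministic(init, p, sc, t_span = c(0, 2),
                                 dt_sample = 0.05)
  tr2 <- integrate_deterministic(setNames(swap(init), state_names), p, sc,
                                 t_span = c(0, 2), dt_sample = 0.05)
  m1 <- as.matrix(tr1[, state_names])
  m2 <- as.matrix(tr2[, state_names])
  expect_equal(m2, m1[, c(2, 1, 4, 3, 6, 5, 8, 7)],
               ignore_attr = TRUE, tolerance = 1e-6)
})

test_that("relaxation finds mirror-image polarized fixed points", {
  p <- base_params()
  s1 <- base_relaxed()
  expect_gt(polarity(s1[["A1"]], s1[["A2"]]), 0)
  expect_lt(max(abs(polarity_rhs(s1, p))), 1e-8)
  s2 <- relax_to_polarized(p, orientation = "pole2")
  expect_equal(unname(s2), unname(polswitch:::pole_swap(s1)),
               tolerance = 1e-9)
  expect_error(relax_to_polarized(p, seed_asymmetry = 0),
               "symmetric manifold")
})

test_that("mixing timescale follows diffusive scaling", {
  expect_equal(mixing_timescale(6, 10), 1.8)
  expect_equal(mixing_timescale(0, 5), 0)
  expect_equal(mixing_timescale(12, 10), 4 * mixing_timescale(6, 10))
})
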