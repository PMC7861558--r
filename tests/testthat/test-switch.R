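test_that("switch events are counted from sign changes of A1 - A2", {
  t <- seq(0, 2, by = 0.01)
  # constant polarity
  expect_equal(count_switch_events(synthetic_trajectory(t, 0.8, 0.1)), 0)
  # single monotone crossing
  tr <- synthetic_trajectory(t, A1 = 0.5 + (t - 1) * 0.2, A2 = 0.5)
  expect_equal(count_switch_events(tr), 1)
  expect_equal(switch_event_times(tr), 1, tolerance = 1e-9)
  # A1 - A2 = cos(2 pi t) on [0, 2] crosses zero 4 times
  tr2 <- synthetic_trajectory(t, A1 = 0.5 + 0.25 * cos(2 * pi * t), A2 = 0.5)
  expect_equal(count_switch_events(tr2), 4)
  expect_equal(switch_event_times(tr2), c(0.25, 0.75, 1.25, 1.75),
               tolerance = 1e-3)
  # a grid-exact zero attaches to the preceding sign (no double count)
  tr3 <- synthetic_trajectory(c(0, 1, 2, 3), A1 = c(0.6, 0.5, 0.4, 0.4),
                              A2 = c(0.4, 0.5, 0.6, 0.6))
  expect_equal(count_switch_events(tr3), 1)
})

test_that("hysteresis band suppresses jitter recrossings", {
  t <- seq(0, 1, by = 0.01)
  jitter <- 0.01 * sin(40 * pi * t)
  tr <- synthetic_trajectory(t, A1 = 0.5 + jitter, A2 = 0.5)
  expect_gt(count_switch_events(tr), 5)
  expect_lte(count_switch_events(tr, hysteresis = 0.2), 1)
})

test_that("switching order sorts species by first zero crossing", {
  t <- seq(0, 4, by = 0.01)
  # manufactured crossings: R at 1, A at 2, B at 3
  tr <- synthetic_trajectory(t,
                             A1 = 0.5 + 0.1 * (2 - t), A2 = 0.5,
                             B1 = 0.5 + 0.1 * (3 - t), B2 = 0.5,
                             R1 = 0.5 + 0.1 * (1 - t), R2 = 0.5)
  ord <- switching_order(tr)
  expect_equal(as.character(ord), c("R", "A", "B"))
  # mirrored trajectory: signs flip, crossing times unchanged
  tr_m <- synthetic_trajectory(t,
                               A1 = 0.5, A2 = 0.5 + 0.1 * (2 - t),
                               B1 = 0.5, B2 = 0.5 + 0.1 * (3 - t),
                               R1 = 0.5, R2 = 0.5 + 0.1 * (1 - t))
  expect_equal(as.character(switching_order(tr_m)), c("R", "A", "B"))
  # non-reversing species are reported separately
  tr_p <- synthetic_trajectory(t, A1 = 0.5 + 0.1 * (2 - t), A2 = 0.5,
                               B1 = 0.8, B2 = 0.1, R1 = 0.8, R2 = 0.1)
  ord_p <- switching_order(tr_p)
  expect_equal(as.character(ord_p), "A")
  expect_setequal(attr(ord_p, "non_reversing"), c("B", "R"))
})

test_that("a null signal leaves the polarized state untouched", {
  p <- base_params()
  sc <- signal_scenario("k_ab", "enhancing", X_max = 0, tau = 1)
  res <- run_switch_experiment(p, sc, t_end = 5, initial = base_relaxed(),
                               dt_sample = 0.05)
  expect_false(res$outcome$switched)
  expect_equal(res$outcome$n_events, 0)
  expect_equal(res$outcome$omega_initial, res$outcome$omega_final,
               tolerance = 1e-6)
})

test_that("deterministic switching parity: switched iff odd event count", {
  p <- base_params()
  init <- base_relaxed()
  for (tau in c(1, 3, 6, 9)) {
    sc <- signal_scenario("k_ab", "enhancing", X_max = 4, tau = tau)
    res <- run_switch_experiment(p, sc, initial = init, dt_sample = 0.02)
    expect_equal(res$outcome$switched, res$outcome$n_events %% 2 == 1,
                 info = paste("tau =", tau))
  }
})

test_that("oscillatory band: extending tau by one band width undoes the switch", {
  p <- base_params()
  init <- base_relaxed()
  sc1 <- signal_scenario("k_ab", "enhancing", X_max = 4, tau = 2)
  r1 <- run_switch_experiment(p, sc1, initial = init, dt_sample = 0.02)
  expect_true(r1$outcome$switched)
  expect_equal(r1$outcome$n_events, 1)
  cls <- classify_persistent_signal(p, sc1, initial = init)
  half <- attr(cls, "period") / 2
  sc2 <- signal_scenario("k_ab", "enhancing", X_max = 4, tau = 2 + half)
  r2 <- run_switch_experiment(p, sc2, initial = init, dt_sample = 0.02)
  expect_false(r2$outcome$switched)
  expect_equal(r2$outcome$n_events, 2)
})

test_that("switching probability limits: null signal and deterministic limit", {
  p <- base_params()
  init <- base_relaxed()
  null_sc <- signal_scenario("k_ab", "enhancing", X_max = 0, tau = 1)
  sp0 <- switching_probability(p, null_sc, noise_config(1e8, seed = 2),
                               n_realizations = 20, t_end = 5,
                               initial = init)
  expect_equal(sp0$prob, 0)
  sc <- signal_scenario("k_ab", "enhancing", X_max = 4, tau = 2)
  sp1 <- switching_probability(p, sc, noise_config(1e10, seed = 2),
                               n_realizations = 10, initial = init,
                               t_pre = 0)
  expect_equal(sp1$prob, 1)  # deterministic switch cell
})

test_that("ensemble estimates do not depend on realization order", {
  p <- base_params()
  init <- base_relaxed()
  sc <- signal_scenario("k_ab", "enhancing", X_max = 4, tau = 2)
  nc <- noise_config(10^3.5, seed = 31)
  a <- switching_probability(p, sc, nc, n_realizations = 40, t_end = 10,
                             initial = init)
  b <- switching_probability(p, sc, nc, n_realizations = 20, t_end = 10,
                             initial = init)
  # the first 20 substreams are identical regardless of ensemble size
  expect_identical(a$switched[1:20], b$switched)
})

test_that("mean inter-switch time reports insufficient events at low noise", {
  p <- base_params()
  init <- base_relaxed()
  sc <- signal_scenario("k_ab", "repressive", X_max = 0.5, tau = 1)
  res <- mean_interswitch_time(p, sc, noise_config(1e8, seed = 4),
                               T_total = 20, initial = init)
  expect_equal(res$status, "insufficient events")
  expect_true(is.na(res$mean))
})

test_that("under continuous-signal oscillations switches recur every half period", {
  p <- base_params()
  init <- base_relaxed()
  sc <- signal_scenario("k_ab", "enhancing", X_max = 4, tau = 1)
  cls <- classify_persistent_signal(p, sc, initial = init)
  half <- attr(cls, "period") / 2
  res <- mean_interswitch_time(p, sc, noise_config(1e7, seed = 6),
                               T_total = 100, initial = init)
  expect_equal(res$status, "ok")
  expect_equal(res$mean, half, tolerance = 0.1)
})
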