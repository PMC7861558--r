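# Shared fixtures. The relaxed polarized state and the mechanism
# representatives are expensive to recompute, so they are cached for the
# duration of the test run.

.fixture_cache <- new.env(parent = emptyenv())

base_params <- function() base_parameters()

base_relaxed <- function() {
  if (is.null(.fixture_cache$relaxed)) {
    .fixture_cache$relaxed <- relax_to_polarized(base_parameters(),
                                                 orientation = "pole1")
  }
  .fixture_cache$relaxed
}

base_fixed_points <- function() {
  if (is.null(.fixture_cache$fps)) {
    .fixture_cache$fps <- find_fixed_points(base_parameters(), seed = 2)
  }
  .fixture_cache$fps
}

mechanism_reps <- function() {
  if (is.null(.fixture_cache$reps)) {
    .fixture_cache$reps <- find_mechanism_representatives(base_parameters())
  }
  .fixture_cache$reps
}

# Build a synthetic trajectory data frame from explicit pole series.
synthetic_trajectory <- function(time, A1, A2, B1 = A2, B2 = A1,
                                 R1 = A1, R2 = A2) {
  structure(data.frame(time = time, A1 = A1, A2 = A2, R1 = R1, R2 = R2,
                       B1 = B1, B2 = B2, X1 = 0, X2 = 0, X_t = 0),
            class = c("polarity_trajectory", "data.frame"))
}

# Independent fixed-step classical Runge-Kutta integrator used as an
# oracle against the adaptive solver.
rk4_integrate <- function(initial, params, scenario, t_span, dt) {
  y <- unname(initial[state_names])
  t <- t_span[1]
  nsteps <- round((t_span[2] - t_span[1]) / dt)
  for (i in seq_len(nsteps)) {
    f <- function(tt, yy) polarity_rhs(yy, params,
                                       signal_profile(tt, scenario), scenario)
    k1 <- f(t, y)
    k2 <- f(t + dt / 2, y + dt / 2 * k1)
    k3 <- f(t + dt / 2, y + dt / 2 * k2)
    k4 <- f(t + dt, y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + dt
  }
  names(y) <- state_names
  y
}
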