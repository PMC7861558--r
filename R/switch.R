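# Three-phase switching protocol, switch-event detection and counting,
# switching-order extraction, ensemble switching probabilities, and mean
# inter-switch times under continuous signals.

#' Run one three-phase switching experiment
#'
#' Phase 1: relax the no-signal model to the pole-1-oriented polarized fixed
#' point (by convention; the pole-exchange symmetry is exact, so the mirror
#' experiment is identical with all omegas negated). Phase 2: apply the
#' signal pulse on \[0, tau). Phase 3: integrate signal-free until `t_end`,
#' long enough for the system to relax back to a polarized steady state.
#' The experiment counts as a successful switch when the sign of omega_A at
#' `t_end` differs from the sign at t = 0.
#'
#' @param params a `polarity_params` vector (must be bistable without
#'   signal).
#' @param scenario a [signal_scenario()].
#' @param t_end end of the observation window, min (default 30).
#' @param initial optional precomputed polarized state (saves the phase-1
#'   relaxation when running many experiments with the same parameters).
#' @param dt_sample trajectory sampling interval, min.
#' @return a list with elements `trajectory` (a `polarity_trajectory`) and
#'   `outcome` (a `switch_outcome`: `omega_initial`, `omega_final`,
#'   `switched`, `n_events`, `first_crossing`, `order`, `mechanism`).
#' @export
run_switch_experiment <- function(params, scenario, t_end = 30,
                                  initial = NULL, dt_sample = 0.01) {
  if (is.null(initial)) {
    initial <- relax_to_polarized(params, orientation = "pole1")
  }
  traj <- integrate_deterministic(initial, params, scenario,
                                  t_span = c(0, max(t_end, scenario$tau)),
                                  dt_sample = dt_sample)
  outcome <- switch_outcome(traj)
  list(trajectory = traj, outcome = outcome)
}

switch_outcome <- function(traj) {
  w <- trajectory_polarity(traj, "A")
  ev <- switch_event_times(traj)
  out <- list(omega_initial = w[1],
              omega_final = w[length(w)],
              switched = sign(w[1]) != sign(w[length(w)]),
              n_events = length(ev),
              first_crossing = if (length(ev)) ev[1] else NA_real_,
              order = switching_order(traj),
              mechanism = NA_character_)
  class(out) <- "switch_outcome"
  out
}

#' @export
print.switch_outcome <- function(x, ...) {
  cat(sprintf(
    "<switch_outcome> omega: %.3f -> %.3f | switched: %s | events: %d\n",
    x$omega_initial, x$omega_final, x$switched, x$n_events))
  if (length(x$order)) {
    cat("  switching order:", paste(x$order, collapse = " -> "), "\n")
  }
  if (!is.na(x$mechanism)) cat("  mechanism:", x$mechanism, "\n")
  invisible(x)
}

# Interpolated times at which a sampled series crosses zero. A sampled
# value of exactly 0 is attached to the preceding sign, so grid-exact
# zeros do not double-count.
zero_crossing_times <- function(time, v) {
  s <- sign(v)
  for (i in seq_along(s)[-1]) if (s[i] == 0) s[i] <- s[i - 1]
  lead <- s == 0  # leading zeros have no preceding sign
  s_prev <- c(NA, s[-length(s)])
  idx <- which(!is.na(s_prev) & s_prev != 0 & s != 0 & s != s_prev)
  vapply(idx, function(i) {
    dv <- v[i] - v[i - 1]
    if (dv == 0) time[i] else time[i - 1] - v[i - 1] * (time[i] - time[i - 1]) / dv
  }, numeric(1))
}

#' Switch events of a trajectory
#'
#' A polarity switch event is a sign change of A1 - A2 between consecutive
#' samples; event times are linearly interpolated. Note that for stochastic
#' trajectories raw crossings of A1 = A2 are counted, which is
#' noise-sensitive near the symmetric configuration; `hysteresis` adds an
#' optional guard band requiring |omega_A| to exceed the band between
#' counted events (off by default).
#'
#' @param traj a `polarity_trajectory` with at least 2 samples.
#' @param hysteresis numeric band on |omega_A| (0 = raw crossings).
#' @return `switch_event_times`: numeric vector of event times;
#'   `count_switch_events`: integer count.
#' @export
count_switch_events <- function(traj, hysteresis = 0) {
  length(switch_event_times(traj, hysteresis))
}

#' @rdname count_switch_events
#' @export
switch_event_times <- function(traj, hysteresis = 0) {
  stopifnot(nrow(traj) >= 2)
  d <- traj$A1 - traj$A2
  times <- zero_crossing_times(traj$time, d)
  if (hysteresis > 0 && length(times) > 1) {
    w <- trajectory_polarity(traj, "A")
    kept <- times[1]
    for (i in seq_along(times)[-1]) {
      inside <- traj$time > kept[length(kept)] & traj$time < times[i]
      if (any(abs(w[inside]) > hysteresis)) kept <- c(kept, times[i])
    }
    times <- kept
  }
  times
}

#' Order in which the polarity proteins reverse
#'
#' Species (A, B, R) sorted by the time of the first zero of their polarity
#' measure omega; species that never cross are omitted and reported in the
#' `"non_reversing"` attribute.
#'
#' @param traj a `polarity_trajectory`.
#' @return character vector (possibly empty) of species in crossing order.
#' @export
switching_order <- function(traj) {
  species <- c("A", "B", "R")
  first <- vapply(species, function(sp) {
    tms <- zero_crossing_times(traj$time, trajectory_polarity(traj, sp))
    if (length(tms)) tms[1] else NA_real_
  }, numeric(1))
  ord <- species[order(first, na.last = NA)]
  attr(ord, "non_reversing") <- species[is.na(first)]
  attr(ord, "first_crossing") <- first
  ord
}

#' Ensemble switching probability of the stochastic model
#'
#' Runs `n_realizations` Langevin realizations of the three-phase protocol
#' (all starting from the same relaxed polarized state) and estimates the
#' probability that the sign of omega_A flips between t = 0 and `t_end`,
#' with its binomial standard error. Realizations use independent
#' substreams keyed by (`noise$seed`, realization), so the estimate does
#' not depend on evaluation order.
#'
#' @inheritParams run_switch_experiment
#' @param noise a [noise_config()].
#' @param n_realizations number of realizations (>= 1).
#' @param t_pre signal-free stochastic burn-in, min. Phase 1 of the
#'   protocol is stochastic too, so each realization enters t = 0 with its
#'   own fluctuation around the polarized state; its own omega_A sign at
#'   t = 0 is the reference for the switch comparison.
#' @return a list: `prob`, `se`, `n`, `switched` (logical vector),
#'   `n_events` (integer vector).
#' @export
switching_probability <- function(params, scenario, noise,
                                  n_realizations = 100, t_end = 30,
                                  initial = NULL, t_pre = 5) {
  stopifnot(n_realizations >= 1)
  if (is.null(initial)) {
    initial <- relax_to_polarized(params, orientation = "pole1")
  }
  res <- em_ensemble(initial, params, scenario, t_end, noise, n_realizations,
                     t_pre = t_pre)
  switched <- sign(res$final[, "A1"] - res$final[, "A2"]) != res$sign0
  p <- mean(switched)
  list(prob = p,
       se = sqrt(p * (1 - p) / n_realizations),
       n = n_realizations,
       switched = switched,
       n_events = res$n_events)
}

#' Mean time between switch events under a continuous signal
#'
#' Applies the scenario's signal for the whole run (tau = `T_total`),
#' simulates one long stochastic trajectory, and averages the intervals
#' between successive crossings of A1 = A2. With fewer than 2 events the
#' mean first-passage time exceeds the window and the result is reported as
#' `status = "insufficient events"` rather than an error.
#'
#' @inheritParams switching_probability
#' @param T_total trajectory length, min.
#' @return a list: `mean` (min or `NA`), `n_events`, `status`,
#'   `event_times`.
#' @export
mean_interswitch_time <- function(params, scenario, noise, T_total = 5000,
                                  initial = NULL) {
  if (is.null(initial)) {
    initial <- relax_to_polarized(params, orientation = "pole1")
  }
  sc <- scenario
  sc$tau <- T_total + 1  # signal never removed within the window
  traj <- simulate_stochastic(initial, params, sc, t_span = c(0, T_total),
                              noise = noise)
  ev <- switch_event_times(traj)
  if (length(ev) < 2) {
    return(list(mean = NA_real_, n_events = length(ev),
                status = "insufficient events", event_times = ev))
  }
  list(mean = mean(diff(ev)), n_events = length(ev), status = "ok",
       event_times = ev)
}
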