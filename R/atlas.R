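# Phase-diagram scans over (tau, X_max), persistent-signal classification,
# and the four-way mechanism taxonomy.

#' Classify the dynamics under a persistent signal
#'
#' Applies the scenario's signal for the whole run of length `T_long` and
#' classifies the long-time behavior of omega_A after discarding the first
#' half as transient: `"symmetric"` if |omega_A| has decayed below 0.01 in
#' the final tenth of the window (single symmetric fixed point),
#' `"oscillatory"` if omega_A keeps alternating sign (at least 3 sign
#' changes, peak |omega_A| > 0.05: a limit cycle), and `"polarized"` if a
#' steady nonzero omega_A remains (still bistable). Anything else is
#' `"indeterminate"`.
#'
#' @param params a `polarity_params` vector.
#' @param scenario a [signal_scenario()]; only its target, sign and `X_max`
#'   matter (the pulse is extended to `T_long`).
#' @param T_long run length, min (default 100).
#' @param initial optional relaxed polarized state.
#' @return a character label with attributes `period` (min, oscillatory
#'   only) and `omega_final`.
#' @export
classify_persistent_signal <- function(params, scenario, T_long = 100,
                                       initial = NULL) {
  if (is.null(initial)) {
    initial <- relax_to_polarized(params, orientation = "pole1")
  }
  sc <- scenario
  sc$tau <- T_long + 1
  traj <- integrate_deterministic(initial, params, sc, t_span = c(0, T_long),
                                  dt_sample = 0.01)
  w <- trajectory_polarity(traj, "A")
  keep <- traj$time >= T_long / 2
  w_keep <- w[keep]
  t_keep <- traj$time[keep]
  tail_w <- w_keep[t_keep >= 0.9 * T_long]
  crossings <- zero_crossing_times(t_keep, w_keep)
  label <-
    if (max(abs(tail_w)) < 0.01) {
      "symmetric"
    } else if (length(crossings) >= 3 && max(abs(w_keep)) > 0.05) {
      "oscillatory"
    } else if (min(abs(tail_w)) > 0.01 &&
               (max(tail_w) - min(tail_w)) < 0.05) {
      "polarized"
    } else {
      "indeterminate"
    }
  period <- NA_real_
  if (label == "oscillatory") {
    up <- crossings[vapply(crossings, function(tc) {
      i <- findInterval(tc, t_keep)
      w_keep[min(i + 1, length(w_keep))] > w_keep[i]
    }, logical(1))]
    if (length(up) >= 2) period <- mean(diff(up))
  }
  structure(label, period = period, omega_final = w_keep[length(w_keep)])
}

#' Deterministic phase-diagram scan of one scenario family
#'
#' Runs the three-phase switching experiment on every cell of a
#' (tau, X_max) grid for one (target, sign) regulation family, and
#' classifies the persistent-signal dynamics once per X_max value.
#'
#' @param params a `polarity_params` vector.
#' @param target one of [core_rate_names].
#' @param sign `"enhancing"` or `"repressive"`.
#' @param tau_grid,xmax_grid strictly increasing grids.
#' @param t_end observation window per cell, min.
#' @param dt_sample trajectory sampling interval for the per-cell runs.
#' @return a `phase_diagram` object: a long data frame (`tau`, `xmax`,
#'   `switched`, `n_events`, `first_crossing`, `persistent_class`,
#'   `mechanism`) with the scan settings in attributes. Per-cell integrator
#'   failures are recorded as `NA` rows and the scan continues.
#' @export
scan_deterministic <- function(params, target, sign, tau_grid, xmax_grid,
                               t_end = 30, dt_sample = 0.02) {
  stopifnot(all(diff(tau_grid) > 0), all(diff(xmax_grid) > 0))
  initial <- relax_to_polarized(params, orientation = "pole1")
  cls <- lapply(xmax_grid, function(xm) {
    sc <- signal_scenario(target, sign, X_max = xm, tau = 1)
    classify_persistent_signal(params, sc, initial = initial)
  })
  class_by_xmax <- vapply(cls, as.character, character(1))
  period_by_xmax <- vapply(cls, function(z) attr(z, "period"), numeric(1))
  grid <- expand.grid(tau = tau_grid, xmax = xmax_grid)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    sc <- signal_scenario(target, sign, X_max = grid$xmax[i],
                          tau = grid$tau[i])
    res <- tryCatch(
      run_switch_experiment(params, sc, t_end = t_end, initial = initial,
                            dt_sample = dt_sample),
      error = function(e) NULL)
    if (is.null(res)) {
      return(data.frame(switched = NA, n_events = NA_integer_,
                        first_crossing = NA_real_))
    }
    data.frame(switched = res$outcome$switched,
               n_events = res$outcome$n_events,
               first_crossing = res$outcome$first_crossing)
  })
  out <- cbind(grid, do.call(rbind, rows))
  out$persistent_class <- class_by_xmax[match(out$xmax, xmax_grid)]
  out$mechanism <- mechanism_label(out$switched, out$persistent_class,
                                   out$first_crossing, out$tau)
  structure(out, class = c("phase_diagram", "data.frame"),
            target = target, sign = sign,
            tau_grid = tau_grid, xmax_grid = xmax_grid,
            period_by_xmax = stats::setNames(period_by_xmax,
                                             format(xmax_grid)),
            params = params)
}

# Vectorized four-way taxonomy given switch flag, persistent class and
# first-crossing timing relative to the signal duration.
mechanism_label <- function(switched, persistent_class, first_crossing, tau) {
  out <- rep("none", length(switched))
  sw <- !is.na(switched) & switched
  out[sw & persistent_class == "oscillatory"] <- "transient_oscillator"
  out[sw & persistent_class == "symmetric"] <- "reset"
  pol <- sw & persistent_class == "polarized"
  out[pol & !is.na(first_crossing) & first_crossing < tau] <- "push"
  out[pol & !is.na(first_crossing) & first_crossing >= tau] <- "prime_release"
  out[sw & persistent_class == "indeterminate"] <- "none"
  out
}

#' Stochastic phase-diagram scan
#'
#' Estimates the Langevin switching probability (with binomial standard
#' error) on every cell of a (tau, X_max) grid.
#'
#' @inheritParams scan_deterministic
#' @param noise a [noise_config()].
#' @param n_realizations realizations per cell.
#' @return a `phase_diagram` data frame (`tau`, `xmax`, `prob`, `se`, `n`).
#' @export
scan_stochastic <- function(params, target, sign, tau_grid, xmax_grid,
                            noise, n_realizations = 50, t_end = 30) {
  stopifnot(all(diff(tau_grid) > 0), all(diff(xmax_grid) > 0))
  initial <- relax_to_polarized(params, orientation = "pole1")
  grid <- expand.grid(tau = tau_grid, xmax = xmax_grid)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    sc <- signal_scenario(target, sign, X_max = grid$xmax[i],
                          tau = grid$tau[i])
    sp <- switching_probability(params, sc, noise, n_realizations,
                                t_end = t_end, initial = initial)
    data.frame(prob = sp$prob, se = sp$se, n = sp$n)
  })
  out <- cbind(grid, do.call(rbind, rows))
  structure(out, class = c("phase_diagram", "data.frame"),
            target = target, sign = sign, tau_grid = tau_grid,
            xmax_grid = xmax_grid, noise = noise, params = params)
}

#' Classify the switching mechanism of one signal
#'
#' Combines the persistent-signal class at the scenario's amplitude with
#' the timing of the polarity reversal: oscillatory dynamics during the
#' signal give a transient-oscillator switch; relaxation to the symmetric
#' state gives a reset switch; if the system stays bistable during the
#' signal, a reversal that begins while the signal is on is a push switch
#' and a reversal only after removal is a prime-release switch. Signals
#' that do not switch are labeled `"none"`.
#'
#' @inheritParams run_switch_experiment
#' @param experiment optional precomputed result of
#'   [run_switch_experiment()] for this scenario.
#' @return one of `"transient_oscillator"`, `"reset"`, `"prime_release"`,
#'   `"push"`, `"none"`.
#' @export
classify_mechanism <- function(params, scenario, initial = NULL,
                               experiment = NULL) {
  if (is.null(initial)) {
    initial <- relax_to_polarized(params, orientation = "pole1")
  }
  if (is.null(experiment)) {
    experiment <- run_switch_experiment(params, scenario, initial = initial)
  }
  oc <- experiment$outcome
  if (!isTRUE(oc$switched)) return("none")
  cls <- classify_persistent_signal(params, scenario, initial = initial)
  mechanism_label(TRUE, as.character(cls), oc$first_crossing, scenario$tau)
}

#' Switching under gradual signal edges
#'
#' Reruns a switching experiment with exponential signal edges for each
#' rate in `lambda_list`. Slow edges let the system track the moving fixed
#' points adiabatically, which abolishes prime-release and push switches
#' while oscillator- and reset-type switches persist.
#'
#' @inheritParams run_switch_experiment
#' @param lambda_list numeric vector of edge rates (min^-1).
#' @return data frame with columns `lambda`, `switched`, `n_events`.
#' @export
gradual_signal_sweep <- function(params, scenario, lambda_list,
                                 t_end = 30, initial = NULL) {
  if (is.null(initial)) {
    initial <- relax_to_polarized(params, orientation = "pole1")
  }
  rows <- lapply(lambda_list, function(lam) {
    sc <- scenario
    sc$lambda <- lam
    # give slow edges time to decay after the nominal duration
    t1 <- max(t_end, scenario$tau + 10 / lam)
    res <- run_switch_experiment(params, sc, t_end = t1, initial = initial)
    data.frame(lambda = lam, switched = res$outcome$switched,
               n_events = res$outcome$n_events)
  })
  do.call(rbind, rows)
}

#' Locate one representative signal per switching mechanism
#'
#' Scans a small set of regulation families over focused (tau, X_max)
#' windows (chosen once, for the base parameter set, to bracket all four
#' regimes) and returns, for each mechanism, one deterministic-switch cell
#' labeled with that mechanism. Cells are chosen as interior points of
#' their labeled region (maximal count of same-labeled grid neighbors).
#'
#' @param params a `polarity_params` vector.
#' @param families optional list of scan windows; each element is a list
#'   with `target`, `sign`, `tau_grid`, `xmax_grid`.
#' @return named list of `signal_scenario` objects (one per mechanism
#'   found) with the scan tables in attribute `"scans"`.
#' @export
find_mechanism_representatives <- function(params,
                                           families = default_scan_families()) {
  scans <- lapply(families, function(fam) {
    scan_deterministic(params, fam$target, fam$sign, fam$tau_grid,
                       fam$xmax_grid)
  })
  mechs <- c("transient_oscillator", "reset", "prime_release", "push")
  reps <- list()
  for (mech in mechs) {
    best <- NULL; best_score <- -1
    for (pd in scans) {
      hits <- which(pd$mechanism == mech)
      if (!length(hits)) next
      for (i in hits) {
        # interiority: same-mechanism neighbors in the (tau, xmax) grid
        neigh <- pd$mechanism == mech &
          abs(match(pd$tau, attr(pd, "tau_grid")) -
                match(pd$tau[i], attr(pd, "tau_grid"))) <= 1 &
          abs(match(pd$xmax, attr(pd, "xmax_grid")) -
                match(pd$xmax[i], attr(pd, "xmax_grid"))) <= 1
        score <- sum(neigh)
        # the defining feature of a reset switch is that the signal lasts
        # long enough to erase polarity, so prefer the longest duration
        # among reset-labeled cells
        if (mech == "reset") score <- match(pd$tau[i], attr(pd, "tau_grid"))
        if (score > best_score) {
          best_score <- score
          best <- signal_scenario(attr(pd, "target"), attr(pd, "sign"),
                                  X_max = pd$xmax[i], tau = pd$tau[i])
        }
      }
    }
    if (!is.null(best)) reps[[mech]] <- best
  }
  attr(reps, "scans") <- scans
  reps
}

#' Default scan windows used to locate the four mechanisms
#'
#' Focused (tau, X_max) windows for three regulation families of the base
#' parameter set: enhancement of the A-displaces-B rate `k_ab` (banded
#' oscillatory regime at moderate amplitude, symmetric reset regime at high
#' amplitude), repression of `k_ab` (solid prime-release regime), and
#' enhancement of the A-recruitment rate `k_rA` (narrow push band below the
#' oscillatory onset). The windows were located by exploratory scanning of
#' this package's own phase diagrams; the original study marks its example
#' signals only graphically.
#'
#' @return list of scan-window definitions for
#'   [find_mechanism_representatives()].
#' @export
default_scan_families <- function() {
  list(
    k_ab_enh = list(target = "k_ab", sign = "enhancing",
                    tau_grid = c(1, 2, 3, 6),
                    xmax_grid = c(4, 6, 80)),
    k_ab_rep = list(target = "k_ab", sign = "repressive",
                    tau_grid = c(6, 8, 10),
                    xmax_grid = c(2, 4, 8)),
    k_rA_enh = list(target = "k_rA", sign = "enhancing",
                    tau_grid = c(10, 15, 20),
                    xmax_grid = c(0.175, 0.18, 0.185))
  )
}
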