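# Deterministic dynamics: polarity measure, signal pulse, regulated rates,
# the 8-variable ODE right-hand side, and piecewise stiff integration.

#' Polarity measure of a species
#'
#' The signed, normalized pole difference omega = (s1 - s2) / (s1 + s2),
#' in \[-1, 1\]. Positive values mean more abundance at pole 1. A polarity
#' reversal is a change of sign of omega over time.
#'
#' Where the denominator is exactly 0 (both poles fully depleted) omega is
#' reported as 0 and the positions are flagged in a `"degenerate"` attribute;
#' the dynamics never reaches this state from valid initial conditions.
#'
#' @param s1,s2 polar abundances (vectors of equal length), >= 0.
#' @return numeric vector of polarity values in \[-1, 1\].
#' @examples
#' polarity(0.6, 0.2)  # 0.5
#' @export
polarity <- function(s1, s2) {
  denom <- s1 + s2
  degen <- denom == 0
  w <- ifelse(degen, 0, (s1 - s2) / denom)
  if (any(degen)) attr(w, "degenerate") <- degen
  w
}

#' Total signal-protein abundance at time t
#'
#' Step pulses jump to `X_max` on \[0, tau) and back to 0; gradual pulses
#' follow X_t(t) = X_max (1 - exp(-lambda t)) while the signal is on and
#' decay as X_max (1 - exp(-lambda tau)) exp(-lambda (t - tau)) after it is
#' withdrawn, which is continuous in t.
#'
#' @param t time in minutes (vectorized), >= 0.
#' @param scenario a [signal_scenario()].
#' @return numeric vector of X_t values.
#' @export
signal_profile <- function(t, scenario) {
  if (any(t < 0)) stop("signal_profile: t must be >= 0")
  if (is.null(scenario)) return(rep(0, length(t)))
  with(scenario, {
    if (is.infinite(lambda)) {
      ifelse(t < tau, X_max, 0)
    } else {
      ifelse(t < tau,
             X_max * (1 - exp(-lambda * t)),
             X_max * (1 - exp(-lambda * tau)) * exp(-lambda * (t - tau)))
    }
  })
}

#' Effective value of a regulated rate
#'
#' Enhancing regulation scales a rate as k (1 + X_i); repressive regulation
#' as k (1 - X_i), floored at 0 since X_i can exceed 1 for strong signals
#' and a negative rate is unphysical.
#'
#' @param k basal rate, >= 0.
#' @param X_i local polar abundance of the signal protein, >= 0.
#' @param sign `"enhancing"` or `"repressive"`.
#' @return effective rate (vectorized over `X_i`).
#' @export
regulated_rate <- function(k, X_i, sign = c("enhancing", "repressive")) {
  sign <- match.arg(sign)
  if (sign == "enhancing") k * (1 + X_i) else pmax(0, k * (1 - X_i))
}

#' Deterministic right-hand side of the polarity model
#'
#' Time derivatives of the 8 polar abundances (A1, A2, R1, R2, B1, B2,
#' X1, X2). Cytoplasmic pools are implicit (totals of A, B, R are 1; the
#' total of X is `X_t`). At each pole i the scenario's target rate is
#' replaced by its regulated value using the *local* polar abundance X_i.
#' The B unbinding term saturates as k_b k_M B_i / (k_M + B_i): unbinding of
#' B slows as polar B accumulates.
#'
#' @param state named numeric vector in [state_names] order.
#' @param params a `polarity_params` vector.
#' @param X_t total signal-protein abundance at this instant.
#' @param scenario a [signal_scenario()] naming the regulated rate, or
#'   `NULL` for the unregulated model.
#' @return numeric vector of 8 time derivatives (min^-1).
#' @export
polarity_rhs <- function(state, params, X_t = 0, scenario = NULL) {
  A <- state[1:2]; R <- state[3:4]; B <- state[5:6]; X <- state[7:8]
  Acyt <- 1 - A[1] - A[2]
  Rcyt <- 1 - R[1] - R[2]
  Bcyt <- 1 - B[1] - B[2]
  Xcyt <- X_t - X[1] - X[2]
  out <- numeric(8)
  for (i in 1:2) {
    k <- pole_rates(params, scenario, X[i])
    dA <- k[["k_rA"]] * Acyt * R[i] - k[["k_a"]] * A[i] -
      k[["k_ba"]] * A[i] * B[i]^2
    dR <- Rcyt * (k[["k_R"]] + k[["k_bR"]] * B[i]) - k[["k_r"]] * R[i]
    den <- k[["k_M"]] + B[i]
    sat <- if (den > 0) k[["k_b"]] * k[["k_M"]] * B[i] / den else 0
    dB <- Bcyt * (k[["k_B"]] + k[["k_bB"]] * B[i]) - sat -
      k[["k_ab"]] * A[i] * B[i]^2
    dX <- params[["k_X"]] * Xcyt * B[i] - params[["k_x"]] * X[i]
    out[c(i, 2 + i, 4 + i)] <- c(dA, dR, dB)
    out[6 + i] <- dX
  }
  names(out) <- state_names
  out
}

# Core rates at one pole with the scenario's target substituted by its
# regulated value for local signal abundance X_i.
pole_rates <- function(params, scenario, X_i) {
  k <- unclass(params)[core_rate_names]
  if (!is.null(scenario) && !is.null(scenario$target)) {
    k[[scenario$target]] <- regulated_rate(k[[scenario$target]], X_i,
                                           scenario$sign)
  }
  k
}

# Pole-exchange permutation of a state (or derivative) vector.
pole_swap <- function(state) {
  state[c(2, 1, 4, 3, 6, 5, 8, 7)]
}

#' Integrate the deterministic model
#'
#' Solves the ODE system with an adaptive stiff-capable integrator (lsoda),
#' piecewise on the sub-intervals where the signal definition changes
#' (before / during / after the pulse), chaining final states as initial
#' conditions so edge discontinuities are never stepped over.
#'
#' @param initial named state vector ([state_names] order).
#' @param params a `polarity_params` vector.
#' @param scenario a [signal_scenario()] or `NULL` (no signal).
#' @param t_span numeric length-2, start and end time in minutes (start >= 0).
#' @param dt_sample output sampling interval, min.
#' @param rtol,atol solver tolerances.
#' @return a `polarity_trajectory` data frame with columns `time`, the 8
#'   state variables, and `X_t`.
#' @export
integrate_deterministic <- function(initial, params, scenario = NULL,
                                    t_span = c(0, 30), dt_sample = 0.01,
                                    rtol = 1e-8, atol = 1e-10) {
  validate_parameters(params)
  stopifnot(length(t_span) == 2, t_span[1] < t_span[2], t_span[1] >= 0)
  breaks <- t_span
  if (!is.null(scenario) && scenario$tau > t_span[1] &&
      scenario$tau < t_span[2]) {
    breaks <- c(t_span[1], scenario$tau, t_span[2])
  }
  y <- unname(initial[state_names])
  derivs <- function(t, y, parms) {
    list(polarity_rhs(y, params, signal_profile(t, scenario), scenario))
  }
  pieces <- vector("list", length(breaks) - 1)
  for (seg in seq_len(length(breaks) - 1)) {
    t0 <- breaks[seg]; t1 <- breaks[seg + 1]
    # project the chained state onto the new signal bound: when the total
    # X_t drops at an edge, the polar signal protein cannot exceed it
    y <- unname(clip_state(y, signal_profile(t0, scenario))[state_names])
    times <- unique(c(seq(t0, t1, by = dt_sample), t1))
    # signal value is constant or smooth strictly inside a segment; sample
    # X_t just inside the left edge so step plateaus are represented exactly
    sol <- tryCatch(
      deSolve::lsoda(y, times, derivs, parms = NULL, rtol = rtol, atol = atol),
      warning = function(w) stop(sprintf(
        "integrator failure on [%g, %g]: %s", t0, t1, conditionMessage(w)))
    )
    y <- unname(sol[nrow(sol), -1])
    df <- as.data.frame(sol)
    names(df) <- c("time", state_names)
    # the shared boundary sample is reported from the *following* segment,
    # whose initial state has been projected onto the new signal bound
    if (seg < length(breaks) - 1) df <- df[-nrow(df), , drop = FALSE]
    pieces[[seg]] <- df
  }
  traj <- do.call(rbind, pieces)
  rownames(traj) <- NULL
  traj$X_t <- signal_profile(traj$time, scenario)
  structure(traj, class = c("polarity_trajectory", "data.frame"),
            params = params, scenario = scenario)
}

#' Polarity time series of a trajectory
#'
#' @param traj a `polarity_trajectory`.
#' @param species `"A"`, `"B"` or `"R"`.
#' @return numeric vector of omega values aligned with `traj$time`.
#' @export
trajectory_polarity <- function(traj, species = "A") {
  species <- match.arg(species, c("A", "B", "R"))
  polarity(traj[[paste0(species, "1")]], traj[[paste0(species, "2")]])
}

#' Relax the unsignaled model to a polarized fixed point
#'
#' Starts from a uniform distribution of each species (one third at each
#' pole and in the cytoplasm) with a small extra amount of the antagonist B
#' seeded at one pole, integrates the no-signal model until the right-hand
#' side infinity norm falls below `tol`, and polishes the endpoint with a
#' Newton step. The symmetric configuration is dynamically invariant, so
#' the seed asymmetry is what selects a basin; the returned state is then
#' reflected, if needed, so that the polarity marker's omega_A matches the
#' requested orientation (exact pole-exchange symmetry makes the reflection
#' a fixed point too).
#'
#' @param params a `polarity_params` vector.
#' @param seed_asymmetry extra B fraction seeded at one pole (default 0.01).
#' @param orientation `"pole1"` (omega_A > 0) or `"pole2"`.
#' @param tol convergence threshold on the rhs infinity norm.
#' @param t_cap maximum integration time, min.
#' @return a named state vector at the polarized fixed point.
#' @export
relax_to_polarized <- function(params, seed_asymmetry = 0.01,
                               orientation = c("pole1", "pole2"),
                               tol = 1e-8, t_cap = 1000) {
  orientation <- match.arg(orientation)
  validate_parameters(params)
  if (seed_asymmetry <= 0) {
    stop("seed_asymmetry must be > 0: the symmetric manifold is invariant")
  }
  y <- c(A1 = 1/3, A2 = 1/3, R1 = 1/3, R2 = 1/3,
         B1 = 1/3 + seed_asymmetry, B2 = 1/3, X1 = 0, X2 = 0)
  derivs <- function(t, y, parms) list(polarity_rhs(y, params))
  t_done <- 0; chunk <- 50
  repeat {
    sol <- deSolve::lsoda(unname(y), c(0, chunk), derivs, parms = NULL,
                          rtol = 1e-10, atol = 1e-12)
    y <- sol[nrow(sol), -1]
    names(y) <- state_names
    t_done <- t_done + chunk
    r <- max(abs(polarity_rhs(y, params)))
    if (r < 1e-5 || t_done >= t_cap) break
  }
  y <- newton_polish(y, params, X_t = 0, scenario = NULL, tol = tol)
  if (max(abs(polarity_rhs(y, params))) > tol) {
    stop("not bistable: no convergence to a fixed point within the time cap")
  }
  if (abs(polarity(y[["A1"]], y[["A2"]])) < 0.05) {
    stop("not bistable: relaxation converged to a symmetric state")
  }
  want <- if (orientation == "pole1") 1 else -1
  if (sign(y[["A1"]] - y[["A2"]]) != want) {
    y <- pole_swap(y)
    names(y) <- state_names
  }
  y
}

# Newton refinement of a near-fixed-point state (finite-difference Jacobian).
newton_polish <- function(state, params, X_t = 0, scenario = NULL,
                          tol = 1e-10, max_iter = 50) {
  y <- unname(state[state_names])
  for (it in seq_len(max_iter)) {
    f <- polarity_rhs(y, params, X_t, scenario)
    if (max(abs(f)) < tol) break
    J <- fd_jacobian(y, params, X_t, scenario)
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step)) break
    # damp to keep the iterate inside the physical region
    alpha <- 1
    repeat {
      y_new <- y + alpha * step
      ok <- all(y_new > -1e-9) &&
        y_new[1] + y_new[2] <= 1 + 1e-9 &&
        y_new[3] + y_new[4] <= 1 + 1e-9 &&
        y_new[5] + y_new[6] <= 1 + 1e-9
      if (ok || alpha < 1e-4) break
      alpha <- alpha / 2
    }
    if (max(abs(polarity_rhs(y_new, params, X_t, scenario))) >= max(abs(f)) &&
        it > 1) break
    y <- y_new
  }
  names(y) <- state_names
  y
}

# Central finite-difference Jacobian of the rhs at a state.
fd_jacobian <- function(state, params, X_t = 0, scenario = NULL, h = 1e-7) {
  y <- unname(state[1:8])
  J <- matrix(0, 8, 8)
  for (j in 1:8) {
    yp <- y; ym <- y
    yp[j] <- yp[j] + h; ym[j] <- ym[j] - h
    J[, j] <- (polarity_rhs(yp, params, X_t, scenario) -
               polarity_rhs(ym, params, X_t, scenario)) / (2 * h)
  }
  J
}

#' Cytoplasmic mixing timescale
#'
#' The time L^2 / (2 D) for a cytoplasmic protein to explore a cell of
#' length L by diffusion; the three-compartment treatment assumes this is
#' fast compared to the polarity kinetics.
#'
#' @param L cell length, micrometres.
#' @param D diffusion coefficient, micrometres^2 per second.
#' @return mixing time in seconds.
#' @examples
#' mixing_timescale(6, 10)  # 1.8 s
#' @export
mixing_timescale <- function(L, D) {
  stopifnot(L >= 0, D > 0)
  L^2 / (2 * D)
}
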