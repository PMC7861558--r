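# Langevin extension: state-dependent (multiplicative) or white noise,
# integrated with a fixed-step Euler-Maruyama scheme with boundary clipping.
# The per-step operations are defined here in R; long trajectories and
# ensembles run through the compiled engine (src/em_engine.cpp), which is
# tested against the R definitions.

#' Configuration of the Langevin noise model
#'
#' Noise variance scales as 1/N, where N is an effective copy-number
#' parameter; the deterministic model is recovered as N grows. In
#' multiplicative mode the noise strength of each equation is the sum of the
#' absolute fluxes of that equation at the current state; in white mode the
#' same sums are evaluated at the fixed uniform reference state
#' (1/3, ..., 1/3, X_t/3, X_t/3).
#'
#' @param N effective copy number, > 0.
#' @param dt Euler-Maruyama step, min (default 1e-4).
#' @param seed integer seed for the random stream. Realization r of an
#'   ensemble uses an independent substream keyed by (seed, r), so ensemble
#'   estimates do not depend on evaluation order.
#' @param mode `"multiplicative"` or `"white"`.
#' @return an object of class `noise_config`.
#' @export
noise_config <- function(N, dt = 1e-4, seed = 1L,
                         mode = c("multiplicative", "white")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(N), N > 0, is.numeric(dt), dt > 0)
  structure(list(N = N, dt = dt, seed = as.integer(seed), mode = mode),
            class = "noise_config")
}

#' Noise strengths of the Langevin model
#'
#' The 8 per-equation noise strengths f: in multiplicative mode each is the
#' sum of the absolute values of the flux terms of the corresponding rate
#' equation (with the scenario's regulated rate substituted, using the local
#' X_i); in white mode the same expressions are evaluated at the uniform
#' reference state, so f depends only on X_t.
#'
#' @inheritParams polarity_rhs
#' @param mode `"multiplicative"` or `"white"`.
#' @return nonnegative numeric vector of 8 noise strengths.
#' @export
noise_strengths <- function(state, params, X_t = 0, scenario = NULL,
                            mode = c("multiplicative", "white")) {
  mode <- match.arg(mode)
  if (mode == "white") {
    state <- c(1/3, 1/3, 1/3, 1/3, 1/3, 1/3, X_t / 3, X_t / 3)
  }
  A <- state[1:2]; R <- state[3:4]; B <- state[5:6]; X <- state[7:8]
  Acyt <- 1 - A[1] - A[2]
  Rcyt <- 1 - R[1] - R[2]
  Bcyt <- 1 - B[1] - B[2]
  Xcyt <- X_t - X[1] - X[2]
  f <- numeric(8)
  for (i in 1:2) {
    k <- pole_rates(params, scenario, X[i])
    den <- k[["k_M"]] + B[i]
    sat <- if (den > 0) k[["k_b"]] * k[["k_M"]] * B[i] / den else 0
    f[i] <- abs(k[["k_rA"]] * Acyt * R[i]) + abs(k[["k_a"]] * A[i]) +
      abs(k[["k_ba"]] * A[i] * B[i]^2)
    f[2 + i] <- abs(Rcyt * (k[["k_R"]] + k[["k_bR"]] * B[i])) +
      abs(k[["k_r"]] * R[i])
    f[4 + i] <- abs(Bcyt * (k[["k_B"]] + k[["k_bB"]] * B[i])) + abs(sat) +
      abs(k[["k_ab"]] * A[i] * B[i]^2)
    f[6 + i] <- abs(params[["k_X"]] * Xcyt * B[i]) + abs(params[["k_x"]] * X[i])
  }
  names(f) <- state_names
  f
}

#' One Euler-Maruyama update with boundary clipping
#'
#' x <- x + dt d(x) + sqrt(dt/N) sqrt(f(x)) xi with xi independent standard
#' normals, followed by clipping: components are floored at 0 first; then,
#' if a species' polar sum exceeds its total (1 for A, B, R; X_t for X), the
#' two polar values are rescaled proportionally onto the bound, which avoids
#' biasing either pole. sqrt(f) at f = 0 is 0: a dead channel gets no noise.
#'
#' @inheritParams polarity_rhs
#' @param dt time step, min.
#' @param noise a [noise_config()].
#' @param xi optional vector of 8 standard-normal draws (drawn from the
#'   session RNG when omitted); pass `rep(0, 8)` for a deterministic Euler
#'   step.
#' @return the updated named state vector.
#' @export
euler_maruyama_step <- function(state, dt, params, scenario = NULL, X_t = 0,
                                noise, xi = NULL) {
  if (is.null(xi)) xi <- rnorm(8)
  d <- polarity_rhs(state, params, X_t, scenario)
  f <- noise_strengths(state, params, X_t, scenario, noise$mode)
  y <- unname(state[state_names]) + dt * d + sqrt(dt / noise$N) * sqrt(f) * xi
  clip_state(y, X_t)
}

#' Project a proposed state back into the physical region
#'
#' @param state numeric vector of 8 components (possibly invalid).
#' @param X_t current total signal abundance (bound for X1 + X2).
#' @return named valid state vector.
#' @export
clip_state <- function(state, X_t = 0) {
  y <- pmax(unname(state[1:8]), 0)
  totals <- c(1, 1, 1, X_t)
  for (s in 1:4) {
    i <- 2 * s - 1
    tot <- totals[s]
    sum_s <- y[i] + y[i + 1]
    if (sum_s > tot) {
      y[i:(i + 1)] <- if (sum_s > 0) y[i:(i + 1)] * (tot / sum_s) else 0
    }
  }
  names(y) <- state_names
  y
}

#' Simulate a stochastic trajectory
#'
#' Fixed-step Euler-Maruyama integration through the compiled engine, with
#' the same signal phasing as the deterministic protocol. Reproducible:
#' identical `(seed, dt)` give bitwise-identical trajectories, regardless of
#' the session RNG.
#'
#' @inheritParams integrate_deterministic
#' @param noise a [noise_config()].
#' @param sample_interval recording interval, min (must be a multiple of
#'   `noise$dt`).
#' @return a `polarity_trajectory` data frame (`time`, 8 states, `X_t`).
#' @export
simulate_stochastic <- function(initial, params, scenario = NULL,
                                t_span = c(0, 30), noise,
                                sample_interval = 0.01) {
  validate_parameters(params)
  stopifnot(inherits(noise, "noise_config"),
            t_span[1] >= 0, t_span[2] > t_span[1])
  stride <- round(sample_interval / noise$dt)
  stopifnot(stride >= 1)
  sc <- scenario_for_engine(scenario)
  m <- cpp_em_simulate(unname(initial[state_names]),
                       unclass(params)[c(core_rate_names, "k_X", "k_x")],
                       sc$target, sc$sign, sc$X_max, sc$tau, sc$lambda,
                       t_span[1], t_span[2], noise$dt, noise$N,
                       as.integer(noise$seed),
                       if (noise$mode == "white") 1L else 0L,
                       as.integer(stride))
  traj <- as.data.frame(m)
  names(traj) <- c("time", state_names, "X_t")
  structure(traj, class = c("polarity_trajectory", "data.frame"),
            params = params, scenario = scenario, noise = noise)
}

# Encode a scenario for the C++ engine: 0-based target index (-1 = none),
# sign +/-1, lambda <= 0 meaning step edges.
scenario_for_engine <- function(scenario) {
  if (is.null(scenario)) {
    return(list(target = -1L, sign = 1L, X_max = 0, tau = 1, lambda = -1))
  }
  list(target = if (is.null(scenario$target)) -1L else
         as.integer(match(scenario$target, core_rate_names) - 1L),
       sign = if (scenario$sign == "enhancing") 1L else -1L,
       X_max = scenario$X_max,
       tau = scenario$tau,
       lambda = if (is.infinite(scenario$lambda)) -1 else scenario$lambda)
}

# Ensemble of realizations: per-realization switch summaries plus endpoint
# states, all computed in compiled code. Returns a list of matrices.
em_ensemble <- function(initial, params, scenario, t_end, noise,
                        n_realizations, t_mark = NULL, t_pre = 0) {
  sc <- scenario_for_engine(scenario)
  if (is.null(t_mark)) t_mark <- min(sc$tau, t_end)
  res <- cpp_em_ensemble(unname(initial[state_names]),
                         unclass(params)[c(core_rate_names, "k_X", "k_x")],
                         sc$target, sc$sign, sc$X_max, sc$tau, sc$lambda,
                         t_end, noise$dt, noise$N,
                         as.integer(noise$seed),
                         if (noise$mode == "white") 1L else 0L,
                         as.integer(n_realizations), t_mark, t_pre)
  colnames(res$final) <- state_names
  colnames(res$at_mark) <- state_names
  res
}
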