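# Phase-space machinery: multi-start fixed-point finding with stability,
# basin labeling, stochastic separatrix estimation with linear-discriminant
# boundaries, and limit-cycle extraction.

#' Find fixed points of the model at a fixed signal level
#'
#' Multi-start damped-Newton root finding on the 8-dimensional right-hand
#' side with the total signal abundance held at the scenario's plateau
#' value (or 0 without a scenario). Starts are `n_starts` random valid
#' states plus the symmetric uniform state and, when the no-signal model is
#' bistable, the two relaxed polarized states. Converged roots are merged
#' at an infinity-norm tolerance of 1e-5 and classified as stable when all
#' Jacobian eigenvalues have negative real part.
#'
#' @param params a `polarity_params` vector.
#' @param scenario a [signal_scenario()] whose plateau `X_max` is held
#'   constant, or `NULL` for the unsignaled model.
#' @param n_starts number of random starting states.
#' @param seed seed for the random starts (session RNG untouched).
#' @param include_relaxed also seed from the two no-signal polarized states.
#' @return a `fixed_point_set`: list with `points` (matrix, one row per
#'   fixed point), `residual`, `stable`, `symmetric`, `max_re_eigen`.
#' @export
find_fixed_points <- function(params, scenario = NULL, n_starts = 20,
                              seed = 1L, include_relaxed = TRUE) {
  validate_parameters(params)
  X_t <- if (is.null(scenario)) 0 else scenario$X_max
  starts <- with_local_seed(seed, {
    lapply(seq_len(n_starts), function(i) random_state(X_t))
  })
  starts <- c(starts,
              list(c(1/3, 1/3, 1/3, 1/3, 1/3, 1/3, X_t / 3, X_t / 3)))
  if (include_relaxed) {
    rel <- tryCatch(relax_to_polarized(params, orientation = "pole1"),
                    error = function(e) NULL)
    if (!is.null(rel)) starts <- c(starts, list(unname(rel)),
                                   list(unname(pole_swap(rel))))
  }
  roots <- list()
  for (s in starts) {
    y <- newton_polish(stats::setNames(s, state_names), params, X_t,
                       scenario, tol = 1e-11, max_iter = 80)
    if (max(abs(polarity_rhs(y, params, X_t, scenario))) > 1e-8) next
    if (any(y < -1e-7) || y[1] + y[2] > 1 + 1e-7 ||
        y[3] + y[4] > 1 + 1e-7 || y[5] + y[6] > 1 + 1e-7 ||
        y[7] + y[8] > X_t + 1e-7) next
    dup <- any(vapply(roots, function(r) max(abs(r - y)) < 1e-5, logical(1)))
    if (!dup) roots[[length(roots) + 1]] <- y
  }
  if (!length(roots)) {
    return(structure(list(points = matrix(numeric(0), 0, 8,
                                          dimnames = list(NULL, state_names)),
                          residual = numeric(0), stable = logical(0),
                          symmetric = logical(0),
                          max_re_eigen = numeric(0), X_t = X_t),
                     class = "fixed_point_set"))
  }
  pts <- do.call(rbind, roots)
  colnames(pts) <- state_names
  res <- apply(pts, 1, function(y)
    max(abs(polarity_rhs(y, params, X_t, scenario))))
  max_re <- apply(pts, 1, function(y) {
    J <- fd_jacobian(y, params, X_t, scenario)
    max(Re(eigen(J, only.values = TRUE)$values))
  })
  sym <- apply(pts, 1, function(y) max(abs(y - pole_swap(y))) < 1e-6)
  structure(list(points = pts, residual = res, stable = max_re < 0,
                 symmetric = sym, max_re_eigen = max_re, X_t = X_t),
            class = "fixed_point_set")
}

random_state <- function(X_t) {
  part <- function(total) {
    u <- runif(3)
    total * u[1:2] / sum(u)
  }
  a <- part(1); r <- part(1); b <- part(1); x <- part(X_t)
  c(a, r, b, x)
}

#' @export
print.fixed_point_set <- function(x, ...) {
  n <- nrow(x$points)
  cat(sprintf("<fixed_point_set> %d point(s) at X_t = %g\n", n, x$X_t))
  if (n) {
    w <- polarity(x$points[, "A1"], x$points[, "A2"])
    for (i in seq_len(n)) {
      cat(sprintf("  omega_A = %+.3f | %s | %s | residual %.1e\n",
                  w[i], if (x$stable[i]) "stable" else "unstable",
                  if (x$symmetric[i]) "symmetric" else "polarized",
                  x$residual[i]))
    }
  }
  invisible(x)
}

#' Which basin of attraction a state belongs to
#'
#' Integrates the no-signal deterministic model from `state` until the
#' trajectory comes within `tol` (infinity norm) of one of the stable fixed
#' points, and reports which. States on the invariant symmetric manifold
#' (or not resolved by `t_max`) give `"unresolved"`.
#'
#' @param state named state vector.
#' @param params a `polarity_params` vector.
#' @param fps optional precomputed `fixed_point_set` at X_t = 0.
#' @param t_max time budget, min.
#' @param tol matching tolerance.
#' @return `"pole1"`, `"pole2"` or `"unresolved"`.
#' @export
basin_label <- function(state, params, fps = NULL, t_max = 200, tol = 1e-4) {
  if (is.null(fps)) fps <- find_fixed_points(params)
  stable <- fps$points[fps$stable & !fps$symmetric, , drop = FALSE]
  if (nrow(stable) != 2) stop("system is not bistable at X_t = 0")
  labels <- ifelse(stable[, "A1"] > stable[, "A2"], "pole1", "pole2")
  y <- unname(state[state_names])
  derivs <- function(t, y, parms) list(polarity_rhs(y, params))
  t_done <- 0; chunk <- 10
  while (t_done < t_max) {
    sol <- deSolve::lsoda(y, c(0, chunk), derivs, parms = NULL,
                          rtol = 1e-8, atol = 1e-10)
    y <- unname(sol[nrow(sol), -1])
    t_done <- t_done + chunk
    d <- apply(stable, 1, function(p) max(abs(p - y)))
    if (min(d) < tol) return(labels[which.min(d)])
  }
  "unresolved"
}

#' Estimate the no-signal separatrix from primed stochastic samples
#'
#' Simulates `n_samples` Langevin realizations with the signal applied
#' until t = tau, labels each endpoint by the basin it falls into once the
#' signal is removed, and fits a linear discriminant to each requested 2D
#' projection of the pole-difference coordinates (A1-A2, B1-B2, R1-R2).
#' The fitted class boundary is the estimate of the separatrix projection.
#'
#' @param params a `polarity_params` vector.
#' @param scenario a [signal_scenario()] that primes the system.
#' @param noise a [noise_config()] (reference protocol: N = 1e3).
#' @param n_samples number of stochastic realizations.
#' @param projections list of length-2 character vectors among
#'   `"A"`, `"B"`, `"R"`.
#' @param initial optional relaxed polarized state.
#' @return a list: `points` (data frame with `dA`, `dB`, `dR`, `label`),
#'   `fractions` (class shares), and `boundaries` (per projection: `w`
#'   normal vector, `threshold` such that the boundary is w . x =
#'   threshold, `accuracy` leave-one-out accuracy); `boundaries` entries
#'   are `NULL` when the endpoint cloud is single-class.
#' @export
estimate_separatrix_projection <- function(params, scenario, noise,
                                           n_samples = 200,
                                           projections = list(c("A", "B"),
                                                              c("A", "R"),
                                                              c("B", "R")),
                                           initial = NULL) {
  if (is.null(initial)) {
    initial <- relax_to_polarized(params, orientation = "pole1")
  }
  res <- em_ensemble(initial, params, scenario, t_end = scenario$tau,
                     noise = noise, n_realizations = n_samples,
                     t_mark = scenario$tau)
  fps <- find_fixed_points(params)
  labels <- apply(res$at_mark, 1, function(y) {
    basin_label(stats::setNames(y, state_names), params, fps = fps)
  })
  pts <- data.frame(dA = res$at_mark[, "A1"] - res$at_mark[, "A2"],
                    dB = res$at_mark[, "B1"] - res$at_mark[, "B2"],
                    dR = res$at_mark[, "R1"] - res$at_mark[, "R2"],
                    label = labels)
  usable <- pts$label != "unresolved"
  frac <- table(factor(pts$label, c("pole1", "pole2", "unresolved"))) /
    nrow(pts)
  boundaries <- stats::setNames(vector("list", length(projections)),
                                vapply(projections, paste, character(1),
                                       collapse = ""))
  two_class <- length(unique(pts$label[usable])) == 2
  if (two_class) {
    for (j in seq_along(projections)) {
      pr <- projections[[j]]
      cols <- paste0("d", pr)
      dat <- pts[usable, c(cols, "label")]
      fit <- MASS::lda(stats::as.formula(paste("label ~", cols[1], "+",
                                               cols[2])), data = dat)
      w <- fit$scaling[, 1]
      z <- as.matrix(dat[, cols]) %*% w
      # decision threshold along the discriminant axis: where the posterior
      # flips between the two classes
      zm <- range(z)
      post_diff <- function(z0) {
        nd <- stats::setNames(data.frame(z0[1], z0[2]), cols)
        p <- predict(fit, nd)$posterior
        p[1] - p[2]
      }
      dirv <- w / sqrt(sum(w^2))
      g <- function(s) {
        nd <- stats::setNames(as.data.frame(t(dirv * s)), cols)
        p <- predict(fit, nd)$posterior
        p[1, 1] - p[1, 2]
      }
      thr <- tryCatch(uniroot(g, interval = zm / sqrt(sum(w^2)),
                              extendInt = "yes")$root * sqrt(sum(w^2)),
                      error = function(e) mean(z))
      cvfit <- MASS::lda(stats::as.formula(paste("label ~", cols[1], "+",
                                                 cols[2])), data = dat,
                         CV = TRUE)
      boundaries[[j]] <- list(w = w, threshold = thr,
                              accuracy = mean(cvfit$class == dat$label))
    }
  }
  list(points = pts, fractions = as.numeric(frac),
       class_table = frac, boundaries = boundaries,
       two_class = two_class)
}

#' Extract the limit cycle under a persistent signal
#'
#' Integrates the deterministic model with the signal applied throughout,
#' discards the transient, and returns one period of the cycle delimited
#' by successive upward crossings of omega_A = 0, together with the period
#' and (optionally) basin labels of points along the cycle after signal
#' removal - the cycle's intersection with the no-signal separatrix is
#' where those labels change.
#'
#' @inheritParams classify_persistent_signal
#' @param n_labels number of points along the cycle to basin-label after
#'   signal removal (0 to skip).
#' @return a list: `cycle` (data frame, one period), `period` (min),
#'   `labels` (per labeled point), `label_times` (times within the cycle).
#' @export
extract_limit_cycle <- function(params, scenario, T_long = 100,
                                initial = NULL, n_labels = 24) {
  if (is.null(initial)) {
    initial <- relax_to_polarized(params, orientation = "pole1")
  }
  cls <- classify_persistent_signal(params, scenario, T_long = T_long,
                                    initial = initial)
  if (as.character(cls) != "oscillatory") {
    stop("persistent-signal dynamics is not oscillatory (", cls, ")")
  }
  sc <- scenario
  sc$tau <- T_long + 1
  traj <- integrate_deterministic(initial, params, sc,
                                  t_span = c(0, T_long), dt_sample = 0.005)
  w <- trajectory_polarity(traj, "A")
  keep <- traj$time >= T_long / 2
  t_k <- traj$time[keep]; w_k <- w[keep]
  cr <- zero_crossing_times(t_k, w_k)
  up <- cr[vapply(cr, function(tc) {
    i <- findInterval(tc, t_k)
    w_k[min(i + 1, length(w_k))] > w_k[i]
  }, logical(1))]
  if (length(up) < 2) stop("fewer than two upward omega_A crossings")
  t0 <- up[length(up) - 1]; t1 <- up[length(up)]
  cyc <- traj[traj$time >= t0 & traj$time <= t1, , drop = FALSE]
  out <- list(cycle = cyc, period = t1 - t0)
  if (n_labels > 0) {
    fps <- find_fixed_points(params)
    idx <- unique(round(seq(1, nrow(cyc), length.out = n_labels)))
    lab <- vapply(idx, function(i) {
      y <- as.numeric(cyc[i, state_names])
      basin_label(stats::setNames(y, state_names), params, fps = fps)
    }, character(1))
    out$labels <- lab
    out$label_times <- cyc$time[idx] - t0
  }
  out
}
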