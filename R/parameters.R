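# Parameter sets, regulation scenarios and their plain-text serialization.

#' Names of the 11 core kinetic parameters
#'
#' Order is canonical and used everywhere a scenario refers to its regulated
#' rate: recruitment of A by R (`k_rA`), spontaneous unbinding of A (`k_a`),
#' displacement of A by B (`k_ba`), intrinsic binding of B (`k_B`),
#' self-recruitment of B (`k_bB`), spontaneous unbinding of B (`k_b`),
#' saturation abundance of B unbinding (`k_M`), displacement of B by A
#' (`k_ab`), intrinsic binding of R (`k_R`), recruitment of R by B (`k_bR`),
#' and spontaneous unbinding of R (`k_r`).
#'
#' @export
core_rate_names <- c("k_rA", "k_a", "k_ba", "k_B", "k_bB", "k_b", "k_M",
                     "k_ab", "k_R", "k_bR", "k_r")

#' Names of the 8 polar state variables, in canonical order
#' @export
state_names <- c("A1", "A2", "R1", "R2", "B1", "B2", "X1", "X2")

#' Base kinetic parameter set of the polarity model
#'
#' Returns the 13 rate constants of the core polarity circuit plus the
#' signal-protein binding/unbinding rates. Units are min^-1 except `k_M`,
#' which is a dimensionless abundance scale. With these values and no signal
#' the model is bistable, with two mirror-image polarized fixed points.
#'
#' @return A named numeric vector of class `polarity_params` with elements
#'   `k_rA`, `k_a`, `k_ba`, `k_B`, `k_bB`, `k_b`, `k_M`, `k_ab`, `k_R`,
#'   `k_bR`, `k_r` (core) and `k_X`, `k_x` (signal protein).
#' @examples
#' p <- base_parameters()
#' p["k_ab"]
#' @export
base_parameters <- function() {
  p <- c(k_rA = 400, k_a = 2, k_ba = 400, k_B = 2, k_bB = 30, k_b = 2.8,
         k_M = 0.3, k_ab = 15, k_R = 0.1, k_bR = 1.5, k_r = 0.4,
         k_X = 20, k_x = 3)
  class(p) <- "polarity_params"
  p
}

#' Randomly perturbed parameter set
#'
#' Multiplies every rate of the base set by an independent uniform draw on
#' \[0.5, 1.5\], the perturbation protocol used for robustness checks.
#' Reproducible given `seed`; the global RNG state is left untouched.
#'
#' @param seed integer seed for the multipliers.
#' @param multipliers optional named numeric vector of explicit multipliers
#'   (values in \[0.5, 1.5\]) overriding the random draw, e.g. to reproduce a
#'   published perturbed set exactly.
#' @return A `polarity_params` vector.
#' @export
perturbed_parameters <- function(seed = 1L, multipliers = NULL) {
  base <- base_parameters()
  if (is.null(multipliers)) {
    multipliers <- with_local_seed(seed, runif(length(base), 0.5, 1.5))
    names(multipliers) <- names(base)
  } else {
    stopifnot(all(names(base) %in% names(multipliers)))
    multipliers <- multipliers[names(base)]
  }
  p <- unclass(base) * multipliers
  class(p) <- "polarity_params"
  p
}

validate_parameters <- function(params) {
  params <- unclass(params)
  stopifnot(is.numeric(params),
            all(c(core_rate_names, "k_X", "k_x") %in% names(params)))
  if (any(params < 0)) stop("all rate constants must be >= 0")
  if (params[["k_M"]] <= 0) stop("k_M must be > 0 (appears in a denominator)")
  invisible(params)
}

# Evaluate `expr` under a private RNG stream; global .Random.seed restored.
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = .GlobalEnv)) {
    old <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old, envir = .GlobalEnv))
  } else {
    on.exit(rm(".Random.seed", envir = .GlobalEnv))
  }
  set.seed(seed)
  expr
}

#' Define a signal-regulation scenario
#'
#' A scenario specifies which core rate the polar signal protein X regulates,
#' the sign of the regulation, and the pulse of total X: amplitude `X_max`
#' applied for duration `tau`, with either instantaneous (step) edges or
#' gradual exponential edges of rate `lambda`.
#'
#' @param target one of [core_rate_names], or `NULL` for a pulse that binds
#'   the poles but regulates nothing.
#' @param sign `"enhancing"` (rate becomes k(1 + X_i)) or `"repressive"`
#'   (k(1 - X_i), floored at 0).
#' @param X_max signal amplitude (dimensionless total abundance of X), >= 0.
#' @param tau signal duration in minutes, > 0.
#' @param lambda edge rate in min^-1 for gradual edges, or `Inf` for a step
#'   pulse (the default).
#' @return An object of class `signal_scenario`.
#' @examples
#' sc <- signal_scenario("k_ab", "enhancing", X_max = 4, tau = 1)
#' @export
signal_scenario <- function(target, sign = c("enhancing", "repressive"),
                            X_max, tau, lambda = Inf) {
  sign <- match.arg(sign)
  if (!is.null(target)) target <- match.arg(target, core_rate_names)
  stopifnot(is.numeric(X_max), length(X_max) == 1, X_max >= 0,
            is.numeric(tau), length(tau) == 1, tau > 0,
            is.numeric(lambda), length(lambda) == 1, lambda > 0)
  structure(list(target = target, sign = sign, X_max = X_max,
                 tau = tau, lambda = lambda),
            class = "signal_scenario")
}

#' @export
print.signal_scenario <- function(x, ...) {
  edge <- if (is.infinite(x$lambda)) "step" else sprintf("lambda = %g", x$lambda)
  cat(sprintf("<signal_scenario> %s (%s), X_max = %g, tau = %g min, %s edges\n",
              if (is.null(x$target)) "<none>" else x$target,
              x$sign, x$X_max, x$tau, edge))
  invisible(x)
}

scenario_id <- function(target, sign) {
  paste0(target, if (sign == "enhancing") "+" else "-")
}

#' Enumerate the 22 candidate regulation scenarios
#'
#' The Cartesian product of the 11 core rates with the two regulation signs,
#' in canonical order. Amplitude and duration are left open: these are
#' scenario *families* to be swept over (tau, X_max).
#'
#' @return A data frame with columns `target`, `sign` and the canonical `id`
#'   (e.g. `"k_ab+"`), 22 rows.
#' @export
enumerate_scenarios <- function() {
  grid <- expand.grid(sign = c("enhancing", "repressive"),
                      target = core_rate_names,
                      stringsAsFactors = FALSE)[, c("target", "sign")]
  grid$id <- mapply(scenario_id, grid$target, grid$sign)
  rownames(grid) <- NULL
  grid
}

#' Read/write a flat key-value configuration file
#'
#' Configurations use a single flat namespace (`model.*` for rates,
#' `signal.*` for the pulse, `noise.*` for the Langevin settings) in a
#' plain-text `key: value` format, one entry per line.
#'
#' @param config named list of scalar values.
#' @param path file path.
#' @return `read_config` returns a named list with numeric values parsed.
#' @export
write_config <- function(config, path) {
  stopifnot(!is.null(names(config)), all(nzchar(names(config))))
  vals <- vapply(config, function(v) {
    if (is.numeric(v)) format(v, digits = 17) else as.character(v)
  }, character(1))
  writeLines(paste0(names(config), ": ", vals), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  m <- regmatches(lines, regexec("^\\s*([^:]+?)\\s*:\\s*(.*?)\\s*$", lines))
  bad <- vapply(m, length, integer(1)) != 3
  if (any(bad)) stop("malformed config line(s): ", paste(lines[bad], collapse = "; "))
  keys <- vapply(m, `[`, character(1), 2)
  vals <- vapply(m, `[`, character(1), 3)
  out <- lapply(vals, function(v) {
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(out) <- keys
  out
}

#' Serialize a parameter set or scenario into the flat config namespace
#' @param params a `polarity_params` vector.
#' @param scenario a `signal_scenario`.
#' @return a named list suitable for [write_config()].
#' @export
params_to_config <- function(params) {
  validate_parameters(params)
  out <- as.list(unclass(params))
  names(out) <- paste0("model.", names(out))
  out
}

#' @rdname params_to_config
#' @export
scenario_to_config <- function(scenario) {
  stopifnot(inherits(scenario, "signal_scenario"))
  list(`signal.target` = if (is.null(scenario$target)) "none" else scenario$target,
       `signal.sign` = scenario$sign,
       `signal.X_max` = scenario$X_max,
       `signal.tau` = scenario$tau,
       `signal.lambda` = if (is.infinite(scenario$lambda)) "step" else scenario$lambda)
}

#' Reconstruct objects from a parsed flat config
#' @param config named list as returned by [read_config()].
#' @return the corresponding object.
#' @export
config_to_params <- function(config) {
  keys <- paste0("model.", names(base_parameters()))
  stopifnot(all(keys %in% names(config)))
  p <- vapply(config[keys], as.numeric, numeric(1))
  names(p) <- sub("^model\\.", "", keys)
  class(p) <- "polarity_params"
  validate_parameters(p)
  p
}

#' @rdname config_to_params
#' @export
config_to_scenario <- function(config) {
  lam <- config[["signal.lambda"]]
  target <- config[["signal.target"]]
  signal_scenario(
    target = if (identical(target, "none")) NULL else target,
    sign = config[["signal.sign"]],
    X_max = as.numeric(config[["signal.X_max"]]),
    tau = as.numeric(config[["signal.tau"]]),
    lambda = if (identical(lam, "step")) Inf else as.numeric(lam))
}

# 32-bit polynomial rolling hash over the canonical config text; used to
# stamp output tables with the configuration that produced them.
config_hash <- function(config) {
  config <- config[order(names(config))]
  txt <- paste(names(config),
               vapply(config, function(v) paste(format(v, digits = 17),
                                                collapse = ","),
                      character(1)),
               sep = "=", collapse = ";")
  h <- 5381
  for (b in utf8ToInt(txt)) h <- (h * 33 + b) %% 4294967296
  sprintf("%08x", h)
}
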