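# Result serialization: tidy trajectory tables and long-format phase
# diagrams, each accompanied by a JSON provenance header.

#' Write a trajectory as a tidy CSV table
#'
#' Columns: `time`, the 8 polar abundances, and `X_t`. A JSON sidecar
#' (`<path>.json`) records the parameters, scenario, noise settings, seed
#' and a hash of the configuration that produced the table.
#'
#' @param traj a `polarity_trajectory`.
#' @param path output CSV path.
#' @param header write the JSON provenance sidecar.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, header = TRUE) {
  write.csv(as.data.frame(traj), path, row.names = FALSE)
  if (header) write_provenance(traj, path)
  invisible(path)
}

#' Write a phase diagram as a long-format CSV table
#'
#' One row per (tau, X_max) cell with the scan columns present
#' (deterministic flags and/or stochastic probabilities), plus a JSON
#' provenance sidecar with the grids, scenario family, noise settings and
#' seed.
#'
#' @param pd a `phase_diagram`.
#' @param path output CSV path.
#' @param header write the JSON provenance sidecar.
#' @return `path`, invisibly.
#' @export
write_phase_diagram <- function(pd, path, header = TRUE) {
  df <- as.data.frame(pd)
  df$target <- attr(pd, "target")
  df$sign <- attr(pd, "sign")
  write.csv(df, path, row.names = FALSE)
  if (header) write_provenance(pd, path)
  invisible(path)
}

write_provenance <- function(obj, path) {
  params <- attr(obj, "params")
  noise <- attr(obj, "noise")
  scenario <- attr(obj, "scenario")
  cfg <- list()
  if (!is.null(params)) cfg <- c(cfg, params_to_config(params))
  if (!is.null(scenario)) cfg <- c(cfg, scenario_to_config(scenario))
  if (!is.null(noise)) {
    cfg <- c(cfg, list(noise.N = noise$N, noise.dt = noise$dt,
                       noise.seed = noise$seed, noise.mode = noise$mode))
  }
  header <- list(
    package = "polswitch",
    version = as.character(utils::packageVersion("polswitch")),
    config = cfg,
    config_hash = config_hash(cfg),
    seed = if (!is.null(noise)) noise$seed else NA,
    tau_grid = attr(obj, "tau_grid"),
    xmax_grid = attr(obj, "xmax_grid"))
  jsonlite::write_json(header, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a trajectory table written by [write_trajectory()]
#' @param path CSV path.
#' @return a `polarity_trajectory` data frame.
#' @export
read_trajectory <- function(path) {
  df <- read.csv(path)
  structure(df, class = c("polarity_trajectory", "data.frame"))
}
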