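#' Write a simulation to disk
#'
#' One tidy CSV (one row per controller tick, one column per signal
#' component) plus a JSON metadata sidecar echoing the full configuration
#' and the divergence flag, so a run is reproducible from its outputs.
#'
#' @param sim A [simulate_reach()] result.
#' @param path Output CSV path; the sidecar is written next to it with a
#'   `.json` extension.
#' @return `path`, invisibly.
#' @export
write_reach_csv <- function(sim, path) {
  stopifnot(inherits(sim, "reach_sim"))
  readr::write_csv(sim$signals, path)
  meta <- list(
    controller = sim$controller$type,
    gains = if (!is.null(sim$controller$gains)) unclass(sim$controller$gains),
    lq = if (!is.null(sim$controller$setup))
      list(Q = sim$controller$setup$Q, R = sim$controller$setup$R,
           J = sim$controller$setup$J, K = sim$controller$setup$K),
    task = unclass(sim$task),
    plant = unclass(sim$plant),
    config = unclass(sim$config),
    diverged = sim$diverged,
    divergence_time = sim$divergence_time
  )
  jsonlite::write_json(meta, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

config_schema <- list(
  experiment = "character",
  controllers = "character",
  delay_ms = "numeric",
  td_hat_ms = "numeric",
  durations_s = "numeric",
  J = "numeric",
  dt_ms = "numeric",
  beta_bar = "numeric",
  kp = "numeric"
)

#' Read and validate an experiment configuration
#'
#' Flat key-value YAML describing one packaged experiment. Recognised keys
#' (all optional except `experiment`): `experiment` (one of
#' `single_joint_fast`, `two_joint`, `inertial_change`, `sweep_beta_kp`,
#' `sweep_delay_estimate`), `controllers`, `delay_ms`, `td_hat_ms`,
#' `durations_s`, `J`, `dt_ms`, `beta_bar`, `kp`. Unknown keys and
#' wrongly-typed values are errors. An example lives at
#' `system.file("extdata", "single_joint_fast.yaml", package = "armtdc")`.
#'
#' @param path Path to a YAML file.
#' @return A validated named list.
#' @export
read_experiment_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), names(config_schema))
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (is.null(cfg$experiment)) stop("config must name an `experiment`", call. = FALSE)
  valid <- c("single_joint_fast", "two_joint", "inertial_change",
             "sweep_beta_kp", "sweep_delay_estimate")
  if (!cfg$experiment %in% valid) {
    stop("`experiment` must be one of: ", paste(valid, collapse = ", "),
         call. = FALSE)
  }
  for (k in names(cfg)) {
    want <- config_schema[[k]]
    ok <- switch(want, character = is.character(cfg[[k]]),
                 numeric = is.numeric(cfg[[k]]))
    if (!ok) stop(sprintf("config key `%s` must be %s", k, want), call. = FALSE)
  }
  cfg
}

#' Run an experiment described by a configuration
#'
#' Dispatches a validated configuration (see [read_experiment_config()]) to
#' the corresponding experiment function, converting the config's
#' milliseconds/degrees units to the SI units used internally.
#'
#' @param cfg A named list as returned by [read_experiment_config()].
#' @return The experiment's result tibble.
#' @export
run_experiment <- function(cfg) {
  # each experiment keeps its own dt default unless the config overrides it
  dtargs <- if (!is.null(cfg$dt_ms)) list(dt = cfg$dt_ms / 1000) else list()
  call_with <- function(f, args) do.call(f, c(args, dtargs))
  switch(
    cfg$experiment,
    single_joint_fast = call_with(exp_single_joint_fast, list(
      delay = if (!is.null(cfg$delay_ms)) cfg$delay_ms / 1000 else 0.065,
      controllers = cfg$controllers %||% c("proposed", "ep", "optimal"),
      J = cfg$J %||% 0.0188)),
    two_joint = call_with(exp_two_joint, list(
      durations = cfg$durations_s %||% c(0.5, 1))),
    inertial_change = call_with(exp_inertial_change, list(
      controllers = cfg$controllers %||% c("proposed", "optimal"))),
    sweep_beta_kp = call_with(sweep_beta_kp, list(
      beta = cfg$beta_bar %||% c(5e-3, 7e-3, 1e-2, 1.2e-2, 1.4e-2, 1.7e-2, 2e-2),
      kp = cfg$kp %||% seq(50, 500, by = 50),
      J = cfg$J %||% 0.0188)),
    sweep_delay_estimate = call_with(sweep_delay_estimate, list(
      td_hat = if (!is.null(cfg$td_hat_ms)) cfg$td_hat_ms / 1000
               else c(0.05, 0.06, 0.065, 0.07, 0.08),
      td = if (!is.null(cfg$delay_ms)) cfg$delay_ms / 1000 else 0.065,
      J = cfg$J %||% 0.0188))
  )
}
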