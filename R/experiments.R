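#' Default task and gain catalogue
#'
#' The study conditions used by the packaged experiments: a fast
#' single-joint elbow flexion from 45 to 145 degrees in 0.2 s; a two-joint
#' planar reach from (-0.2, 0.5) m to (0.25, 0.35) m; and an elbow flexion
#' from 50 to 85 degrees in 0.25 s performed with an intermediate inertial
#' load J = 0.165 kg m^2 that is swapped, unannounced, for a 25% lighter
#' (0.12) or heavier (0.205) load.
#'
#' @name experiment-defaults
#' @keywords internal
NULL

fast_task <- function() min_jerk_task(deg2rad(45), deg2rad(145), 0.2)
pinter_task <- function() min_jerk_task(deg2rad(50), deg2rad(85), 0.25)
two_joint_task <- function(duration) {
  min_jerk_task(c(-0.2, 0.5), c(0.25, 0.35), duration, space = "cartesian")
}

fast_controllers <- function(J) {
  list(
    proposed = controller_proposed(tdc_gains(beta_bar = 0.01, kv = 200, kp = 500)),
    ep = controller_ep(ep_gains(p = 0, d = 0.76, t_dp = 0.065, t_dv = 0.025)),
    optimal = controller_optimal(lq_setup(Q = diag(c(10, 10)), R = 2, J = J))
  )
}

inertial_controllers <- function(J_model = 0.165) {
  list(
    proposed = controller_proposed(tdc_gains(beta_bar = 0.15, kv = 25, kp = 150)),
    optimal = controller_optimal(lq_setup(Q = diag(c(500, 500)), R = 2, J = J_model))
  )
}

#' Fast single-joint movement under sensory delay
#'
#' Runs the 45-to-145-degree, 0.2-s elbow flexion under a given feedback
#' delay for each requested controller, with each controller's catalogued
#' gains (proposed: `Kv = 200`, `Kp = 500`, `beta_bar = 0.01`;
#' equilibrium-point: `P = 0`, `D = 0.76` with 65/25 ms loop delays;
#' optimal: `Q = diag(10, 10)`, `R = 2` with the exact plant inertia).
#' The movement starts after a 0.1-s quiescent lead-in and tracking RMSE is
#' evaluated over 0.1-0.3 s.
#'
#' @param delay Sensory feedback delay (s); the controller's delay estimate
#'   is set equal to it.
#' @param controllers Character subset of
#'   `c("proposed", "ep", "optimal")`.
#' @param J Plant inertia (kg m^2). Default 0.0188 (the forearm inertia,
#'   matching the optimal controller's limb model).
#' @param dt Controller sample period (s).
#' @return A tibble with one row per controller: movement metrics plus the
#'   simulation object in the `sim` list-column.
#' @export
exp_single_joint_fast <- function(delay = 0.065,
                                  controllers = c("proposed", "ep", "optimal"),
                                  J = 0.0188, dt = 1e-4) {
  ctrls <- fast_controllers(J)[match.arg(controllers, names(fast_controllers(J)),
                                         several.ok = TRUE)]
  plant <- arm_inertia(J)
  task <- fast_task()
  cfg <- sim_config(dt = dt, horizon = 1, td = delay, td_hat = delay)
  purrr::imap_dfr(ctrls, function(ctrl, name) {
    sim <- simulate_reach(task, ctrl, plant, cfg)
    met <- movement_metrics(sim, window = c(0.1, 0.3))
    dplyr::bind_cols(
      tibble::tibble(controller = name, delay_ms = 1000 * delay),
      met, tibble::tibble(diverged = sim$diverged, sim = list(sim))
    )
  })
}

#' Two-joint reach: interaction-torque compensation
#'
#' Runs the (-0.2, 0.5) m to (0.25, 0.35) m planar reach with the
#' Smith-architecture controller (`beta_bar = diag(0.018, 0.015)`,
#' `Kv = 25 I`, `Kp = 150 I`) for each requested duration, planning a
#' straight minimum-jerk hand path. Faster movements generate larger
#' interaction torques; a controller that compensates them keeps the hand
#' path deviation comparable across speeds.
#'
#' @param durations Movement durations (s).
#' @param controller Optional replacement controller (e.g.
#'   [controller_none()] for an uncontrolled contrast run).
#' @param dt Controller sample period (s).
#' @param settle Extra simulated time after movement end (s).
#' @return Tibble with one row per duration: `max_deviation_mm`,
#'   `endpoint_error_mm`, `diverged`, `sim`.
#' @export
exp_two_joint <- function(durations = c(0.5, 1), controller = NULL,
                          dt = 1e-3, settle = 0.5) {
  plant <- arm_params()
  if (is.null(controller)) {
    controller <- controller_proposed(
      tdc_gains(beta_bar = c(0.018, 0.015), kv = c(25, 25), kp = c(150, 150)))
  }
  purrr::map_dfr(durations, function(Tm) {
    task <- two_joint_task(Tm)
    cfg <- sim_config(dt = dt, horizon = 0.1 + Tm + settle)
    sim <- simulate_reach(task, controller, plant, cfg)
    pm <- if (sim$diverged) {
      tibble::tibble(max_deviation_mm = NA_real_, endpoint_error_mm = NA_real_)
    } else {
      path_metrics(sim)
    }
    dplyr::bind_cols(tibble::tibble(duration_s = Tm), pm,
                     tibble::tibble(diverged = sim$diverged, sim = list(sim)))
  })
}

#' Unexpected inertial load change (equifinality)
#'
#' The 50-to-85-degree, 0.25-s elbow flexion with gains chosen for the
#' intermediate load `J = 0.165` kg m^2 (proposed: `Kv = 25`, `Kp = 150`,
#' `beta_bar = 0.15`; optimal: `Q = diag(500, 500)`, `R = 2`, predictor
#' model fixed at 0.165). The plant inertia is then swapped, without
#' retuning, for the light (ML, 0.12) or heavy (MH, 0.205) load; MM keeps
#' the intermediate load. A controller that estimates the dynamics online
#' converges to the target under all three loads (equifinality); a
#' controller committed to a fixed internal model does not.
#'
#' @param controllers Character subset of `c("proposed", "optimal")`.
#' @param loads Named numeric vector of plant inertias per condition.
#' @param delay Sensory feedback delay (s).
#' @param dt Controller sample period (s).
#' @return Tibble with one row per controller x condition: the condition
#'   label, plant inertia, movement metrics, `diverged`, `sim`.
#' @export
exp_inertial_change <- function(controllers = c("proposed", "optimal"),
                                loads = c(ML = 0.12, MM = 0.165, MH = 0.205),
                                delay = 0.065, dt = 1e-4) {
  ctrls <- inertial_controllers()[match.arg(controllers,
                                            c("proposed", "optimal"),
                                            several.ok = TRUE)]
  task <- pinter_task()
  cfg <- sim_config(dt = dt, horizon = 1, td = delay, td_hat = delay)
  purrr::imap_dfr(ctrls, function(ctrl, name) {
    purrr::imap_dfr(as.list(loads), function(J, cond) {
      sim <- simulate_reach(task, ctrl, arm_inertia(J), cfg)
      met <- movement_metrics(sim)
      dplyr::bind_cols(
        tibble::tibble(controller = name, condition = cond, J = J),
        met, tibble::tibble(diverged = sim$diverged, sim = list(sim))
      )
    })
  })
}

#' Sensitivity sweep over the TDE gain and stiffness
#'
#' Grid of tracking RMSE for the fast single-joint task as `beta_bar` and
#' `Kp` vary, with `Kv = 0.4 Kp` throughout. Divergent cells carry
#' `NA` RMSE and `diverged = TRUE`.
#'
#' @param beta TDE gain values (kg m^2).
#' @param kp Stiffness values (1/s^2).
#' @param delay Feedback delay (s).
#' @param J Plant inertia (kg m^2).
#' @param dt Controller sample period (s).
#' @return A tibble of class `reach_sweep` with columns `beta_bar`, `kp`,
#'   `rmse_deg`, `endpoint_error_deg`, `diverged`.
#' @export
sweep_beta_kp <- function(beta = c(5e-3, 7e-3, 1e-2, 1.2e-2, 1.4e-2, 1.7e-2, 2e-2),
                          kp = seq(50, 500, by = 50),
                          delay = 0.065, J = 0.0188, dt = 1e-4) {
  stopifnot(length(beta) > 0, length(kp) > 0)
  task <- fast_task()
  plant <- arm_inertia(J)
  cfg <- sim_config(dt = dt, horizon = 1, td = delay, td_hat = delay)
  grid <- tidyr::expand_grid(beta_bar = beta, kp = kp)
  res <- purrr::pmap_dfr(grid, function(beta_bar, kp) {
    ctrl <- controller_proposed(tdc_gains(beta_bar, 0.4 * kp, kp))
    sim <- simulate_reach(task, ctrl, plant, cfg)
    if (sim$diverged) {
      tibble::tibble(rmse_deg = NA_real_, endpoint_error_deg = NA_real_,
                     diverged = TRUE)
    } else {
      m <- movement_metrics(sim, window = c(0.1, 0.3))
      tibble::tibble(rmse_deg = m$tracking_rmse_deg,
                     endpoint_error_deg = m$endpoint_error_deg,
                     diverged = FALSE)
    }
  })
  out <- dplyr::bind_cols(grid, res)
  class(out) <- c("reach_sweep", class(out))
  attr(out, "axes") <- c("beta_bar", "kp")
  out
}

#' Sensitivity sweep over the delay estimate
#'
#' Fast single-joint task with the actual feedback delay anchored at
#' `td` while the controller's delay estimate varies: within a range of
#' under- and over-estimates the Smith cancellation degrades gracefully,
#' while a gross mismatch destabilises the loop.
#'
#' @param td_hat Delay-estimate values (s).
#' @param td Actual feedback delay (s).
#' @inheritParams sweep_beta_kp
#' @return A `reach_sweep` tibble: `td_hat_ms`, `stable`,
#'   `endpoint_error_deg`, `rmse_deg`.
#' @export
sweep_delay_estimate <- function(td_hat = c(0.05, 0.06, 0.065, 0.07, 0.08),
                                 td = 0.065, J = 0.0188, dt = 1e-4) {
  task <- fast_task()
  plant <- arm_inertia(J)
  ctrl <- controller_proposed(tdc_gains(0.01, 200, 500))
  res <- purrr::map_dfr(td_hat, function(th) {
    cfg <- sim_config(dt = dt, horizon = 1, td = td, td_hat = th)
    sim <- simulate_reach(task, ctrl, plant, cfg)
    if (sim$diverged) {
      tibble::tibble(td_hat_ms = 1000 * th, stable = FALSE,
                     endpoint_error_deg = NA_real_, rmse_deg = NA_real_)
    } else {
      m <- movement_metrics(sim, window = c(0.1, 0.3))
      tibble::tibble(td_hat_ms = 1000 * th, stable = TRUE,
                     endpoint_error_deg = m$endpoint_error_deg,
                     rmse_deg = m$tracking_rmse_deg)
    }
  })
  class(res) <- c("reach_sweep", class(res))
  attr(res, "axes") <- "td_hat_ms"
  res
}
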