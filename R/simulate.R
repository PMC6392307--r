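#' Simulation configuration
#'
#' Timing and numerical settings of the hybrid discrete/continuous
#' simulation: the controller runs at a fixed sample period `dt` with
#' zero-order-hold commands (the TDE lag is exactly one controller sample),
#' while plant and forward-model ODEs are integrated continuously within
#' each tick by fixed-step RK4 with `n_substeps` substeps.
#'
#' @param dt Controller sample period (s); 0.1 ms by default, approximating
#'   the continuous-time limit the TDE analysis assumes.
#' @param horizon Total simulated time (s).
#' @param td Sensory feedback delay (s).
#' @param td_hat The controller's estimate of the delay (s); defaults to
#'   `td` (the CNS assumed to know the delay exactly).
#' @param t_lead Quiescent lead-in before movement onset (s). The reference
#'   holds the start pose for `t < t_lead`; default 0.1 s.
#' @param n_substeps RK4 substeps per controller tick.
#' @param poly Reference polynomial blend, see [min_jerk_sample()].
#' @param divergence_limit Joint-angle magnitude (rad) beyond which a run is
#'   truncated and flagged divergent.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(dt = 1e-4, horizon = 1, td = 0.065, td_hat = td,
                       t_lead = 0.1, n_substeps = 2L,
                       poly = c("quintic", "degree6"),
                       divergence_limit = 1e4) {
  poly <- match.arg(poly)
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (horizon <= 0) stop("horizon must be > 0", call. = FALSE)
  if (td < 0 || td_hat < 0) stop("delays must be >= 0", call. = FALSE)
  if (t_lead < 0) stop("t_lead must be >= 0", call. = FALSE)
  structure(list(dt = dt, horizon = horizon, td = td, td_hat = td_hat,
                 t_lead = t_lead, n_substeps = as.integer(n_substeps),
                 poly = poly, divergence_limit = divergence_limit),
            class = "sim_config")
}

rk4_step <- function(x, t, h, f) {
  k1 <- f(t, x)
  k2 <- f(t + h / 2, x + h / 2 * k1)
  k3 <- f(t + h / 2, x + h / 2 * k2)
  k4 <- f(t + h, x + h * k3)
  x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

# Exact action of n_sub RK4 substeps on the linear system xdot = A x + B u
# with u held constant: x_next = R x + S u. (RK4 applied to a linear constant
# system is the degree-4 Taylor truncation of the matrix exponential, so the
# maps can be precomputed once per run.)
rk4_linear_maps <- function(A, B, h, n_sub) {
  n <- nrow(A)
  A2 <- A %*% A; A3 <- A2 %*% A; A4 <- A3 %*% A
  R1 <- diag(n) + h * A + h^2 / 2 * A2 + h^3 / 6 * A3 + h^4 / 24 * A4
  S1 <- (h * diag(n) + h^2 / 2 * A + h^3 / 6 * A2 + h^4 / 24 * A3) %*% B
  R <- diag(n); S <- matrix(0, n, ncol(B))
  for (i in seq_len(n_sub)) {
    S <- R1 %*% S + S1
    R <- R1 %*% R
  }
  list(R = R, S = S)
}

#' Run one closed-loop reaching simulation
#'
#' Couples the continuous arm plant, the discrete controller and (for the
#' Smith-architecture controller) the continuously integrated forward model.
#' At each controller tick the delay lines are updated and queried, the
#' corrected reference is formed, and the command is computed and held over
#' the tick while plant and forward model are integrated by RK4. The
#' computed-torque controller, being memoryless and delay-free, is instead
#' evaluated continuously inside the integrator. Divergence (joint angle
#' beyond `divergence_limit`, or non-finite state) truncates the run and
#' sets the `diverged` flag rather than raising an error, so sensitivity
#' sweeps can visit unstable regions.
#'
#' @param task A [min_jerk_task()]. Joint-space tasks must match the plant's
#'   dimension; Cartesian tasks require the two-link plant.
#' @param controller A controller specification, see
#'   [controller_proposed()].
#' @param plant Plant parameters ([arm_params()] or [arm_inertia()]).
#' @param config A [sim_config()].
#' @param load Optional disturbance hook `function(t, q, qdot)` returning an
#'   external torque (N m) opposing `tau`.
#' @return An object of class `reach_sim`: a list with the tick-indexed
#'   `signals` tibble (plant state, reference, corrected reference,
#'   estimator state, command, TDE estimate), the inputs, and the
#'   `diverged` flag. Use [tidy()][generics::tidy],
#'   [glance()][generics::glance], [movement_metrics()] and
#'   [ggplot2::autoplot()] on it.
#' @examples
#' task <- min_jerk_task(deg2rad(50), deg2rad(85), 0.25)
#' ctrl <- controller_proposed(tdc_gains(0.15, 25, 150))
#' sim <- simulate_reach(task, ctrl, arm_inertia(0.165), sim_config())
#' glance(sim)
#' @export
simulate_reach <- function(task, controller, plant, config = sim_config(),
                           load = NULL) {
  stopifnot(inherits(task, "min_jerk_task"),
            inherits(controller, "reach_controller"),
            inherits(config, "sim_config"))
  n <- n_joints(plant)
  if (task$space == "joint" && length(task$from) != n) {
    stop("joint-space task dimension does not match the plant", call. = FALSE)
  }
  if (task$space == "cartesian" && n != 2L) {
    stop("cartesian tasks require the two-link plant", call. = FALSE)
  }
  if (controller$type == "optimal" && n != 1L) {
    stop("the optimal controller/predictor is implemented for single-joint tasks",
         call. = FALSE)
  }

  dt <- config$dt
  nt <- as.integer(round(config$horizon / dt))
  ref_fun <- make_reference(task, if (n == 2L) plant else NULL,
                            config$t_lead, config$poly)

  q0 <- if (task$space == "joint") task$from else inverse_kinematics(task$from, plant)
  type <- controller$type
  has_fm <- type == "proposed"

  # tick-indexed histories (row r = time (r-1)*dt)
  zmat <- function() matrix(NA_real_, nt + 1L, n)
  Qm <- zmat(); QDm <- zmat(); QDDm <- zmat(); TAUm <- zmat()
  RQ <- zmat(); RQD <- zmat(); RQDD <- zmat()
  QRm <- zmat(); QRDm <- zmat(); QRDDm <- zmat()
  QH <- zmat(); QHD <- zmat(); QHDD <- zmat(); HH <- zmat()

  q <- q0; qdot <- numeric(n)
  qhat <- q0; qhat_dot <- numeric(n)          # estimator starts at the true state
  tau_prev <- numeric(n); qhatdd_prev <- numeric(n)
  zero <- numeric(n)

  gains <- controller$gains
  setup <- controller$setup
  td <- config$td; td_hat <- config$td_hat
  m_pred <- if (type == "optimal") as.integer(round(td_hat / dt)) else 0L
  k_td <- if (type == "optimal") as.integer(round(td / dt)) else 0L
  ctc_model <- if (type == "ctc") {
    if (is.null(controller$model)) plant else controller$model
  }

  # plant acceleration given held command
  plant_acc <- if (n == 1L) {
    J <- plant$J
    if (is.null(load)) function(t, q, qdot, tau) tau / J
    else function(t, q, qdot, tau) (tau - load(t, q, qdot)) / J
  } else {
    if (is.null(load)) {
      function(t, q, qdot, tau) {
        drop(solve(mass_matrix(q, plant),
                   tau - coriolis_vector(q, qdot, plant)))
      }
    } else {
      function(t, q, qdot, tau) {
        drop(solve(mass_matrix(q, plant),
                   tau - coriolis_vector(q, qdot, plant) - load(t, q, qdot)))
      }
    }
  }

  iq <- seq_len(n); iqd <- n + iq
  tau_cur <- zero; p_cur <- zero
  deriv_zoh <- function(t, x) {
    c(x[iqd], plant_acc(t, x[iq], x[iqd], tau_cur))
  }
  deriv_ctc <- function(t, x) {
    r <- ref_fun(t)
    tau_t <- ctc_torque(r, x[iq], x[iqd], controller$kv, controller$kp, ctc_model)
    c(x[iqd], plant_acc(t, x[iq], x[iqd], tau_t))
  }

  h <- dt / config$n_substeps
  # forward-model tick update (linear, per joint, forcing held): RK4 as a
  # precomputed linear map
  fm_maps <- if (has_fm) {
    lapply(seq_len(n), function(j) {
      rk4_linear_maps(matrix(c(0, -gains$kp[j], 1, -gains$kv[j]), 2L, 2L),
                      matrix(c(0, 1)), h, config$n_substeps)
    })
  }
  # exact ZOH update for the linear single-joint plant (no disturbance)
  plant_exact_1d <- n == 1L && is.null(load) && type != "ctc"
  diverged <- FALSE; div_time <- NA_real_
  k_last <- nt

  for (k in 0:nt) {
    t <- k * dt
    r <- ref_fun(t)
    row <- k + 1L
    Qm[row, ] <- q; QDm[row, ] <- qdot
    QH[row, ] <- qhat; QHD[row, ] <- qhat_dot
    RQ[row, ] <- r$q; RQD[row, ] <- r$qdot; RQDD[row, ] <- r$qddot

    qhatdd_now <- zero
    if (type == "proposed") {
      md <- list(q = grid_query(Qm, row, t - td, dt, q0),
                 qdot = grid_query(QDm, row, t - td, dt, zero),
                 qddot = grid_query(QDDm, k, t - td, dt, zero))
      ed <- list(q = grid_query(QH, row, t - td_hat, dt, q0),
                 qdot = grid_query(QHD, row, t - td_hat, dt, zero),
                 qddot = grid_query(QHDD, k, t - td_hat, dt, zero))
      qr <- smith_reference(r, md, ed, scope = controller$scope)
      acc_src <- if (controller$accel_source == "measured") {
        if (k == 0L) zero else QDDm[k, ]
      } else {
        qhatdd_prev
      }
      tau <- proposed_torque(tau_prev, acc_src, qr, qhat, qhat_dot, gains)
      p_cur <- fm_forcing(qr, gains)
      qhatdd_now <- -gains$kv * qhat_dot - gains$kp * qhat + p_cur
      QRm[row, ] <- qr$q; QRDm[row, ] <- qr$qdot; QRDDm[row, ] <- qr$qddot
      HH[row, ] <- tde_estimate(tau_prev, acc_src, gains$beta_bar)
    } else if (type == "tdc") {
      acc_prev <- if (k == 0L) zero else QDDm[k, ]
      tau <- tdc_torque(tau_prev, acc_prev, r, q, qdot, gains)
      HH[row, ] <- tde_estimate(tau_prev, acc_prev, gains$beta_bar)
    } else if (type == "ctc") {
      tau <- ctc_torque(r, q, qdot, controller$kv, controller$kp, ctc_model)
    } else if (type == "optimal") {
      sq <- grid_query(Qm, row, t - td, dt, q0)
      sqd <- grid_query(QDm, row, t - td, dt, zero)
      cmd_rows <- k - k_td + seq_len(m_pred)
      cmds <- ifelse(cmd_rows >= 1L & cmd_rows <= k, TAUm[pmax(cmd_rows, 1L), 1L], 0)
      pred <- predictor_estimate(sq, sqd, cmds, setup, dt)
      qhat <- pred$q; qhat_dot <- pred$qdot
      QH[row, ] <- qhat; QHD[row, ] <- qhat_dot
      tau <- optimal_torque(r, qhat, qhat_dot, setup)
    } else if (type == "ep") {
      qp <- grid_query(Qm, row, t - gains$t_dp, dt, q0)
      qv <- grid_query(QDm, row, t - gains$t_dv, dt, zero)
      tau <- ep_torque(r, qp, qv, gains)
    } else {
      tau <- zero
    }

    acc <- plant_acc(t, q, qdot, tau)
    QDDm[row, ] <- acc
    TAUm[row, ] <- tau
    if (has_fm) QHDD[row, ] <- qhatdd_now

    bad <- !all(is.finite(c(q, qdot, tau))) ||
      max(abs(q)) > config$divergence_limit
    if (bad) {
      diverged <- TRUE; div_time <- t; k_last <- k
      break
    }

    if (k < nt) {
      if (plant_exact_1d) {
        q <- q + qdot * dt + acc * dt^2 / 2
        qdot <- qdot + acc * dt
      } else {
        tau_cur <- tau
        x <- c(q, qdot)
        f <- if (type == "ctc") deriv_ctc else deriv_zoh
        ts <- t
        for (s in seq_len(config$n_substeps)) {
          x <- rk4_step(x, ts, h, f)
          ts <- ts + h
        }
        q <- x[iq]; qdot <- x[iqd]
      }
      if (has_fm) {
        for (j in seq_len(n)) {
          mj <- fm_maps[[j]]
          xj <- mj$R %*% c(qhat[j], qhat_dot[j]) + mj$S * p_cur[j]
          qhat[j] <- xj[1L]; qhat_dot[j] <- xj[2L]
        }
      }
      if (!all(is.finite(c(q, qdot, qhat, qhat_dot)))) {
        diverged <- TRUE; div_time <- t + dt; k_last <- k
        break
      }
    }
    tau_prev <- tau
    qhatdd_prev <- qhatdd_now
  }

  keep <- seq_len(k_last + 1L)
  nm <- function(base) paste0(base, "_", seq_len(n))
  tabs <- list(time = (keep - 1L) * dt)
  addm <- function(tabs, base, M) {
    cols <- stats::setNames(lapply(seq_len(n), function(j) M[keep, j]), nm(base))
    c(tabs, cols)
  }
  tabs <- addm(tabs, "q", Qm); tabs <- addm(tabs, "qdot", QDm)
  tabs <- addm(tabs, "qddot", QDDm)
  tabs <- addm(tabs, "qd", RQ); tabs <- addm(tabs, "qd_dot", RQD)
  tabs <- addm(tabs, "qd_ddot", RQDD)
  tabs <- addm(tabs, "tau", TAUm)
  if (type == "proposed") {
    tabs <- addm(tabs, "qr", QRm); tabs <- addm(tabs, "qr_dot", QRDm)
    tabs <- addm(tabs, "qr_ddot", QRDDm)
  }
  if (type %in% c("proposed", "optimal")) {
    tabs <- addm(tabs, "qhat", QH); tabs <- addm(tabs, "qhat_dot", QHD)
  }
  if (type == "proposed") tabs <- addm(tabs, "qhat_ddot", QHDD)
  if (type %in% c("proposed", "tdc")) tabs <- addm(tabs, "H_hat", HH)

  structure(list(signals = tibble::as_tibble(tabs),
                 task = task, controller = controller, plant = plant,
                 config = config, q0 = q0,
                 diverged = diverged, divergence_time = div_time),
            class = "reach_sim")
}

#' @export
print.reach_sim <- function(x, ...) {
  n <- n_joints(x$plant)
  cat(sprintf("<reach simulation> %s controller, %d joint%s, %d ticks @ dt = %g s\n",
              x$controller$type, n, if (n > 1) "s" else "",
              nrow(x$signals), x$config$dt))
  if (x$diverged) {
    cat(sprintf("  DIVERGED at t = %g s\n", x$divergence_time))
  } else {
    qf <- unlist(x$signals[nrow(x$signals), paste0("q_", seq_len(n))])
    cat("  final angles (deg):", round(rad2deg(qf), 3), "\n")
  }
  invisible(x)
}
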