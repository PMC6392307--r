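#' Kinematic movement metrics
#'
#' Summarises a single-joint reach the way the motor-control literature
#' does: endpoint error at the end of the observation window, peak angular
#' velocity and its timing relative to the movement time, a terminal
#' oscillation count, and the tracking RMSE against the planned trajectory
#' over a stated window.
#'
#' The oscillation count uses two thresholds: the *reversal point* is the
#' first instant after the velocity peak at which the absolute angular
#' velocity drops below 5 deg/s; from there, velocity zero-crossings are
#' counted until the excursion amplitude about the target — the peak
#' absolute deviation from the target within each half-cycle — falls below
#' 2 deg.
#'
#' @param x A [simulate_reach()] result, or a data frame with columns
#'   `time`, `q`, `qdot` (radians / rad/s) and optionally `qd`.
#' @param window Length-2 numeric RMSE window (s); defaults to the movement
#'   interval `[t_lead, t_lead + duration]`.
#' @param ... Passed between methods.
#' @return A one-row tibble: `final_angle_deg`, `endpoint_error_deg`,
#'   `peak_velocity_deg_s`, `rel_time_to_peak`, `oscillation_count`,
#'   `tracking_rmse_deg`.
#' @export
movement_metrics <- function(x, ...) UseMethod("movement_metrics")

#' @rdname movement_metrics
#' @export
movement_metrics.reach_sim <- function(x, window = NULL, ...) {
  if (x$diverged) {
    stop("cannot compute movement metrics for a divergent run", call. = FALSE)
  }
  if (n_joints(x$plant) != 1L) {
    stop("movement metrics are defined for single-joint runs; see path_metrics()",
         call. = FALSE)
  }
  qf <- x$task$to[1]
  df <- tibble::tibble(time = x$signals$time, q = x$signals$q_1,
                       qdot = x$signals$qdot_1, qd = x$signals$qd_1)
  movement_metrics(df, qf = qf, t_onset = x$config$t_lead,
                   duration = x$task$duration, window = window)
}

#' @rdname movement_metrics
#' @param qf Target angle (rad).
#' @param t_onset Movement onset time (s).
#' @param duration Movement duration (s).
#' @export
movement_metrics.data.frame <- function(x, qf, t_onset = 0, duration,
                                        window = NULL, ...) {
  if (is.null(window)) window <- c(t_onset, t_onset + duration)
  tt <- x$time; q <- x$q; qdot <- x$qdot
  move <- tt >= t_onset
  ip <- which(move)[which.max(abs(qdot[move]))]
  t_peak <- tt[ip]
  peak_vel <- abs(qdot[ip])

  # total movement time runs from onset to the reversal point (first
  # post-peak instant with |velocity| < 5 deg/s); a heavier-than-expected
  # load both delays the peak and stretches the movement, so the ratio is
  # taken against the realised, not the planned, duration
  i_rev <- reversal_index(tt, qdot, ip)
  t_total <- if (is.na(i_rev)) NA_real_ else tt[i_rev] - t_onset

  osc <- oscillation_count(tt, q, qdot, qf, i_peak = ip)

  rmse <- NA_real_
  if ("qd" %in% names(x)) {
    inw <- tt >= window[1] & tt <= window[2]
    rmse <- sqrt(mean((q[inw] - x$qd[inw])^2))
  }
  tibble::tibble(
    final_angle_deg = rad2deg(q[length(q)]),
    endpoint_error_deg = rad2deg(abs(q[length(q)] - qf)),
    peak_velocity_deg_s = rad2deg(peak_vel),
    rel_time_to_peak = (t_peak - t_onset) / t_total,
    oscillation_count = osc,
    tracking_rmse_deg = rad2deg(rmse)
  )
}

# first post-peak index with |velocity| below the reversal threshold
reversal_index <- function(time, qdot, i_peak, vel_thresh = deg2rad(5)) {
  post <- seq(i_peak, length(time))
  hit <- which(abs(qdot[post]) < vel_thresh)
  if (!length(hit)) NA_integer_ else post[hit[1]]
}

# Count terminal oscillations: from the reversal point (first post-peak
# |qdot| < vel_thresh) count velocity zero-crossings until the per-half-cycle
# peak excursion about the target drops below amp_thresh.
oscillation_count <- function(time, q, qdot, qf,
                              i_peak = which.max(abs(qdot)),
                              vel_thresh = deg2rad(5),
                              amp_thresh = deg2rad(2)) {
  nT <- length(time)
  i_rev <- reversal_index(time, qdot, i_peak, vel_thresh)
  if (is.na(i_rev)) return(NA_integer_)   # movement never slowed down
  idx <- seq(i_rev, nT)
  s <- sign(qdot[idx])
  nz <- which(s != 0)
  cross <- integer(0)
  if (length(nz) > 1L) {
    chg <- which(s[nz[-1]] != s[nz[-length(nz)]])
    cross <- idx[nz[chg + 1L]]
  }
  bounds <- c(i_rev, cross, nT)
  count <- 0L
  for (j in seq_len(length(bounds) - 1L)) {
    seg <- seq(bounds[j], bounds[j + 1L])
    if (max(abs(q[seg] - qf)) < amp_thresh) break
    if (j < length(bounds) - 1L) count <- count + 1L
  }
  count
}

#' Hand-path metrics for two-joint reaches
#'
#' Maximum perpendicular deviation of the simulated hand path from the
#' straight line between the task's Cartesian endpoints, and the Cartesian
#' endpoint error at the end of the run.
#'
#' @param sim A two-joint [simulate_reach()] result for a Cartesian task.
#' @return One-row tibble with `max_deviation_mm` and `endpoint_error_mm`.
#' @export
path_metrics <- function(sim) {
  stopifnot(inherits(sim, "reach_sim"), sim$task$space == "cartesian")
  if (sim$diverged) stop("cannot compute path metrics for a divergent run", call. = FALSE)
  params <- sim$plant
  qs <- cbind(sim$signals$q_1, sim$signals$q_2)
  hand <- t(apply(qs, 1L, forward_kinematics, params = params))
  a <- sim$task$from; b <- sim$task$to
  u <- b - a; L <- sqrt(sum(u^2))
  # perpendicular distance of each hand point from segment a->b
  dx <- hand[, 1] - a[1]; dy <- hand[, 2] - a[2]
  dev <- abs(u[1] * dy - u[2] * dx) / L
  endpt <- hand[nrow(hand), ]
  tibble::tibble(
    max_deviation_mm = 1000 * max(dev),
    endpoint_error_mm = 1000 * sqrt(sum((endpt - b)^2))
  )
}

#' Spectral stability margin of the TDE loop
#'
#' The TDE estimation error obeys a linear recursion whose state matrix is
#' \eqn{I - M(q)^{-1}\bar\beta}; if its spectral radius stays below one over
#' the visited postures the estimation error is asymptotically bounded, and
#' the closed loop is expected to remain stable. For the single-joint plant
#' this is simply `|1 - beta_bar / J|`.
#'
#' @param gains A [tdc_gains()] object.
#' @param plant Plant parameters.
#' @param q_samples For the two-link arm, a list/matrix of joint-angle
#'   vectors to sample; defaults to a grid of elbow angles over
#'   `[-pi, pi]` (the shoulder angle does not enter the mass matrix).
#' @return The maximum spectral radius over the sampled postures.
#' @export
stability_margin <- function(gains, plant, q_samples = NULL) {
  stopifnot(inherits(gains, "tdc_gains"))
  if (n_joints(plant) == 1L) {
    return(abs(1 - gains$beta_bar[1] / plant$J))
  }
  if (is.null(q_samples)) {
    q_samples <- lapply(seq(-pi, pi, length.out = 73), function(q2) c(0, q2))
  }
  if (is.matrix(q_samples)) q_samples <- asplit(q_samples, 1L)
  bb <- diag(gains$beta_bar, 2L)
  radius <- vapply(q_samples, function(q) {
    A <- diag(2L) - solve(mass_matrix(q, plant)) %*% bb
    max(Mod(eigen(A, only.values = TRUE)$values))
  }, numeric(1))
  max(radius)
}

#' TDE error-recursion diagnostics
#'
#' Reconstructs, from a stored TDC-family run, the estimation error
#' \eqn{\epsilon(k) = \nu(k) - \ddot\theta(k)} (with \eqn{\nu} the new
#' control input, i.e. the bracketed desired-dynamics term), the forcing
#' terms \eqn{\zeta(k-1) = \nu(k) - \nu(k-1)} and
#' \eqn{\eta(k-1) = (I - M_k^{-1} M_{k-1})\ddot\theta(k-1) +
#' M_k^{-1}(f_k - f_{k-1})}, the true and estimated lumped dynamics `H`,
#' `H_hat`, and the residual of the error recursion
#' \deqn{\epsilon(k) = (I - M_k^{-1}\bar\beta)(\epsilon(k-1) + \zeta(k-1))
#'   + \eta(k-1)}
#' on the stored grid. For runs of the Smith-architecture law, which
#' cancels with the *estimated* rather than measured previous acceleration,
#' the exact recursion carries the extra term
#' \eqn{-M_k^{-1}\bar\beta(\ddot\theta - \ddot{\hat\theta})(k-1)}, which is
#' included. On constant-inertia runs the recursion is exact algebra and
#' the residual is at floating-point level.
#'
#' @param sim A [simulate_reach()] run using `controller_tdc()` or
#'   `controller_proposed()`.
#' @return Class `tde_diag`: list with the per-tick `trace` tibble and the
#'   posture-maximised `spectral_margin`.
#' @export
tde_error_trace <- function(sim) {
  stopifnot(inherits(sim, "reach_sim"))
  type <- sim$controller$type
  if (!type %in% c("proposed", "tdc")) {
    stop("TDE diagnostics require a TDC-family run", call. = FALSE)
  }
  g <- sim$controller$gains
  plant <- sim$plant
  n <- n_joints(plant)
  sg <- sim$signals
  K <- nrow(sg)
  col <- function(base) as.matrix(sg[paste0(base, "_", seq_len(n))])

  qm <- col("q"); qdm <- col("qdot"); qddm <- col("qddot")
  if (type == "proposed") {
    nu <- col("qr_ddot") + t(g$kv * t(col("qr_dot") - col("qhat_dot"))) +
      t(g$kp * t(col("qr") - col("qhat")))
    # the acceleration-substitution correction applies only when the TDE
    # term used the forward model's acceleration instead of the plant's
    delta <- if (identical(sim$controller$accel_source, "estimated")) {
      qddm - col("qhat_ddot")
    } else {
      matrix(0, K, n)
    }
  } else {
    nu <- col("qd_ddot") + t(g$kv * t(col("qd_dot") - qdm)) +
      t(g$kp * t(col("qd") - qm))
    delta <- matrix(0, K, n)
  }
  eps <- nu - qddm
  zeta <- rbind(matrix(NA_real_, 1L, n), diff(nu))   # zeta[k] = nu(k) - nu(k-1)

  Mlist <- if (n == 1L) NULL else lapply(seq_len(K), function(i) mass_matrix(qm[i, ], plant))
  fmat <- if (n == 1L) matrix(0, K, 1L) else
    t(vapply(seq_len(K), function(i) coriolis_vector(qm[i, ], qdm[i, ], plant),
             numeric(2)))

  Htrue <- matrix(NA_real_, K, n); eta <- matrix(NA_real_, K, n)
  resid <- matrix(NA_real_, K, n)
  bb <- if (n == 1L) matrix(g$beta_bar) else diag(g$beta_bar, n)
  for (k in seq_len(K)) {
    Mk <- if (n == 1L) matrix(plant$J) else Mlist[[k]]
    Htrue[k, ] <- drop((Mk - bb) %*% qddm[k, ]) + fmat[k, ]
    if (k >= 2L) {
      Mi <- solve(Mk)
      Mk1 <- if (n == 1L) matrix(plant$J) else Mlist[[k - 1L]]
      eta[k, ] <- drop((diag(n) - Mi %*% Mk1) %*% qddm[k - 1L, ]) +
        drop(Mi %*% (fmat[k, ] - fmat[k - 1L, ]))
      A <- diag(n) - Mi %*% bb
      pred <- drop(A %*% (eps[k - 1L, ] + zeta[k, ])) + eta[k, ] -
        drop(Mi %*% bb %*% delta[k - 1L, ])
      resid[k, ] <- eps[k, ] - pred
    }
  }

  nmm <- function(base) paste0(base, "_", seq_len(n))
  trace <- tibble::as_tibble(c(
    list(time = sg$time),
    stats::setNames(asplit(eps, 2L), nmm("eps")),
    stats::setNames(asplit(nu, 2L), nmm("nu")),
    stats::setNames(asplit(zeta, 2L), nmm("zeta")),
    stats::setNames(asplit(eta, 2L), nmm("eta")),
    stats::setNames(asplit(Htrue, 2L), nmm("H")),
    stats::setNames(asplit(col("H_hat"), 2L), nmm("H_hat")),
    stats::setNames(asplit(resid, 2L), nmm("residual"))
  ))
  structure(list(trace = trace,
                 spectral_margin = stability_margin(g, plant)),
            class = "tde_diag")
}

#' @export
print.tde_diag <- function(x, ...) {
  r <- as.matrix(dplyr::select(x$trace, dplyr::starts_with("residual")))
  cat(sprintf("<TDE diagnostics> spectral margin %.4f, max |recursion residual| %.3g\n",
              x$spectral_margin, max(abs(r), na.rm = TRUE)))
  invisible(x)
}
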