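#' Define a minimum-jerk reaching task
#'
#' A rest-to-rest point reach described by its endpoints, duration and the
#' space in which the smooth (minimum-jerk) path is planned: directly in
#' joint space, or as a straight hand-path line in Cartesian space that is
#' subsequently mapped to joint space through the arm's inverse kinematics.
#'
#' @param from,to Start and end configuration: joint angles in radians
#'   (`space = "joint"`) or hand positions in metres (`space = "cartesian"`).
#'   Equal lengths.
#' @param duration Movement time `T` in seconds, strictly positive.
#' @param space Planning space.
#' @return An object of class `min_jerk_task`.
#' @examples
#' task <- min_jerk_task(deg2rad(45), deg2rad(145), 0.2)
#' min_jerk_sample(0.1, task)
#' @export
min_jerk_task <- function(from, to, duration, space = c("joint", "cartesian")) {
  space <- match.arg(space)
  if (length(from) != length(to)) stop("`from` and `to` must have equal length", call. = FALSE)
  if (!is.finite(duration) || duration <= 0) stop("`duration` must be > 0", call. = FALSE)
  if (space == "cartesian" && length(from) != 2L) {
    stop("cartesian tasks need planar (x, y) endpoints", call. = FALSE)
  }
  structure(list(from = as.numeric(from), to = as.numeric(to),
                 duration = duration, space = space),
            class = "min_jerk_task")
}

#' @export
print.min_jerk_task <- function(x, ...) {
  cat(sprintf("<min-jerk task> %s space, T = %g s\n", x$space, x$duration))
  cat("  from:", signif(x$from, 4), "\n  to:  ", signif(x$to, 4), "\n")
  invisible(x)
}

#' Degrees/radians helpers
#' @param x Angle(s).
#' @return Converted angle(s).
#' @export
deg2rad <- function(x) x * pi / 180

#' @rdname deg2rad
#' @export
rad2deg <- function(x) x * 180 / pi

# Normalized blend s(t') and its first two derivatives w.r.t. t'.
# "quintic" is the classic rest-to-rest minimum-jerk polynomial
# 10 t'^3 - 15 t'^4 + 6 t'^5 (zero velocity and acceleration at both ends).
# "degree6" is the alternative blend 6 t'^6 - 15 t'^5 + 10 t'^4, kept for
# comparison runs; note it reaches the target with nonzero end velocity.
mj_blend <- function(tp, poly) {
  if (poly == "quintic") {
    list(s  = tp^3 * (10 - 15 * tp + 6 * tp^2),
         ds = 30 * tp^2 * (1 - tp)^2,
         d2s = 60 * tp * (1 - 3 * tp + 2 * tp^2))
  } else {
    list(s  = 6 * tp^6 - 15 * tp^5 + 10 * tp^4,
         ds = 36 * tp^5 - 75 * tp^4 + 40 * tp^3,
         d2s = 180 * tp^4 - 300 * tp^3 + 120 * tp^2)
  }
}

#' Sample a minimum-jerk trajectory
#'
#' Position, velocity and acceleration of the planned trajectory at time `t`,
#' with exact analytic derivatives of the position polynomial. Outside
#' `[0, duration]` the trajectory clamps: start pose at rest for `t < 0`, end
#' pose at rest beyond the movement (the held target that endpoint metrics
#' need).
#'
#' @param t Time in seconds (scalar).
#' @param task A [min_jerk_task()].
#' @param poly Polynomial blend: `"quintic"` (default; rest-to-rest) or
#'   `"degree6"` (alternative blend with nonzero end velocity, for
#'   comparison experiments).
#' @return A list with components `q`, `qdot`, `qddot` (vectors in the task's
#'   planning space).
#' @export
min_jerk_sample <- function(t, task, poly = c("quintic", "degree6")) {
  poly <- match.arg(poly)
  Tm <- task$duration
  delta <- task$to - task$from
  if (t <= 0) {
    return(list(q = task$from, qdot = 0 * delta, qddot = 0 * delta))
  }
  if (t >= Tm && poly == "quintic") {
    return(list(q = task$to, qdot = 0 * delta, qddot = 0 * delta))
  }
  if (t >= Tm) {  # degree6 clamps position; velocity held at zero beyond T
    return(list(q = task$to, qdot = 0 * delta, qddot = 0 * delta))
  }
  b <- mj_blend(t / Tm, poly)
  list(q = task$from + delta * b$s,
       qdot = delta * b$ds / Tm,
       qddot = delta * b$d2s / Tm^2)
}

#' Tabulate a reference trajectory
#'
#' Convenience sampler over a time grid, returned as a tibble in long-ready
#' wide form (one column per joint/coordinate and derivative order).
#'
#' @param times Numeric vector of sample times (s).
#' @inheritParams min_jerk_sample
#' @return A tibble with columns `time`, `q_<i>`, `qdot_<i>`, `qddot_<i>`.
#' @export
min_jerk_profile <- function(times, task, poly = c("quintic", "degree6")) {
  poly <- match.arg(poly)
  n <- length(task$from)
  rows <- lapply(times, function(t) {
    s <- min_jerk_sample(t, task, poly)
    c(time = t,
      stats::setNames(s$q, paste0("q_", seq_len(n))),
      stats::setNames(s$qdot, paste0("qdot_", seq_len(n))),
      stats::setNames(s$qddot, paste0("qddot_", seq_len(n))))
  })
  tibble::as_tibble(do.call(rbind, rows))
}

#' Joint-space reference for a Cartesian task
#'
#' Samples the straight-line Cartesian minimum-jerk path at time `t`, maps
#' the hand position to joint angles via [inverse_kinematics()] and pushes
#' velocity and acceleration through the arm Jacobian and its time
#' derivative: `qdot = J^-1 xdot`, `qddot = J^-1 (xddot - Jdot qdot)`.
#'
#' @param t Time (s).
#' @param task A Cartesian-space [min_jerk_task()].
#' @param params An [arm_params()] object.
#' @inheritParams min_jerk_sample
#' @return A list `q`, `qdot`, `qddot` in joint space (rad, rad/s, rad/s^2).
#' @export
joint_reference <- function(t, task, params, poly = c("quintic", "degree6")) {
  stopifnot(task$space == "cartesian")
  poly <- match.arg(poly)
  s <- min_jerk_sample(t, task, poly)
  q <- inverse_kinematics(s$q, params)
  J <- arm_jacobian(q, params)
  qdot <- drop(solve(J, s$qdot))
  Jd <- arm_jacobian_dot(q, qdot, params)
  qddot <- drop(solve(J, s$qddot - Jd %*% qdot))
  list(q = q, qdot = qdot, qddot = qddot)
}

# Reference closure used by the simulation engine: shifts time by the
# quiescent lead-in and resolves cartesian tasks to joint space once per call.
make_reference <- function(task, params, t_lead, poly = "quintic") {
  if (task$space == "joint") {
    function(t) min_jerk_sample(t - t_lead, task, poly)
  } else {
    function(t) joint_reference(t - t_lead, task, params, poly)
  }
}
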