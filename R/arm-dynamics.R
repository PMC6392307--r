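#' Physical parameters of the two-link planar arm
#'
#' Constructs the parameter set of a horizontal-plane, two-degree-of-freedom
#' arm (shoulder and elbow). Defaults are anthropometric values for a human
#' arm: link rotational inertias about their own centres of mass `J1`, `J2`
#' (kg m^2), link masses `M1`, `M2` (kg), link lengths `l1`, `l2` (m) and
#' proximal-joint-to-centre-of-mass distances `lm1`, `lm2` (m). Gravity is
#' absent (horizontal plane) and no friction is modelled; external torques can
#' be injected through the `load` hook of [forward_dynamics()].
#'
#' @param J1,J2 Link rotational inertias (kg m^2), strictly positive.
#' @param M1,M2 Link masses (kg), strictly positive.
#' @param l1,l2 Link lengths (m), strictly positive.
#' @param lm1,lm2 Distance from the proximal joint to the link centre of mass
#'   (m); must satisfy `lm1 <= l1`, `lm2 <= l2`.
#' @return An object of class `arm_params_2d`.
#' @seealso [arm_inertia()] for the single-joint plant, [mass_matrix()],
#'   [forward_dynamics()].
#' @examples
#' p <- arm_params()
#' mass_matrix(c(0, pi / 2), p)
#' @export
arm_params <- function(J1 = 0.0141, M1 = 1.93, l1 = 0.31, lm1 = 0.165,
                       J2 = 0.0188, M2 = 1.52, l2 = 0.34, lm2 = 0.19) {
  vals <- c(J1 = J1, M1 = M1, l1 = l1, lm1 = lm1,
            J2 = J2, M2 = M2, l2 = l2, lm2 = lm2)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all arm parameters must be finite and strictly positive", call. = FALSE)
  }
  if (lm1 > l1 || lm2 > l2) {
    stop("centre-of-mass distances cannot exceed link lengths", call. = FALSE)
  }
  structure(as.list(vals), class = "arm_params_2d")
}

#' Single-joint arm plant
#'
#' A one-degree-of-freedom rotational plant `J qddot = tau` used for the
#' elbow-only tasks. `J = 0.0188` kg m^2 is the forearm inertia that also
#' defines the state-space limb model of the optimal controller's predictor;
#' the composite forearm-about-the-elbow value `J2 + M2 * lm2^2` (about
#' 0.0737 kg m^2 with the default two-link parameters) can be supplied
#' instead when the hand/load mass should rotate with the segment.
#'
#' @param J Rotational inertia about the joint (kg m^2), strictly positive.
#' @return An object of class `arm_params_1d`.
#' @export
arm_inertia <- function(J = 0.0188) {
  if (!is.finite(J) || J <= 0) stop("J must be finite and > 0", call. = FALSE)
  structure(list(J = J), class = "arm_params_1d")
}

#' @export
print.arm_params_2d <- function(x, ...) {
  cat("<two-link planar arm>\n")
  cat(sprintf("  upper arm: J1=%.4f kg m^2  M1=%.2f kg  l1=%.3f m  lm1=%.3f m\n",
              x$J1, x$M1, x$l1, x$lm1))
  cat(sprintf("  forearm:   J2=%.4f kg m^2  M2=%.2f kg  l2=%.3f m  lm2=%.3f m\n",
              x$J2, x$M2, x$l2, x$lm2))
  invisible(x)
}

#' @export
print.arm_params_1d <- function(x, ...) {
  cat(sprintf("<single-joint arm> J=%.4f kg m^2\n", x$J))
  invisible(x)
}

n_joints <- function(params) {
  if (inherits(params, "arm_params_2d")) 2L
  else if (inherits(params, "arm_params_1d")) 1L
  else stop("unknown plant parameter object", call. = FALSE)
}

check_len <- function(x, n, what) {
  if (length(x) != n) {
    stop(sprintf("%s must have length %d, got %d", what, n, length(x)),
         call. = FALSE)
  }
  invisible(x)
}

#' Inertia matrix of the two-link arm
#'
#' The configuration-dependent, symmetric positive-definite mass matrix
#' \eqn{M(q)} of the shoulder-elbow system. Only the elbow angle `q[2]`
#' enters; `M[2,2]` is configuration independent.
#'
#' @param q Joint-angle vector `c(q1, q2)` (rad): shoulder angle from the
#'   x-axis and elbow flexion relative to the upper arm.
#' @param params An [arm_params()] object.
#' @return A symmetric 2x2 matrix (kg m^2).
#' @export
mass_matrix <- function(q, params) {
  stopifnot(inherits(params, "arm_params_2d"))
  check_len(q, 2L, "q")
  c2 <- cos(q[2])
  m11 <- params$J1 + params$J2 + params$M1 * params$lm1^2 +
    params$M2 * (params$l1^2 + params$lm2^2 + 2 * params$l1 * params$lm2 * c2)
  m12 <- params$J2 + params$M2 * (params$lm2^2 + params$l1 * params$lm2 * c2)
  m22 <- params$J2 + params$M2 * params$lm2^2
  matrix(c(m11, m12, m12, m22), 2L, 2L)
}

#' Coriolis and centripetal torques of the two-link arm
#'
#' Velocity-product torques \eqn{C(q, \dot q)}: the elbow's motion loads the
#' shoulder and vice versa. Quadratic in the joint velocities and zero
#' whenever the elbow is straight (`sin q2 = 0`).
#'
#' @inheritParams mass_matrix
#' @param qdot Joint angular-velocity vector (rad/s), length 2.
#' @return Length-2 torque vector (N m).
#' @export
coriolis_vector <- function(q, qdot, params) {
  stopifnot(inherits(params, "arm_params_2d"))
  check_len(q, 2L, "q")
  check_len(qdot, 2L, "qdot")
  # Christoffel form: the shoulder component carries a minus sign so that
  # free motion conserves kinetic energy (dM11/dq2 < 0 for flexion)
  h <- params$M2 * params$l1 * params$lm2 * sin(q[2])
  c(-h * (2 * qdot[1] + qdot[2]) * qdot[2], h * qdot[1]^2)
}

#' Forward dynamics of the arm plant
#'
#' Solves for the joint angular accelerations given applied torques. For the
#' two-link arm this is \eqn{M(q)\ddot q = \tau - C(q,\dot q) - \tau_{ext}};
#' for the single-joint plant \eqn{\ddot q = (\tau - \tau_{ext})/J}. The
#' optional `load` hook injects an external/unmodelled torque and is how
#' disturbances are introduced in robustness experiments.
#'
#' @param q,qdot Joint position (rad) and velocity (rad/s) vectors.
#' @param tau Applied joint torques (N m), same length as `q`.
#' @param params An [arm_params()] or [arm_inertia()] object.
#' @param load `NULL` (default, no disturbance) or a function
#'   `function(t, q, qdot)` returning an external torque vector subtracted
#'   from `tau`.
#' @param t Simulation time passed to `load` (s).
#' @return Angular-acceleration vector (rad/s^2).
#' @export
forward_dynamics <- function(q, qdot, tau, params, load = NULL, t = 0) {
  n <- n_joints(params)
  check_len(q, n, "q"); check_len(qdot, n, "qdot"); check_len(tau, n, "tau")
  ext <- if (is.null(load)) numeric(n) else check_len(load(t, q, qdot), n, "load output")
  if (n == 1L) {
    (tau - ext) / params$J
  } else {
    M <- mass_matrix(q, params)
    drop(solve(M, tau - coriolis_vector(q, qdot, params) - ext))
  }
}

#' Hand position of the two-link arm
#'
#' Planar forward kinematics with the shoulder fixed at the origin:
#' `x = l1 cos(q1) + l2 cos(q1 + q2)`, `y = l1 sin(q1) + l2 sin(q1 + q2)`.
#'
#' @inheritParams mass_matrix
#' @return Hand position `c(x, y)` in metres.
#' @export
forward_kinematics <- function(q, params) {
  stopifnot(inherits(params, "arm_params_2d"))
  check_len(q, 2L, "q")
  s <- q[1] + q[2]
  c(params$l1 * cos(q[1]) + params$l2 * cos(s),
    params$l1 * sin(q[1]) + params$l2 * sin(s))
}

#' Joint angles reaching a hand position
#'
#' Closed-form two-link inverse kinematics returning the elbow-flexed branch
#' (`q2 >= 0`). Errors if the target lies outside the reachable annulus
#' `[|l1 - l2|, l1 + l2]`.
#'
#' @param pos Hand position `c(x, y)` (m).
#' @param params An [arm_params()] object.
#' @return Joint-angle vector `c(q1, q2)` (rad).
#' @export
inverse_kinematics <- function(pos, params) {
  stopifnot(inherits(params, "arm_params_2d"))
  check_len(pos, 2L, "pos")
  l1 <- params$l1; l2 <- params$l2
  d2 <- sum(pos^2)
  c2 <- (d2 - l1^2 - l2^2) / (2 * l1 * l2)
  if (c2 > 1 + 1e-12 || c2 < -1 - 1e-12) {
    stop(sprintf("target (%.3f, %.3f) is outside the reachable workspace",
                 pos[1], pos[2]), call. = FALSE)
  }
  c2 <- min(1, max(-1, c2))
  q2 <- acos(c2)                                   # q2 >= 0 branch
  q1 <- atan2(pos[2], pos[1]) - atan2(l2 * sin(q2), l1 + l2 * cos(q2))
  c(q1, q2)
}

#' Hand Jacobian and its time derivative
#'
#' `arm_jacobian()` maps joint velocities to hand velocities,
#' `arm_jacobian_dot()` is its total time derivative (needed to convert hand
#' accelerations to joint accelerations along a planned path).
#'
#' @inheritParams coriolis_vector
#' @return A 2x2 matrix.
#' @export
arm_jacobian <- function(q, params) {
  stopifnot(inherits(params, "arm_params_2d"))
  check_len(q, 2L, "q")
  s1 <- sin(q[1]); c1 <- cos(q[1])
  s12 <- sin(q[1] + q[2]); c12 <- cos(q[1] + q[2])
  l1 <- params$l1; l2 <- params$l2
  matrix(c(-l1 * s1 - l2 * s12, l1 * c1 + l2 * c12,
           -l2 * s12,           l2 * c12), 2L, 2L)
}

#' @rdname arm_jacobian
#' @export
arm_jacobian_dot <- function(q, qdot, params) {
  stopifnot(inherits(params, "arm_params_2d"))
  check_len(q, 2L, "q"); check_len(qdot, 2L, "qdot")
  c1 <- cos(q[1]); s1 <- sin(q[1])
  c12 <- cos(q[1] + q[2]); s12 <- sin(q[1] + q[2])
  w1 <- qdot[1]; w12 <- qdot[1] + qdot[2]
  l1 <- params$l1; l2 <- params$l2
  matrix(c(-l1 * c1 * w1 - l2 * c12 * w12, -l1 * s1 * w1 - l2 * s12 * w12,
           -l2 * c12 * w12,                -l2 * s12 * w12), 2L, 2L)
}
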