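#' Control laws
#'
#' Pure (side-effect free) implementations of the individual control laws;
#' [simulate_reach()] orchestrates them with the delay lines and forward
#' model. They are exported so each law can be exercised and tested in
#' isolation.
#'
#' @name control-laws
NULL

#' Computed-torque command
#'
#' Model-based feedback linearization: cancels the arm's velocity-product
#' torques exactly using known parameters, feeds the desired acceleration
#' through the inertia matrix, and adds proportional-derivative feedback
#' `kv (qdot_d - qdot) + kp (qd - q)` (gains act directly as torques per
#' rad, not through the inertia). Requires the exact plant model and
#' undelayed state.
#'
#' @param ref Reference sample: list with `q`, `qdot`, `qddot`.
#' @param q,qdot Current joint position/velocity.
#' @param kv,kp Feedback gain vectors (diagonal entries).
#' @param params Plant parameters ([arm_params()] or [arm_inertia()]).
#' @return Torque vector (N m).
#' @export
ctc_torque <- function(ref, q, qdot, kv, kp, params) {
  n <- n_joints(params)
  check_len(q, n, "q"); check_len(qdot, n, "qdot")
  fb <- kv * (ref$qdot - qdot) + kp * (ref$q - q)
  if (n == 1L) {
    params$J * ref$qddot + fb
  } else {
    drop(mass_matrix(q, params) %*% ref$qddot) +
      coriolis_vector(q, qdot, params) + fb
  }
}

#' Time-delay estimate of the lumped dynamics
#'
#' One-sample-old estimate `H_hat(t) = tau(t - dt) - beta_bar * qddot(t - dt)`
#' of the lumped unknown dynamics: everything the previous command did *not*
#' turn into acceleration through the assumed inertia `beta_bar` must have
#' been plant dynamics or disturbance, and is assumed piecewise continuous
#' across one sample.
#'
#' @param tau_prev Previous-step command vector.
#' @param accel_prev Previous-step joint acceleration: measured for plain
#'   TDC, the forward model's estimate for the Smith-architecture law.
#' @param beta_bar TDE gain vector (diagonal entries).
#' @return Estimated-dynamics torque vector.
#' @export
tde_estimate <- function(tau_prev, accel_prev, beta_bar) {
  tau_prev - beta_bar * accel_prev
}

#' Smith-corrected reference
#'
#' Shifts the planned trajectory by the mismatch between the delayed
#' measurement and the equally delayed internal estimate:
#' `qr = qd - (q(t - td) - qhat(t - td_hat))`. When the estimator is right
#' the two delayed signals cancel and the controller effectively acts on the
#' undelayed estimate. The same pattern is applied to the velocity and
#' acceleration histories (rather than differentiating `qr` numerically).
#'
#' @param ref Reference sample (`q`, `qdot`, `qddot`).
#' @param meas_delayed Delayed measurement: list `q`, `qdot`, `qddot`.
#' @param est_delayed Delayed estimator state: list `q`, `qdot`, `qddot`.
#' @param scope Which components receive the Smith correction:
#'   `"pos_vel"` (default) corrects position and velocity and passes the
#'   planned acceleration through unchanged; `"pos"` corrects position
#'   only; `"pos_vel_acc"` applies the pattern to all three components.
#'   See the package vignette for why feeding back the raw acceleration
#'   difference is destabilising under delay-estimate mismatch.
#' @return Corrected reference list (`q`, `qdot`, `qddot`).
#' @export
smith_reference <- function(ref, meas_delayed, est_delayed,
                            scope = c("pos_vel", "pos", "pos_vel_acc")) {
  scope <- match.arg(scope)
  list(q = ref$q - (meas_delayed$q - est_delayed$q),
       qdot = if (scope == "pos") ref$qdot else
         ref$qdot - (meas_delayed$qdot - est_delayed$qdot),
       qddot = if (scope == "pos_vel_acc")
         ref$qddot - (meas_delayed$qddot - est_delayed$qddot) else ref$qddot)
}

#' Smith-architecture TDC command
#'
#' The parameter-free internal-model control law
#' \deqn{\tau(t) = \tau(t-dt) - \bar\beta \ddot{\hat\theta}(t-dt) +
#'   \bar\beta(\ddot\theta_r + K_v(\dot\theta_r - \dot{\hat\theta}) +
#'   K_p(\theta_r - \hat\theta)),}
#' i.e. TDE dynamics cancellation (using the *estimated* previous
#' acceleration, so no acceleration sensing is needed) plus desired error
#' dynamics formed on the corrected reference and the forward-model state.
#'
#' @param tau_prev Previous command.
#' @param est_accel_prev Previous-step forward-model acceleration.
#' @param ref_corrected Corrected reference from [smith_reference()].
#' @param qhat,qhat_dot Current forward-model position/velocity estimates.
#' @param gains A [tdc_gains()] object.
#' @return Torque vector.
#' @export
proposed_torque <- function(tau_prev, est_accel_prev, ref_corrected,
                            qhat, qhat_dot, gains) {
  tde_estimate(tau_prev, est_accel_prev, gains$beta_bar) +
    gains$beta_bar * (ref_corrected$qddot +
                        gains$kv * (ref_corrected$qdot - qhat_dot) +
                        gains$kp * (ref_corrected$q - qhat))
}

#' Plain TDC command
#'
#' Time-delay control acting on the (undelayed) measured state with the
#' measured previous-step acceleration in the TDE term.
#'
#' @inheritParams proposed_torque
#' @param accel_prev Measured previous-step acceleration.
#' @param ref Reference sample.
#' @param q,qdot Measured joint state.
#' @return Torque vector.
#' @export
tdc_torque <- function(tau_prev, accel_prev, ref, q, qdot, gains) {
  tde_estimate(tau_prev, accel_prev, gains$beta_bar) +
    gains$beta_bar * (ref$qddot + gains$kv * (ref$qdot - qdot) +
                        gains$kp * (ref$q - q))
}

#' Forward-model dynamics
#'
#' The internal forward model is the desired closed-loop error dynamics
#' itself, \eqn{\ddot{\hat\theta} = -K_v \dot{\hat\theta} - K_p \hat\theta + p}
#' with forcing \eqn{p = \ddot\theta_r + K_v \dot\theta_r + K_p \theta_r}:
#' it predicts what the limb will do *assuming the inverse model succeeds in
#' imposing those dynamics*, and therefore needs no plant parameters.
#'
#' @param qhat,qhat_dot Forward-model state vectors.
#' @param p Forcing vector (see [fm_forcing()]).
#' @param gains A [tdc_gains()] object.
#' @return List `dq` (= `qhat_dot`), `dqdot` (the estimated acceleration).
#' @export
forward_model_derivative <- function(qhat, qhat_dot, p, gains) {
  list(dq = qhat_dot,
       dqdot = -gains$kv * qhat_dot - gains$kp * qhat + p)
}

#' @rdname forward_model_derivative
#' @param ref_corrected Corrected reference (`q`, `qdot`, `qddot`).
#' @export
fm_forcing <- function(ref_corrected, gains) {
  ref_corrected$qddot + gains$kv * ref_corrected$qdot + gains$kp * ref_corrected$q
}

#' Delay-compensating state predictor
#'
#' Propagates a delayed sensed state forward through the modelled limb
#' dynamics `(As, Bs)` driven by the recorded motor commands (zero-order
#' held at the controller period `dt`), yielding an estimate of the current
#' state. The propagation time is `length(commands) * dt`.
#'
#' @param q,qdot Sensed (delayed) scalar joint position/velocity.
#' @param commands Numeric vector of the commands issued over the prediction
#'   window, oldest first; may be empty (no propagation).
#' @param setup An [lq_setup()] object.
#' @param dt Controller sample period (s).
#' @return List `q`, `qdot`: the predicted current state.
#' @export
predictor_estimate <- function(q, qdot, commands, setup, dt) {
  J <- setup$J
  for (u in commands) {
    # exact ZOH discretization of the double integrator
    q <- q + qdot * dt + u / J * dt^2 / 2
    qdot <- qdot + u / J * dt
  }
  list(q = q, qdot = qdot)
}

#' LQ optimal command
#'
#' `tau = K %*% c(qd - qhat, qd_dot - qhat_dot)` with the steady-state LQ
#' gain.
#'
#' @param ref Reference sample.
#' @param qhat,qhat_dot Predicted current state (from
#'   [predictor_estimate()]).
#' @param setup An [lq_setup()] object.
#' @return Scalar torque.
#' @export
optimal_torque <- function(ref, qhat, qhat_dot, setup) {
  drop(setup$K %*% c(ref$q - qhat, ref$qdot - qhat_dot))
}

#' Delayed equilibrium-point command
#'
#' Proportional-derivative feedback toward the shifting reference using
#' delayed sensory signals, `tau = d (qdot_d(t) - qdot(t - t_dv)) +
#' p (qd(t) - q(t - t_dp))`. No anticipatory or internal-model component.
#' Note that with the position gain at zero (as tuned for the fast-movement
#' comparison) the position loop is disabled entirely and only the delayed
#' velocity servo acts.
#'
#' @param ref Reference sample.
#' @param q_delayed Position at `t - t_dp`.
#' @param qdot_delayed Velocity at `t - t_dv`.
#' @param gains An [ep_gains()] object.
#' @return Torque vector.
#' @export
ep_torque <- function(ref, q_delayed, qdot_delayed, gains) {
  gains$d * (ref$qdot - qdot_delayed) + gains$p * (ref$q - q_delayed)
}

# ---- controller specification objects ---------------------------------------

new_controller <- function(type, ...) {
  structure(list(type = type, ...), class = "reach_controller")
}

#' Controller specifications
#'
#' Constructors bundling a control law with its gains for use by
#' [simulate_reach()].
#'
#' * `controller_proposed()`: the TDC-Smith internal-model controller
#'   (parameter-free; uses the forward model and the configured delays).
#' * `controller_tdc()`: plain TDC on the undelayed measured state.
#' * `controller_ctc()`: computed-torque control, evaluated continuously
#'   inside the integrator (memoryless, delay-free, exact model).
#' * `controller_optimal()`: steady-state LQ feedback with the
#'   delay-compensating predictor (single-joint only).
#' * `controller_ep()`: delayed equilibrium-point control.
#' * `controller_none()`: zero torque (free swing; baseline/contrast runs).
#'
#' @param gains A [tdc_gains()] (proposed/tdc), [ep_gains()] (ep) object.
#' @param setup An [lq_setup()] object (optimal).
#' @param kv,kp CTC feedback gain vectors.
#' @param model Plant parameters the CTC believes; defaults to the true
#'   plant passed to [simulate_reach()].
#' @param accel_source Acceleration used in the TDE cancellation term of the
#'   Smith-architecture law: `"measured"` (default) takes the plant's
#'   previous-tick acceleration, which is the form the error-recursion
#'   analysis assumes and the one that actually cancels the plant dynamics;
#'   `"estimated"` takes the forward model's acceleration. The estimated
#'   variant avoids acceleration sensing but is degenerate: because the
#'   forward model's acceleration *is* the desired-dynamics bracket, the
#'   cancellation telescopes away and the command collapses to
#'   `beta_bar * nu`, leaving the plant under-driven by the factor
#'   `beta_bar / J` whenever the two differ. It is retained for comparison
#'   (at zero delay it coincides exactly with plain TDC).
#' @return An object of class `reach_controller`.
#' @export
#' @param scope Smith-correction scope, see [smith_reference()].
controller_proposed <- function(gains,
                                accel_source = c("measured", "estimated"),
                                scope = c("pos_vel", "pos", "pos_vel_acc")) {
  stopifnot(inherits(gains, "tdc_gains"))
  new_controller("proposed", gains = gains,
                 accel_source = match.arg(accel_source),
                 scope = match.arg(scope))
}

#' @rdname controller_proposed
#' @export
controller_tdc <- function(gains) {
  stopifnot(inherits(gains, "tdc_gains"))
  new_controller("tdc", gains = gains)
}

#' @rdname controller_proposed
#' @export
controller_ctc <- function(kv, kp, model = NULL) {
  new_controller("ctc", kv = kv, kp = kp, model = model)
}

#' @rdname controller_proposed
#' @export
controller_optimal <- function(setup) {
  stopifnot(inherits(setup, "lq_setup"))
  new_controller("optimal", setup = setup)
}

#' @rdname controller_proposed
#' @export
controller_ep <- function(gains) {
  stopifnot(inherits(gains, "ep_gains"))
  new_controller("ep", gains = gains)
}

#' @rdname controller_proposed
#' @export
controller_none <- function() new_controller("none")

#' @export
print.reach_controller <- function(x, ...) {
  cat(sprintf("<reach controller: %s>\n", x$type))
  invisible(x)
}
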