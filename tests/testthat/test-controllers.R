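test_that("computed-torque command assembles cancellation + feedforward + feedback", {
  # 1-DOF: J*qddot_d + Kp*e with zero velocity error
  ref <- list(q = 0.1, qdot = 0, qddot = 1)
  expect_equal(ctc_torque(ref, 0, 0, kv = 5, kp = 10, arm_inertia(2)),
               2 * 1 + 10 * 0.1)
  zero <- list(q = 0, qdot = 0, qddot = 0)
  expect_equal(ctc_torque(zero, 0, 0, 5, 10, arm_inertia(2)), 0)
  # 2-DOF: equals M qddot_d + C + feedback
  ref2 <- list(q = c(0.4, 0.9), qdot = c(0.3, -0.2), qddot = c(1, -2))
  q <- c(0.5, 1); qd <- c(1, 0.5)
  tau <- ctc_torque(ref2, q, qd, kv = c(2, 2), kp = c(30, 30), paper_arm)
  expect_equal(tau,
               drop(mass_matrix(q, paper_arm) %*% ref2$qddot) +
                 coriolis_vector(q, qd, paper_arm) +
                 2 * (ref2$qdot - qd) + 30 * (ref2$q - q))
})

test_that("TDE estimate is the previous command minus scaled acceleration", {
  expect_equal(tde_estimate(0, 0, 0.01), 0)
  expect_equal(tde_estimate(0.5, 10, 0.01), 0.4)
  expect_equal(tde_estimate(c(1, 2), c(10, 20), c(0.1, 0.2)), c(0, -2))
})

test_that("TDE converges to the true lumped dynamics on a cruise", {
  # constant-velocity cruise of the 2-DOF arm: H = (M - beta) qddot + C; the
  # one-sample-old estimate must match it to O(dt)
  sim <- proposed_two_joint_run()
  tr <- tde_error_trace(sim)$trace
  # during the movement the one-sample-old estimate lags by O(dt * dH/dt)
  mid <- tr$time > 0.2 & tr$time < 0.5
  dH <- max(abs(diff(tr$H_1)), abs(diff(tr$H_2))) / 1e-3
  expect_lt(max(abs(tr$H_hat_1[mid] - tr$H_1[mid])), 3 * dH * 1e-3)
  # once the arm settles the estimate matches the true dynamics closely
  # (movement-phase dynamics torques are of order 1 N m)
  late <- tr$time > 0.9
  expect_lt(max(abs(tr$H_hat_1[late] - tr$H_1[late])), 5e-3)
  expect_lt(max(abs(tr$H_hat_2[late] - tr$H_2[late])), 5e-3)
})

test_that("Smith correction shifts the reference by the delayed mismatch", {
  ref <- list(q = 1, qdot = 0.2, qddot = -1)
  meas <- list(q = 0.8, qdot = 0.1, qddot = 0.5)
  est <- list(q = 0.75, qdot = 0.12, qddot = 0.5)
  qr <- smith_reference(ref, meas, est)
  expect_equal(qr$q, 0.95)
  expect_equal(qr$qdot, 0.2 - (0.1 - 0.12))
  expect_equal(qr$qddot, -1)  # default scope passes the plan through
  qr_all <- smith_reference(ref, meas, est, scope = "pos_vel_acc")
  expect_equal(qr_all$qddot, -1)
  qr_pos <- smith_reference(ref, meas, est, scope = "pos")
  expect_equal(qr_pos$qdot, 0.2)
  # exact estimator: corrected reference equals the plan
  same <- list(q = 0.8, qdot = 0.1, qddot = 0.5)
  expect_equal(smith_reference(ref, meas, same), ref)
})

test_that("the Smith-architecture command matches its closed form", {
  g <- tdc_gains(0.01, 200, 500)
  qr <- list(q = 0, qdot = 0, qddot = 2)
  # first step from rest with zero errors: tau = beta * qddot_r
  expect_equal(proposed_torque(0, 0, qr, 0, 0, g), 0.02)
  # steady hold: all errors and accelerations zero -> command held
  hold <- list(q = 0.5, qdot = 0, qddot = 0)
  expect_equal(proposed_torque(0.37, 0, hold, 0.5, 0, g), 0.37)
})

test_that("forward model dynamics realize the desired error dynamics", {
  g <- tdc_gains(0.01, 25, 150)
  d0 <- forward_model_derivative(0, 0, 0, g)
  expect_equal(d0$dq, 0); expect_equal(d0$dqdot, 0)
  # constant forcing p = Kp * qstar makes qstar the fixed point
  qstar <- 0.8
  x <- c(0, 0); h <- 1e-3
  for (i in seq_len(5000)) {
    k1 <- unlist(forward_model_derivative(x[1], x[2], 150 * qstar, g))
    k2 <- unlist(forward_model_derivative(x[1] + h / 2 * k1[1], x[2] + h / 2 * k1[2], 150 * qstar, g))
    k3 <- unlist(forward_model_derivative(x[1] + h / 2 * k2[1], x[2] + h / 2 * k2[2], 150 * qstar, g))
    k4 <- unlist(forward_model_derivative(x[1] + h * k3[1], x[2] + h * k3[2], 150 * qstar, g))
    x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  expect_equal(unname(x[1]), qstar, tolerance = 1e-6)
  expect_equal(unname(x[2]), 0, tolerance = 1e-6)
})

test_that("forward-model forcing follows the corrected reference", {
  g <- tdc_gains(0.01, 25, 150)
  qr <- list(q = 0.2, qdot = 0.5, qddot = -1)
  expect_equal(fm_forcing(qr, g), -1 + 25 * 0.5 + 150 * 0.2)
})

test_that("LQ gain solves the Riccati equation", {
  # closed form for the double integrator with Q = I, R = 1: K = [1, sqrt(3)]
  A <- matrix(c(0, 0, 1, 0), 2); B <- matrix(c(0, 1))
  sol <- lqr_gain(A, B, diag(2), 1)
  expect_equal(drop(sol$K), c(1, sqrt(3)), tolerance = 1e-9)
  expect_lt(sol$residual, 1e-10)
  # zero state weight: zero gain
  expect_equal(drop(lqr_gain(A, B, 0 * diag(2), 1)$K), c(0, 0), tolerance = 1e-10)
  # catalogued limb setting
  setup <- lq_setup(Q = diag(c(500, 500)), R = 2, J = 0.165)
  expect_lt(setup$riccati_residual, 1e-8)
  # closed loop is stable
  eigs <- eigen(setup$As - setup$Bs %*% setup$K, only.values = TRUE)$values
  expect_true(all(Re(eigs) < 0))
})

test_that("LQ closed-loop error decays from a small offset", {
  # regulation about a fixed target through the packaged simulator
  setup <- lq_setup(Q = diag(c(500, 500)), R = 2, J = 0.165)
  task <- min_jerk_task(0.02, 0, 1e-3)  # near-step to the origin
  # ten time constants of the slow closed-loop mode (about -1 rad/s)
  sim <- simulate_reach(task, controller_optimal(setup), arm_inertia(0.165),
                        sim_config(dt = 1e-3, horizon = 10, td = 0, td_hat = 0,
                                   t_lead = 0))
  expect_false(sim$diverged)
  expect_lt(abs(sim$signals$q_1[nrow(sim$signals)]), 1e-4)
})

test_that("predictor propagates the delayed state through the limb model", {
  setup <- lq_setup(J = 0.165)
  dt <- 1e-3
  # no propagation: state unchanged
  p0 <- predictor_estimate(0.3, 1.2, numeric(0), setup, dt)
  expect_equal(p0, list(q = 0.3, qdot = 1.2))
  # ballistic propagation over 65 ms
  m <- 65
  pb <- predictor_estimate(0.3, 1.2, rep(0, m), setup, dt)
  expect_equal(pb$q, 0.3 + 1.2 * 0.065, tolerance = 1e-12)
  expect_equal(pb$qdot, 1.2)
  # constant command: closed-form double-integrator response
  tau <- 0.4
  pc <- predictor_estimate(0.3, 1.2, rep(tau, m), setup, dt)
  expect_equal(pc$qdot, 1.2 + tau / 0.165 * 0.065, tolerance = 1e-12)
  expect_equal(pc$q, 0.3 + 1.2 * 0.065 + tau / 0.165 * 0.065^2 / 2,
               tolerance = 1e-12)
})

test_that("optimal and equilibrium-point commands follow their formulas", {
  setup <- lq_setup(J = 0.165)
  ref <- list(q = 0.5, qdot = 0.1, qddot = 0)
  expect_equal(optimal_torque(ref, 0.5, 0.1, setup), 0)
  setup$K <- matrix(c(2, 1), 1)
  expect_equal(optimal_torque(ref, 0, 0.2, setup), 2 * 0.5 + 1 * (-0.1))

  g <- ep_gains(p = 0, d = 0.76)
  expect_equal(ep_torque(list(q = 1, qdot = 1, qddot = 0), 0.2, 0, g), 0.76)
  expect_equal(ep_torque(list(q = 1, qdot = 0, qddot = 0), 1, 0,
                         ep_gains(p = 3, d = 2)), 0)
})

test_that("gain constructors enforce positivity and delay signs", {
  expect_error(tdc_gains(0, 1, 1), "positive")
  expect_error(ep_gains(p = -1), ">= 0")
  expect_error(ep_gains(t_dv = -0.1), ">= 0")
  g <- tdc_gains(0.01, c(25, 25), 150)
  expect_length(g$kp, 2)
})
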