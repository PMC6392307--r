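test_that("metrics on the reference trajectory itself are ideal", {
  tt <- seq(0, 1, by = 1e-3)
  task <- pinter_task_fix
  prof <- lapply(tt, function(t) min_jerk_sample(t - 0.1, task))
  df <- tibble::tibble(time = tt,
                       q = vapply(prof, `[[`, numeric(1), "q"),
                       qdot = vapply(prof, `[[`, numeric(1), "qdot"))
  df$qd <- df$q
  m <- movement_metrics(df, qf = task$to, t_onset = 0.1, duration = 0.25)
  expect_equal(m$endpoint_error_deg, 0)
  expect_equal(m$peak_velocity_deg_s, 1.875 * 35 / 0.25, tolerance = 1e-3)
  # the realised movement time ends at the 5 deg/s reversal threshold, a
  # shade before the planned duration, so the ratio sits just above 1/2
  expect_equal(m$rel_time_to_peak, 0.5, tolerance = 0.05)
  expect_equal(m$oscillation_count, 0L)
  expect_equal(m$tracking_rmse_deg, 0)
})

test_that("a constant hold at the target has zero error and no oscillations", {
  df <- tibble::tibble(time = seq(0, 1, by = 1e-3), q = 0.9, qdot = 0)
  m <- movement_metrics(df, qf = 0.9, t_onset = 0, duration = 0.2)
  expect_equal(m$endpoint_error_deg, 0)
  expect_equal(m$oscillation_count, 0L)
})

test_that("oscillation counting matches the closed-form damped oscillation", {
  # terminal ring about the target: q = qf + A exp(-lam t) cos(w t)
  A <- deg2rad(5); w <- 2 * pi * 4; lam <- 3; qf <- 0.9
  tt <- seq(0, 2, by = 1e-4)
  q <- qf + A * exp(-lam * tt) * cos(w * tt)
  qdot <- A * exp(-lam * tt) * (-lam * cos(w * tt) - w * sin(w * tt))
  df <- tibble::tibble(time = tt, q = q, qdot = qdot)

  # closed-form oracle: velocity zeros lie at w t = pi/2 + k pi + delta with
  # delta = atan2(-w, lam); the excursion peak of the half-cycle starting at
  # a zero t_k is A exp(-lam t_k) |sin delta| (extrema of a log-spiral
  # cosine), so the count is the number of successive zeros whose preceding
  # half-cycle amplitude still reaches 2 degrees
  delta <- atan2(-w, lam)
  zk <- (pi / 2 + (1:12) * pi + delta) / w
  amp <- A * exp(-lam * zk) * abs(sin(delta))
  # first half-cycle (reversal -> first zero) carries amplitude >= amp[1]
  expected <- 1L + sum(cumprod(amp[-length(amp)] >= deg2rad(2)))

  m <- movement_metrics(df, qf = qf, t_onset = 0, duration = 0.2)
  expect_equal(m$oscillation_count, expected)
  expect_gt(m$oscillation_count, 0)
})

test_that("TDE error trace satisfies its defining identity and recursion", {
  sim <- tdc_pinter_run()
  diag <- tde_error_trace(sim)
  tr <- diag$trace
  # eps = nu - qddot holds identically by construction
  expect_equal(tr$eps_1, tr$nu_1 - sim$signals$qddot_1)
  # constant-inertia plant: the recursion is exact algebra
  rel <- max(abs(tr$residual_1), na.rm = TRUE) / max(abs(tr$eps_1), 1)
  expect_lt(rel, 1e-10)
  # eta vanishes for constant inertia
  expect_lt(max(abs(tr$eta_1), na.rm = TRUE), 1e-12)
  expect_equal(diag$spectral_margin, abs(1 - 0.15 / 0.165), tolerance = 1e-12)
})

test_that("TDE recursion stays exact on the configuration-dependent arm", {
  sim <- proposed_two_joint_run()
  tr <- tde_error_trace(sim)$trace
  scale <- max(abs(tr$eps_1), abs(tr$eps_2), 1)
  expect_lt(max(abs(tr$residual_1), na.rm = TRUE) / scale, 1e-9)
  expect_lt(max(abs(tr$residual_2), na.rm = TRUE) / scale, 1e-9)
  # eta is nonzero here (inertia matrix varies along the movement)
  expect_gt(max(abs(tr$eta_1), na.rm = TRUE), 0)
})

test_that("TDE error decays geometrically after a step disturbance", {
  # hold task + step load: after the step the forcing terms zeta, eta are
  # negligible and the recursion's homogeneous solution dominates, so
  # |eps(k)| should shrink by |1 - beta/J| per controller tick
  task <- min_jerk_task(0.3, 0.3, 0.1)
  g <- tdc_gains(0.08, 10, 25)
  sim <- simulate_reach(task, controller_tdc(g), arm_inertia(0.165),
                        sim_config(dt = 1e-3, horizon = 0.5, t_lead = 0),
                        load = function(t, q, qd) 0.5)
  tr <- tde_error_trace(sim)$trace
  r_pred <- 1 - 0.08 / 0.165
  seg <- 3:10
  ratios <- tr$eps_1[seg + 1] / tr$eps_1[seg]
  expect_equal(mean(ratios), r_pred, tolerance = 0.05)
})

test_that("spectral margin evaluates the TDE stability condition", {
  expect_equal(stability_margin(tdc_gains(0.15, 25, 150), arm_inertia(0.165)),
               abs(1 - 0.15 / 0.165), tolerance = 1e-12)
  expect_equal(stability_margin(tdc_gains(0.33, 25, 150), arm_inertia(0.165)),
               1, tolerance = 1e-12)                           # beta = 2J
  expect_equal(stability_margin(tdc_gains(0.40, 25, 150), arm_inertia(0.165)),
               abs(1 - 0.40 / 0.165), tolerance = 1e-12)       # > 1
  # two-link margin is the worst posture's spectral radius and is < 1 for
  # the catalogued gains
  m2 <- stability_margin(tdc_gains(c(0.018, 0.015), 25, 150), paper_arm)
  expect_lt(m2, 1)
  expect_gt(m2, 0.8)  # shoulder inertia dwarfs beta_bar: slow but stable
})

test_that("hand-path metrics measure deviation from the straight line", {
  sim <- proposed_two_joint_run()
  pm <- path_metrics(sim)
  expect_lt(pm$endpoint_error_mm, 5)
  expect_gt(pm$max_deviation_mm, 0)
  expect_lt(pm$max_deviation_mm, 50)
})
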