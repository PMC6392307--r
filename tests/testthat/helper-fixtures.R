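# Shared fixtures. Expensive closed-loop runs are cached so that unit and
# acceptance tests can share them without re-simulating.

paper_arm <- arm_params()  # anthropometric defaults used throughout

fast_task_fix <- min_jerk_task(deg2rad(45), deg2rad(145), 0.2)
pinter_task_fix <- min_jerk_task(deg2rad(50), deg2rad(85), 0.25)

.sim_cache <- new.env(parent = emptyenv())
cached <- function(key, fn) {
  if (is.null(.sim_cache[[key]])) assign(key, fn(), envir = .sim_cache)
  .sim_cache[[key]]
}

fast_results_65 <- function() cached("fast65", function() exp_single_joint_fast(0.065))
fast_proposed_300 <- function() {
  cached("fast300", function() exp_single_joint_fast(0.3, controllers = "proposed"))
}
inertial_results <- function() cached("inertial", function() exp_inertial_change())

# plain-TDC run on the intermediate-load task: the TDE error recursion is
# exact algebra on this constant-inertia plant
tdc_pinter_run <- function() {
  cached("tdc_pinter", function() {
    simulate_reach(pinter_task_fix,
                   controller_tdc(tdc_gains(0.15, 25, 150)),
                   arm_inertia(0.165),
                   sim_config(dt = 1e-3, horizon = 0.6))
  })
}

# proposed-controller run on the two-joint reach (varying inertia matrix)
proposed_two_joint_run <- function() {
  cached("prop_2j", function() {
    task <- min_jerk_task(c(-0.2, 0.5), c(0.25, 0.35), 0.5, space = "cartesian")
    simulate_reach(task,
                   controller_proposed(
                     tdc_gains(c(0.018, 0.015), c(25, 25), c(150, 150))),
                   paper_arm, sim_config(dt = 1e-3, horizon = 1.1))
  })
}

expect_all_finite <- function(x) expect_true(all(is.finite(as.matrix(x))))
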