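Package: armtdc
Title: Time-Delay Estimation Control for Simulated Arm Reaching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Closed-loop simulation of planar single- and two-joint arm
    reaching under sensory feedback delay. Implements a parameter-free
    internal-model controller that combines time-delay estimation (TDE) with
    the Smith-predictor architecture, alongside three comparison controllers:
    computed-torque control, steady-state linear-quadratic optimal control
    with a delay-compensating state predictor, and delayed equilibrium-point
    control. Provides minimum-jerk reference trajectories, a hybrid
    discrete/continuous delay-line simulation engine, movement kinematic
    metrics (endpoint error, peak velocity, oscillation counting), TDE
    error-recursion diagnostics with a spectral stability margin, and
    parameter-sensitivity sweeps, all returned as tidy tibbles with
    ggplot2 autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    Matrix,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
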