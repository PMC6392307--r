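---
title: "Internal-model control without plant parameters: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Internal-model control without plant parameters: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(armtdc)
```

## The question the simulator addresses

Reaching movements are fast relative to sensory feedback delays (tens to
hundreds of milliseconds), and multi-joint movements generate interaction
torques that pure feedback control cannot anticipate. The classical account
is that the central nervous system maintains *internal models*: an inverse
model that maps a planned trajectory to motor commands, and a forward model
that predicts the sensory consequences of those commands. Both are usually
assumed to embody an accurate parametric model of limb dynamics, acquired
through long practice.

`armtdc` simulates an alternative: both internal models can be built
*without plant parameters* by time-delay estimation (TDE). The lumped,
unknown limb-plus-environment dynamics

$$H(t) \;=\; \bigl(M(\theta) - \bar\beta\bigr)\ddot\theta + C(\theta,\dot\theta) + \dots$$

is estimated one controller sample late from the efference copy and its
kinematic consequence,

$$\hat H(t) \;=\; \tau(t-\mathrm{d}t) - \bar\beta\,\ddot\theta(t-\mathrm{d}t),$$

and injected back into the command so that the residual closed loop follows
chosen error dynamics $\ddot e + K_v\dot e + K_p e = 0$. Sensory delay is
handled with a Smith-predictor architecture: a forward model — itself
parameter-free, because it simply integrates the *desired* error dynamics —
supplies an undelayed state estimate, and its intentionally delayed copy
cancels the delayed measurement,

$$\theta_r(t) = \theta_d(t) - \bigl(\theta(t-t_d) - \hat\theta(t-\hat t_d)\bigr).$$

Three comparison controllers are implemented on the same engine: computed
torque (exact model-based feedback linearization), steady-state LQ optimal
control with a model-based delay-compensating predictor, and delayed
equilibrium-point (PD) control with no anticipatory component.

## Plant, reference, and tasks

The plant is a planar two-link arm (shoulder/elbow; gravity-free
horizontal plane, no friction) with the anthropometric defaults of
`arm_params()`, or a single-joint inertia `arm_inertia(J)`. The Coriolis
vector uses the Christoffel form with a negative shoulder component: the
positive-sign variant printed in some treatments does not conserve kinetic
energy in free motion, which the test suite checks explicitly.

References are rest-to-rest minimum-jerk trajectories. The default blend is
the standard quintic $10t'^3 - 15t'^4 + 6t'^5$, whose velocity and
acceleration vanish at both ends; the degree-6 blend $6t'^6 - 15t'^5 +
10t'^4$ that sometimes appears in print reaches the target with velocity
$|q_f - q_0|/T \ne 0$, violating the rest-to-rest premise of every task
simulated here, and is retained only behind `poly = "degree6"`. Two-joint
tasks are planned as straight Cartesian hand paths and mapped to joint
space through closed-form inverse kinematics and the arm Jacobian.

Three tasks are packaged: a fast elbow flexion 45°→145° in 0.2 s; a
two-joint reach (−0.2, 0.5) m → (0.25, 0.35) m at 0.5 s and 1 s; and an
elbow flexion 50°→85° in 0.25 s with the gains tuned on an intermediate
inertia J = 0.165 kg m² that is swapped, unannounced, for 0.12 (ML) or
0.205 (MH). The single-joint plant for the fast task defaults to the
forearm inertia J₂ = 0.0188 kg m², the same state-space limb model the LQ
predictor uses; with the larger composite forearm value (≈0.074 kg m²,
available as an argument) the LQ controller's bandwidth at the catalogued
weights is too low to track the 0.2-s movement, so the forearm-only value
is the one under which all four controllers behave as reported.

## The simulation engine

The engine is a hybrid discrete/continuous loop. The controller runs at a
fixed sample period `dt` with zero-order-hold commands; the TDE lag is
exactly one controller sample. Within each tick the plant is integrated
continuously: the single-joint ZOH plant in closed form (exact), the
two-link plant by fixed-step RK4 with `n_substeps` substeps. The forward
model is the linear ODE $\ddot{\hat\theta} = -K_v\dot{\hat\theta} -
K_p\hat\theta + p$ with forcing held per tick, so its RK4 update is
precomputed once as a linear map (RK4 on a constant linear system is the
degree-4 Taylor truncation of the matrix exponential); the test suite
verifies the integrated estimator against the exact matrix-exponential
solution to 10⁻⁶. Delayed signals are read from tick-indexed histories with
linear interpolation and an initial-value pre-history (positions and
velocities hold their initial values for $t \le 0$, commands are zero).

`dt` defaults to 0.1 ms. The choice matters scientifically, not just
numerically: TDE is exact only in the continuous-time limit, and every
tracking-error figure of the scheme scales roughly linearly with `dt`. At
0.1 ms the fast task tracks its reference to ≈0.4° RMS; at 1 ms the same
configuration misses by ≈4°. We regard the small-`dt` limit as the modelled
condition and keep `dt` configurable for studying the degradation.

Divergence (|q| > 10⁴ rad or a non-finite state) truncates a run and sets a
flag instead of raising, because the sensitivity sweeps deliberately visit
unstable regions. Runs are deterministic: identical configurations give
byte-identical outputs.

## Two places where the printed equations cannot be meant literally

Both are established by direct experiment in this package's history and
test suite; both variants remain selectable so the degeneracies can be
reproduced.

**The TDE cancellation term.** Written literally, the Smith-architecture
command subtracts $\bar\beta$ times the *forward model's* previous
acceleration. But the forward model's acceleration *is* the
desired-dynamics bracket by construction, so the subtraction telescopes and
the command collapses to $\tau = \bar\beta\nu$: no dynamics estimation
occurs and the plant is under-driven by the factor $\bar\beta/J$ (the fast
task then peaks at 665°/s instead of ≈937°/s). The error-recursion analysis
that justifies the scheme is written for the *measured* previous
acceleration, and only that form cancels the dynamics; it is the default
(`accel_source = "measured"`). At zero delay both forms reduce exactly to
plain TDC, which the tests verify to 10⁻⁹.

**The scope of the Smith correction.** The delayed-mismatch correction is
defined for position; the controller also needs corrected velocity and
acceleration. Applying the same pattern to the acceleration feeds the raw
delayed acceleration difference back with unit gain and no damping: with a
15 ms error in the delay estimate the loop is effectively unstable (the
fast task ends 450° from target). The default corrects position and
velocity and passes the planned acceleration through (`scope = "pos_vel"`),
which leaves matched-delay behaviour unchanged and degrades gracefully
under mismatch (±5 ms: <0.2°; ±15 ms: ≈5°, bounded).

A further structural consequence worth knowing: because the forward model
is forced by the corrected reference through its own desired dynamics, its
output equals the corrected reference identically (the transfer function is
a pole-zero cancellation). The stiffness and viscosity gains therefore act
on a signal that is zero up to discretization ripple, and in nominal
conditions tracking quality is governed almost entirely by $\bar\beta$ and
`dt`, not by $K_p$. This is why the packaged stiffness sweep shows only a
weak (and slightly inverted) dependence on $K_p$, while reproducing cleanly
the reported failure of low $\bar\beta$ (≈5×10⁻³) even at high stiffness.

## Stability diagnostics

The TDE estimation error obeys the linear recursion
$\epsilon(k) = (I - M^{-1}\bar\beta)\,(\epsilon(k-1) + \zeta(k-1)) + \eta(k-1)$
with forcing terms $\zeta$ (change of the desired-dynamics input) and
$\eta$ (change of the configuration-dependent dynamics; the $f$-difference
is premultiplied by $M^{-1}$, which the constant- and varying-inertia
residual tests confirm is the consistent form). `tde_error_trace()`
reconstructs all terms from a stored run and verifies the recursion
residual at floating-point level; `stability_margin()` evaluates the
spectral radius of $I - M(q)^{-1}\bar\beta$ over postures. The acceptance
suite shows that closed-loop divergence over a $(\bar\beta, J)$ grid
coincides with margin > 1 (a ±5% band around the boundary is treated as
indeterminate at finite horizon).

## Movement metrics

`movement_metrics()` reports endpoint error, peak angular velocity, the
time to peak velocity *relative to the realised movement time* (onset to
the reversal point, the first post-peak instant with |ω| < 5°/s — using the
realised rather than planned duration is what makes the load-ordering of
this measure come out as observed empirically), an oscillation count
(velocity zero-crossings from the reversal point until the per-half-cycle
peak excursion about the target falls below 2°), and tracking RMSE over a
stated window (default: the movement interval; the fast-task experiments
use 0.1–0.3 s with the standard 0.1 s quiescent lead-in). Endpoint error is
measured at the simulation horizon (1 s for single-joint tasks; movement
time plus a fixed 0.5 s settling window for two-joint tasks).

## What the experiments show

```{r experiments, eval = FALSE}
exp_single_joint_fast(delay = 0.065)   # proposed tracks; EP fails; LQ tracks
exp_single_joint_fast(delay = 0.3, controllers = "proposed")
exp_two_joint()                        # comparable path deviation at 0.5 s and 1 s
exp_inertial_change()                  # equifinality for TDE, residual error for LQ
sweep_beta_kp()                        # low beta_bar underperforms at any stiffness
sweep_delay_estimate()                 # ±15 ms delay mismatch tolerated, 500 ms not
```

The equifinality experiment is the discriminating one: after the
unannounced load swap the TDE controller still ends within 0.02° of the
target under all three loads, because whatever dynamics the new load
produces is re-estimated within a few samples; the LQ controller, whose
predictor and gain are committed to J = 0.165, leaves endpoint errors an
order of magnitude larger (and increasing with the size of the mismatch) at
the 1-s horizon. Peak velocity, relative time-to-peak and oscillation count
all decrease (weakly) from ML to MH for both controllers, matching the
perturbation literature.

## What the synthetic conditions do and do not cover

All inputs are task specifications; there is no empirical data in the
package, and passing tests show reproduction of the *simulated* phenomena,
not agreement with human kinematic recordings. The plant has no muscle
dynamics, signal-dependent noise, joint limits, or gravity; sensory
feedback is a single lumped delayed channel without noise; controller gains
are constant within a movement (no impedance modulation near the target,
which is why post-0.3 s behaviour of the fast task is not compared against
experiment). The delayed equilibrium-point controller is simulated with the
catalogued zero position gain, which disables its position loop entirely —
a tuned, not structural, property worth remembering when reading its
failure on the fast task.

## Numerical choices, collected

- `dt = 1e-4` s controller period and TDE lag (see above); `n_substeps = 2`.
- RK4 throughout; forward model via precomputed linear RK4 maps.
- Delay queries interpolate linearly; acceleration histories clamp to the
  newest stored sample (they lag the state histories by one tick).
- Divergence threshold 10⁴ rad; divergence is a flag, not an error.
- Riccati equations are solved by the Hamiltonian-eigenvector method with a
  residual check at 10⁻⁸; `Q = 0` is special-cased to the minimal solution.
- The inverse kinematics always returns the elbow-flexed (q₂ ≥ 0) branch.
- Angles are degrees at the interface (tasks, metrics, CLI) and radians
  internally; times are seconds internally, milliseconds in the CLI.
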