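---
title: "Hierarchical neuromuscular reaching and human-aware robot assistance: models and methods"
author: "reacharm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical neuromuscular reaching and human-aware robot assistance: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`reacharm` simulates planar point-to-point human reaching as the closed-loop
interplay of three levels of the sensorimotor hierarchy, and uses the
resulting forward model inside a robot controller that minimizes the user's
predicted neuromuscular effort during physical interaction. This vignette is
the package's account of the science: the models, their assumptions, the
parameters that matter, the numerical choices, and what the bundled
experiments do and do not demonstrate.

## 1. The high-level module: optimal control on an internal model

The highest level plans and perceives in an *abstract task space*: the brain
is modeled as controlling a 2-D point mass of mass $m = 3\,$kg driven by two
abstract muscles that can push and pull. Each abstract muscle produces force
$a_i F_{max}$ ($F_{max} = 1000\,$N) where the activation follows first-order
dynamics $\tau \dot a_i = u_i - a_i$ with $\tau = 30\,$ms. Discretized by
forward Euler at $\Delta t = 5\,$ms, the state
$X = [x, y, \dot x, \dot y, a_x, a_y]$ (expressed target-relative, so the
origin means "at the target, at rest, muscles off") evolves as

$$X_{k+1} = A X_k + B u_k + \textstyle\sum_i \varepsilon_{i,k} C_i u_k + \xi_k,$$

with *signal-dependent* motor noise: each command channel adds Gaussian noise
whose standard deviation is $0.2\,|u_i|$, entering through the corresponding
column of $B$ ($C_i = 0.2\, B e_i e_i^T$). Sensory feedback is a full noisy
readout of the state delayed by $d = 50\,$ms, and the controller minimizes
the finite-horizon quadratic cost with a *dwell* structure: the state
penalty is zero for the first $N - D$ steps and the identity for the final
$D = 21$ steps, while the control penalty $R = I_2$ is always active. The
controller must therefore arrive and stay at rest during the dwell, but the
path is left free — the canonical recipe from which straight paths and
bell-shaped speed profiles emerge.

Because the noise is multiplicative, the optimal feedback gains $L^*_k$ (with
$u_k = L^*_k \hat X_k$) and the Kalman gains $K_k$ are no longer separable;
`solve_ofc()` alternates the coupled backward (controller) and forward
(filter) Riccati-type recursions until the gains change by less than
$10^{-9}$, usually in well under ten alternations. With the multiplicative
scale set to zero the recursions collapse to the classical finite-horizon
LQR and Kalman solutions, which the test suite verifies against independent
textbook implementations to $10^{-8}$.

**Sensory delay.** The delay is realized with ring buffers rather than state
augmentation, keeping the belief 6-dimensional: raw measurements wait
$n_d = d / \Delta t = 10$ ticks in a buffer; the Kalman filter runs on the
*delayed time base* (it estimates the state of $n_d$ ticks ago, which is
exactly what the oldest buffered measurement observes, using the command of
the same age from a parallel command buffer); and the current belief is the
forward prediction of that delayed estimate through the internal model using
the buffered recent commands. This is the standard predictor treatment of
sensory delay in this model family. A 66-dimensional augmented-observation
formulation would make the delay-optimal gains exact; we chose the
predictor form because it preserves the 6-dimensional belief and, at these
noise levels, the gain schedules differ negligibly while closed-loop
behavior is indistinguishable in the bundled experiments. With $d = 0$ the
two coincide exactly.

**Estimation noise $\eta$.** The stated estimation-noise covariance is
2-dimensional while the estimate has six states; we inject it through the
two command channels of $B$ (the only 2-D input port of the estimator),
which is the smallest-assumption reading and is numerically irrelevant at
its $10^{-9}$ scale.

**Dwell penalty.** The dwell penalty is literally diag$_6(1)$, i.e. it also
penalizes residual abstract activations, asking for a genuinely relaxed
arrival; we implement that literally.

## 2. The mid-level module: muscle synergies

The 2-D command must become six non-negative muscle excitations. A *synergy*
is a fixed non-negative co-activation pattern $S_i \in \mathbb{R}^6_{\ge 0}$;
its action in task space is the hand-force vector $B_i$ produced by
activating the pattern isometrically. Online, the desired hand force is
decomposed onto the four synergy force vectors by non-negative least
squares, $\min_{C \ge 0} \|BC - u\|^2$, and the excitations are the clipped
weighted sum $e = \mathrm{clip}(SC, 0, 1)$. Clipping to $[0,1]$ is required
by the excitation semantics of the activation dynamics; in the bundled
experiments commands stay far below the clip.

**Offline synergy learning.** The synergies are learned once per arm model:
minimum-effort static activation patterns ($\min \|a\|^2$ subject to the
isometric statics map producing the force, $0 \le a \le 1$) are computed for
16 unit forces equally spaced on the circle at the reference posture, and
the resulting $6 \times 16$ matrix is reduced to 4 non-negative components
by multiplicative-update NMF (seeded, deterministic), normalized to unit
maximum element. Four synergies reconstruct the sampled optimal activations
with $R^2 \ge 0.9$ and their force vectors positively span the plane, so
every commanded direction is reachable within the synergy cone. The
load-sharing equality constraint is enforced through a weighted NNLS
formulation (weight $10^4$; constraint violation of order $10^{-8}$ N,
verified to $10^{-6}$ N), with a box-constrained refinement when the
unbounded solution would exceed full activation.

**Velocity compensation.** The linear point-mass abstraction knows nothing
of the arm's velocity-product (Coriolis/centrifugal) accelerations, so the
desired hand force is $u F_{max}$ *plus* the task-space equivalent
$J^{-T} c(q, \dot q)$ of those joint torques, computed from the known arm
dynamics; the correction vanishes identically at rest.

**Posture dependence.** By default the basis is recomputed from the muscle
geometry at the current posture every tick (the statics map changes
meaningfully over a 25 cm reach); the synergy patterns themselves stay
fixed, which is the part that corresponds to a stored motor memory.

## 3. The low-level module: the musculoskeletal arm

The plant is a planar shoulder–elbow linkage (upper arm 0.30 m / 1.9 kg,
forearm 0.33 m / 1.1 kg, anthropometric COMs and inertias, no gravity —
tabletop movements) actuated by six Hill-type muscles: mono-articular
flexor/extensor pairs at each joint plus a bi-articular pair. Muscle paths
are straight origin–insertion lines; moment arms are the exact analytic
derivatives $-\partial \ell_i / \partial q_j$ of those path lengths (2–7 cm
at the reference posture, extensor insertions behind the elbow so the flexed
joint keeps extensor leverage). Muscle force is
$F = a\, f_l(\ell/\ell_0)\, f_v(\dot\ell / (v_{max}\ell_0))\, F_{max}$ with a
Gaussian force–length bell of width 0.4 centred on $\ell_0$ (set to each
muscle's length at the reference posture), a Hill hyperbola on the
shortening side ($f_v(-1) = 0$, curvature constant 0.25), and a smooth
saturating eccentric branch plateauing at 1.5, joined $C^1$ at zero
velocity. Excitation-to-activation dynamics uses activation-dependent rates
($\tau_{act} = 15\,$ms, $\tau_{deact} = 50\,$ms). Tendon compliance,
pennation, and wrapping are deliberately absent. All fixture values are a
documented synthetic stand-in, overridable via the configuration file; the
package's tests depend on properties of the model, never on these numbers.

**Endpoint inertia and the hand mass.** A point mass of 1.8 kg at the hand
(hand plus grasped load) is part of the fixture. This makes the arm's
endpoint inertia (eigenvalues ≈ 2.5–3.6 kg across the workspace) consistent
with the 3 kg point mass the internal model assumes. That consistency is
not cosmetic: the high-level gains are tuned for a 3 kg plant, and an arm
that is much lighter at the hand closes the 50 ms-delayed loop at roughly
2.5× the design gain, which destabilizes the dwell phase. We read this as a
modeling constraint the architecture itself imposes — the brain's internal
model and the limb it controls must agree about gross dynamics — and chose
the fixture accordingly.

The full plant state (joints, activations, and robot joints when coupled)
is integrated with fixed-step RK4 at the 5 ms controller clock, with
excitations and robot torques held constant across each tick.

## 4. Robot, coupling, and environment

The robot is a two-link planar arm (0.3 m / 0.5 kg / 0.15 m COM /
$5\times10^{-3}$ kg m² per link) whose base sits 0.75 m anterior to the
shoulder, so that all scenario start and target points lie well inside both
workspaces; its elbow branch is chosen at initialization opposite to the
human's to stay clear of singularities. The hand is attached to the
end-effector by a revolute joint, modeled as a 2-D position constraint
solved at acceleration level together with both free-body equations — one
6×6 linear system per evaluation whose Lagrange multiplier *is* the
interaction force (force on the human, exact negation on the robot).
Baumgarte stabilization ($\alpha = \beta = 20\,$s$^{-1}$) keeps position
drift below $10^{-6}$ m over full simulations. The curl force field
$F = b\,[[0,1],[-1,0]]\,v$ applies at the hand with $b = \pm 3$ N s/m.

## 5. The human-aware controller

The robot's NMPC rolls the *entire* closed-loop human model forward
$N_p = 50$ steps under candidate torque profiles and minimizes the predicted
mean squared excitation $J = \frac{1}{N_p}\sum_k |e_k|^2$. Torques are
parameterized per joint as a quadratic polynomial in the horizon index, so
each re-plan optimizes six coefficients. The optimizer is box-constrained
quasi-Newton (L-BFGS-B with finite-difference gradients), multi-started
from the one-step-shifted previous solution and from the zero profile, and
the returned profile is never worse than the better of those two starts, so
the controller can only help relative to an unactuated robot at the
planning stage. Coefficient bounds of ±20 N m (scaled down for the linear
and quadratic terms) keep the search bounded; an unconstrained effort-only
objective would be ill-posed. Optimization is skipped when the incumbent
objective is already below $10^{-6}$ (e.g., before movement onset), which
is also why warm-started runs are fast. The rollout itself runs in the
package's compiled (C++) engine, which mirrors the R reference stepper
exactly; the test suite asserts agreement at machine precision, and the
plain-R path remains available (`engine = "reference"`).

The baseline assistive controller is an end-effector impedance law
($k_p = 50$ N/m, $k_d = 10$ N s/m) tracking the stored free-reach
trajectory advanced by 50 ms, mapped to joint torques through the robot
Jacobian transpose.

The NMPC is given direct access to the simulation snapshot (target, timing,
human state and belief); estimating the human's internal state from
measurable signals is explicitly out of scope.

## 6. Experiments, metrics, and what they show

The bundled experiments run noise-free by default: the stochastic terms
exist to shape the optimal gains (signal-dependent noise is why the gains
are iterated), while single simulated trials are deterministic
demonstrations; seeded stochastic mode is available
(`noise = TRUE`).

* **Center-out**: eight 12 cm reaches in 1 s (movement 200 ticks + 21 dwell,
  $N = 221$). Checked properties: terminal error < 1 cm, straightness
  (peak lateral deviation over distance) < 0.1, a single interior speed
  peak at 35–65 % of movement time, and co-contraction (mean of pairwise
  flexor/extensor minima) below 20 % of the mean agonist drive.
* **Curl fields**: the same reaches under $b = \pm 3$ N s/m. The
  field-induced deflection is quantified *against the null-field path of
  the same direction* (the standard way curl-field deflection is measured,
  and robust to the few millimetres of intrinsic path curvature the
  unperturbed model already shows): its signed area must flip sign between
  the two fields in every direction, the strongest lateral deviation must
  be visibly curved (> 1 cm), and all reaches must still terminate within
  2 cm.
* **Interaction scenarios**: A free reach (25 cm left, 1 s); B coupled with
  robot off; C coupled under the human-aware controller; D coupled under
  the impedance baseline. Checked orderings: effort(C) < effort(B); the
  speed peak in B is later than in A (the human carries the robot's
  inertia); effort(D) within ±25 % of effort(A) (the impedance baseline
  does not substantially assist). Scenario C runs at the full $N = 221$
  with $N_p = 50$.

`movement_metrics()` fixes the tie rules: the speed peak takes the first
maximum; the movement portion excludes the dwell; effort averages
$|e_k|^2$ over the simulation.

**What passing does not show.** The generator and plant are the same model
family — these experiments validate the architecture's internal
consistency and its reproduction of canonical movement phenomenology, not
agreement with any specific human dataset. Real arms differ in muscle
geometry and activation dynamics; reflexes, limb stiffness modulation, and
co-adaptation to the robot are outside the model.

## 7. Numerical choices and degenerate inputs

* Gain iteration: tolerance $10^{-9}$ on the maximum gain change, 500
  alternation cap, convergence error carrying the last residual.
* NNLS: in-package Lawson–Hanson with a data-scaled dual tolerance and an
  anti-cycling guard (degenerate near-optimal columns are temporarily
  blocked); exhaustively verified against an active-set enumeration oracle.
  Out-of-cone commands return the projection onto the cone with a reported
  residual.
* Infeasible static forces raise an error naming the maximum achievable
  magnitude along the requested direction (bisection over a box-constrained
  least-squares feasibility test).
* Zero target displacement, zero commands, singular Jacobians: each has a
  defined result or a named error; the velocity compensation falls back to
  the uncompensated command with a warning at singular postures.
* RK4 at 5 ms keeps passive energy drift below $10^{-6}$ J over 1 s for
  both chains, and the coupled drift is of the same order.
* Determinism: all randomness (synergy NMF, stochastic mode) flows from
  explicit seeds; reruns are bitwise identical, including written CSV/JSON
  files.

## 8. Problem sizes used by the test and acceptance runs

Full-length simulations ($N = 221$) are used for the center-out, curl, and
all four interaction scenarios, including the receding-horizon scenario C
(221 re-plans of a 50-step rollout; a few minutes on one core with the
compiled rollout engine and warm starts). Unit tests exercise the same code
paths at $N = 61$–$121$ where full length adds nothing to the property
under test.
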