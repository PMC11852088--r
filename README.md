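# reacharm

Simulation of planar human reaching as a hierarchical sensorimotor control
loop, and of a robot that uses that model to help its user.

`reacharm` is aimed at computational motor-control and physical human–robot
interaction (pHRI) researchers who need a *predictive* forward model of
reaching — one that produces hand paths, speed profiles, and muscle
excitations from nothing but a target and a movement time — fast enough to
be re-run thousands of times inside a robot controller.

## The model

Three levels close the loop at a 5 ms clock:

1. **High level — stochastic optimal feedback control on an internal
   model.** Decisions are made on an abstract 2-D point mass (m = 3 kg)
   driven by two push–pull abstract muscles with first-order activation
   dynamics (τ = 30 ms, F_max = 1000 N). The state
   X = [x, y, ẋ, ẏ, aₓ, a_y] is target-relative and evolves as

       X_{k+1} = A X_k + B u_k + Σᵢ εᵢ Cᵢ u_k + ξ,   Y_k = X_{k−d} + ω,

   with *signal-dependent* motor noise (sd = 0.2·|uᵢ|) and a 50 ms sensory
   delay. The cost Σ XᵀQ_k X + uᵀR u penalizes state only during the final
   21-step dwell, so the controller must arrive and rest at the target but
   the path is free. Because the noise is multiplicative, the feedback
   gains L*_k (u = L*X̂) and Kalman gains K_k are computed by *alternating
   coupled recursions* until convergence; with the noise scale at zero they
   reduce exactly to finite-horizon LQR/Kalman. The delayed measurements
   are handled by a ring-buffer predictor that keeps the belief
   6-dimensional.

2. **Mid level — muscle synergies.** Four non-negative co-activation
   patterns S (6 muscles × 4), learned offline by minimum-effort static
   load sharing over 16 force directions + non-negative matrix
   factorization. The desired hand force (u·F_max plus a Coriolis
   compensation term from the known arm dynamics) is decomposed onto the
   synergy force vectors B (2×4) by non-negative least squares, BC = u,
   and expanded to excitations e = clip(SC, 0, 1).

3. **Low level — a 2-link, 6-muscle Hill-type arm**, optionally rigidly
   coupled to a 2-link robot. Muscle force F = a·fl·fv·F_max with
   straight-line paths and analytic moment arms; activation dynamics with
   τ_act = 15 ms, τ_deact = 50 ms; RK4 integration; the hand/end-effector
   coupling is a position constraint whose Lagrange multiplier is the
   interaction force. A curl force field F = b·[[0,1],[−1,0]]·v can perturb
   the hand.

**Human-aware control.** The robot's NMPC rolls this entire closed-loop
model forward 50 steps per candidate torque profile (a quadratic polynomial
per joint, 6 coefficients) and minimizes the user's predicted neuromuscular
effort J = mean|e_k|², re-planning every 5 ms. The rollout runs in a
compiled C++ engine that mirrors the R reference stepper to machine
precision. An impedance controller (k_p = 50 N/m, k_d = 10 N s/m, tracking
the free reach advanced 50 ms) is included as the conventional baseline.

## Worked example

```r
library(reacharm)

arm <- arm_model_default()
syn <- learn_synergies(arm, seed = 1)
syn
#> Muscle synergy set: 4 synergies over 6 muscles (reconstruction R^2 = 0.936)

# scenario A: free reach, 25 cm to the left in 1 s
A <- simulate_scenario(scenario_config(target = c(-0.25, 0.40)),
                       arm = arm, synergies = syn)
A
#> Reach simulation: 221 steps (1.10 s), robot mode 'none'
#>   terminal error 1.19 mm, straightness 0.093, peak-speed fraction 0.49, effort 1.165e-03

# scenario B: same reach while dragging an unpowered robot
B <- simulate_scenario(scenario_config(target = c(-0.25, 0.40), robot_mode = "off"),
                       arm = arm, synergies = syn)

# scenario C: the robot predicts the user and minimizes their effort
C <- simulate_scenario(scenario_config(target = c(-0.25, 0.40), robot_mode = "nmpc"),
                       arm = arm, synergies = syn)
movement_metrics(B)$effort   #> 1.71e-03  (inertia costs effort)
movement_metrics(C)$effort   #> 6.33e-04  (the human-aware robot more than wins it back)

# center-out with a clockwise curl field
runs <- run_center_out(scenario_config(type = "center_out", field_b = 3),
                       arm = arm, synergies = syn)
movement_metrics(runs[["90"]])
#> terminal error 1.06 mm | straightness 0.091 | peak @ 0.51 | effort 2.806e-04 | co-contraction 7.06e-04 (agonist mean 6.07e-03)
```

The numbers read as: the free reach lands ~1 mm from the target with a
nearly straight path and its speed peak mid-movement; coupling to a dead
robot raises mean squared excitation from 1.17e-3 to 1.71e-3 and delays the
speed peak; the human-aware controller drops it to 6.3e-4 — less than the
unencumbered reach — while the curl field bends but does not defeat the
reaches.

A command-line interface wraps the same functions
(`system.file("cli", "reacharm", package = "reacharm")`): subcommands
`reach`, `interact --mode {off,nmpc,impedance}`, `center-out [--field-b B]`,
`learn-synergies`, and `metrics`, with `--config`, `--seed`, `--out`
globals. Runs are reproducible from their saved YAML config and seed alone.

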