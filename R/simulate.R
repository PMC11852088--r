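# Closed-loop orchestration of the sensorimotor hierarchy and the reaching
# experiments.
#
# One control tick (fixed order):
#   1. read hand kinematics from the musculoskeletal plant;
#   2. form the sensory vector (kinematic channels from the plant, abstract
#      activation channels self-read from the belief);
#   3. feedback command u from the scheduled optimal gain;
#   4. mid-level expansion: velocity compensation, NNLS decomposition onto
#      the synergy basis, excitations e;
#   5. robot controller (none / zero torque / NMPC / impedance) -> torques;
#   6. integrate the plant (arm, or coupled arm+robot, plus any force field)
#      one RK4 step with e and torques held constant;
#   7. Kalman update of the belief with the pre-integration measurement.

#' Scenario configuration
#'
#' @param type one of `"reach"` (single reach; interaction scenarios A-D are
#'   reaches with different `robot_mode`) or `"center_out"`
#' @param target world-frame target (m); for `"center_out"` the reach targets
#'   are placed on a circle of `radius` around the start instead
#' @param robot_mode `"none"` (uncoupled), `"off"` (coupled, zero torques),
#'   `"nmpc"` (human-aware controller), `"impedance"`
#' @param field_b curl-field gain (N s/m); 0 disables the field
#' @param N total steps; `D` dwell steps; `dt` step (s)
#' @param radius center-out circle radius (m)
#' @param n_targets number of center-out targets
#' @param noise logical: draw sensory/estimation noise (seeded)
#' @param seed integer seed used when `noise = TRUE`
#' @param start_offset hand start position relative to the shoulder (m)
#' @param internal extra arguments passed to [internal_model_params()]
#' @param nmpc extra arguments passed to [nmpc_config()]
#' @param impedance extra arguments passed to [impedance_params()]
#' @param reference reference trajectory for the impedance mode (a
#'   `reference_trajectory`, or `NULL`; see [simulate_scenario()])
#' @return a `scenario_config` object
#' @export
scenario_config <- function(type = c("reach", "center_out"),
                            target = c(-0.25, 0.40),
                            robot_mode = c("none", "off", "nmpc", "impedance"),
                            field_b = 0, N = 221, D = 21, dt = 0.005,
                            radius = 0.12, n_targets = 8,
                            noise = FALSE, seed = 1,
                            start_offset = c(0, 0.40),
                            internal = list(), nmpc = list(),
                            impedance = list(), reference = NULL) {
  type <- match.arg(type)
  robot_mode <- match.arg(robot_mode)
  stop_if(N <= D, "total steps must exceed the dwell")
  structure(list(type = type, target = as.numeric(target),
                 robot_mode = robot_mode, field_b = field_b,
                 N = as.integer(N), D = as.integer(D), dt = dt,
                 radius = radius, n_targets = as.integer(n_targets),
                 noise = isTRUE(noise), seed = as.integer(seed),
                 start_offset = as.numeric(start_offset),
                 internal = internal, nmpc = nmpc, impedance = impedance,
                 reference = reference),
            class = "scenario_config")
}

# Assemble the full simulation state for one reach.
sim_init <- function(config, arm = NULL, synergies = NULL, robot = NULL,
                     target = NULL) {
  arm <- arm %||% arm_model_default()
  target <- target %||% config$target
  ip_args <- utils::modifyList(
    list(dt = config$dt, N = config$N, D = config$D), config$internal)
  params <- do.call(internal_model_params, ip_args)
  start <- arm$skeleton$base + config$start_offset
  # the internal model works target-relative in world coordinates
  plant <- build_internal_model(params, target)
  cost <- build_cost_schedule(params)
  x0 <- c(start - target, 0, 0, 0, 0)
  sol <- solve_ofc(plant, cost, params, x0 = x0)
  q0 <- twolink_ik(arm$skeleton, start, elbow = "up")
  if (is.null(synergies)) synergies <- learn_synergies(arm, seed = 1)
  coupled <- config$robot_mode != "none"
  theta <- thetad <- NULL
  if (!coupled) robot <- NULL
  if (coupled) {
    robot <- robot %||% robot_params(base = arm$skeleton$base + c(0, 0.75))
    theta <- robot_inverse_kinematics(robot, start, elbow = "down")
    thetad <- c(0, 0)
  }
  field <- if (config$field_b != 0) curl_field(config$field_b) else NULL
  sim <- list(
    config = config, params = params, plant = plant, sol = sol,
    arm = arm, syn = synergies, robot = robot, field = field,
    target = as.numeric(target), start = start,
    k = 1L, nL = length(sol$L),
    state = arm_state(q0), theta = theta, thetad = thetad,
    belief = belief_state(x0, plant),
    u_last = c(0, 0), e_last = rep(0, 6),
    noise = config$noise
  )
  class(sim) <- "reach_sim"
  sim
}

# Current raw sensory vector: hand kinematics from the plant (target-
# relative), abstract activation channels self-read from the belief.
sim_measurement <- function(sim) {
  fk <- twolink_fk(sim$arm$skeleton, sim$state$q, sim$state$qd)
  y <- c(fk$pos - sim$target, fk$vel, sim$belief$xhat[5:6])
  if (sim$noise) {
    sd_om <- sqrt(diag(sim$params$omega))
    y[1:4] <- y[1:4] + stats::rnorm(4, 0, sd_om[1:4])
  }
  y
}

# Packed plant state for the integrator.
.pack <- function(sim) {
  if (is.null(sim$robot)) c(sim$state$q, sim$state$qd, sim$state$a)
  else c(sim$state$q, sim$state$qd, sim$state$a, sim$theta, sim$thetad)
}

.unpack <- function(sim, z) {
  sim$state$q <- z[1:2]; sim$state$qd <- z[3:4]
  sim$state$a <- clip01(z[5:10])
  if (!is.null(sim$robot)) { sim$theta <- z[11:12]; sim$thetad <- z[13:14] }
  sim
}

# Time derivative of the packed state with excitations and robot torques
# held constant over the step.
.sim_deriv <- function(sim, z, e, torques) {
  q <- z[1:2]; qd <- z[3:4]; a <- clip01(z[5:10])
  st <- list(q = q, qd = qd, a = a)
  geom <- muscle_geometry(q, sim$arm, qd)
  mf <- muscle_forces(st, sim$arm, geom)
  adot <- activation_rate(a, e, sim$arm$tau_act, sim$arm$tau_deact)
  if (is.null(sim$robot)) {
    f_ext <- if (is.null(sim$field)) c(0, 0) else {
      J <- twolink_jacobian(sim$arm$skeleton, q)
      curl_field_force(sim$field, as.numeric(J %*% qd))
    }
    qdd <- arm_dynamics(st, mf, sim$arm, hand_force = f_ext, geom = geom)
    c(qd, qdd, adot)
  } else {
    acc <- coupled_accelerations(sim$arm, st, mf, sim$robot,
                                 z[11:12], z[13:14], torques = torques,
                                 field = sim$field, geom = geom)
    c(qd, acc$qdd, adot, z[13:14], acc$thetadd)
  }
}

# One full control tick; `torques` are this tick's robot motor torques
# (ignored when uncoupled). Returns the updated sim with per-tick
# diagnostics in $last. `light = TRUE` (used inside NMPC rollouts) skips the
# logging-only interaction-force solve.
sim_tick <- function(sim, torques = c(0, 0), light = FALSE) {
  kL <- min(sim$k, sim$nL)
  y <- sim_measurement(sim)
  u <- as.numeric(sim$sol$L[[kL]] %*% sim$belief$xhat)
  geom0 <- muscle_geometry(sim$state$q, sim$arm, sim$state$qd)
  J0 <- twolink_jacobian(sim$arm$skeleton, sim$state$q)
  # velocity-compensated desired hand force
  cv <- arm_velocity_torques(sim$arm, sim$state$q, sim$state$qd)
  f_task <- u * sim$params$fmax + as.numeric(solve(t(J0), cv))
  # synergy basis at the current posture through the isometric statics map
  Phi <- arm_statics_map(sim$state$q, sim$arm, return_matrix = TRUE, geom = geom0)
  basis <- Phi %*% sim$syn$S
  co <- decompose_command(f_task, basis)
  e <- expand_to_excitations(sim$syn, co)
  interaction <- c(0, 0); gap <- 0
  if (!light && !is.null(sim$robot)) {
    mf <- muscle_forces(sim$state, sim$arm, geom0)
    acc <- coupled_accelerations(sim$arm, sim$state, mf, sim$robot,
                                 sim$theta, sim$thetad, torques = torques,
                                 field = sim$field, geom = geom0)
    interaction <- acc$interaction
    gap <- acc$gap
  }
  z <- rk4_step(.pack(sim), function(zz) .sim_deriv(sim, zz, e, torques), sim$params$dt)
  sim <- .unpack(sim, z)
  eta <- if (sim$noise) stats::rnorm(2, 0, sqrt(diag(sim$params$eta))) else NULL
  sim$belief <- estimate_state(sim$belief, u, y, sim$sol, kL, eta = eta)
  sim$u_last <- u; sim$e_last <- e
  if (light) {
    sim$last <- list(u = u, e = e, torques = torques)
  } else {
    sim$last <- list(u = u, e = e, torques = torques, interaction = interaction,
                     gap = gap, coef = as.numeric(co))
  }
  sim$k <- sim$k + 1L
  sim
}

#' Advance the closed-loop simulation by one control tick
#'
#' Exposed wrapper around the internal stepper; useful for custom loops and
#' for inspecting the fixed intra-tick ordering documented above.
#'
#' @param sim a simulation state from `sim_init` (see [simulate_scenario()])
#' @param torques robot motor torques for this tick (N m)
#' @return the updated simulation state
#' @export
step_closed_loop <- function(sim, torques = c(0, 0)) {
  stopifnot(inherits(sim, "reach_sim"))
  sim_tick(sim, torques)
}

#' Simulate a full reaching scenario
#'
#' Runs an N-step closed-loop rollout of the hierarchy. The four interaction
#' scenarios are selected by `config$robot_mode`: `"none"` (scenario A,
#' uncoupled), `"off"` (B: coupled, zero torques), `"nmpc"` (C: human-aware
#' controller), `"impedance"` (D: impedance tracking of a time-advanced
#' reference from a scenario-A run, which must be supplied via
#' `config$reference` or the `reference` argument).
#'
#' @param config `scenario_config`
#' @param arm optional `arm_model` (default fixture)
#' @param synergies optional `synergy_set` (learned once if missing)
#' @param robot optional `robot_params`
#' @param reference optional `reference_trajectory` for the impedance mode
#' @return a `simulation_result`
#' @export
simulate_scenario <- function(config, arm = NULL, synergies = NULL,
                              robot = NULL, reference = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  reference <- reference %||% config$reference
  if (config$robot_mode == "impedance" && is.null(reference)) {
    stop(paste("the impedance mode tracks a stored free-reach trajectory;",
               "run the scenario with robot_mode = 'none' first and pass its",
               "result via reference_from_result()"), call. = FALSE)
  }
  if (config$noise) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(config$seed)
  }
  sim <- sim_init(config, arm = arm, synergies = synergies, robot = robot)
  imp <- NULL
  nmpc_cfg <- NULL
  profile <- NULL
  if (config$robot_mode == "impedance") {
    imp <- do.call(impedance_params, config$impedance)
    reference <- shift_reference(reference, imp$time_shift)
  }
  if (config$robot_mode == "nmpc") {
    nmpc_cfg <- do.call(nmpc_config, config$nmpc)
  }
  N <- config$N
  res <- list(
    time = (seq_len(N) - 1) * config$dt,
    hand_pos = matrix(NA_real_, N, 2), hand_vel = matrix(NA_real_, N, 2),
    q = matrix(NA_real_, N, 2), qd = matrix(NA_real_, N, 2),
    theta = matrix(NA_real_, N, 2), thetad = matrix(NA_real_, N, 2),
    a = matrix(NA_real_, N, 6), e = matrix(0, N, 6),
    u = matrix(0, N, 2), xhat = matrix(NA_real_, N, 6),
    torques = matrix(0, N, 2), interaction = matrix(0, N, 2),
    gap = numeric(N), effort = numeric(N)
  )
  log_state <- function(res, sim, k) {
    fk <- twolink_fk(sim$arm$skeleton, sim$state$q, sim$state$qd)
    res$hand_pos[k, ] <- fk$pos; res$hand_vel[k, ] <- fk$vel
    res$q[k, ] <- sim$state$q; res$qd[k, ] <- sim$state$qd
    res$a[k, ] <- sim$state$a; res$xhat[k, ] <- sim$belief$xhat
    if (!is.null(sim$robot)) { res$theta[k, ] <- sim$theta; res$thetad[k, ] <- sim$thetad }
    res
  }
  res <- log_state(res, sim, 1)
  for (k in seq_len(N - 1)) {
    torques <- c(0, 0)
    if (config$robot_mode == "nmpc") {
      profile <- nmpc_step(sim, nmpc_cfg, warm_start = profile)
      torques <- evaluate_torque_profile(profile, 0)
    } else if (config$robot_mode == "impedance") {
      rk <- robot_kinematics(sim$robot, sim$theta, sim$thetad)
      refk <- reference_sample(reference, k)
      torques <- impedance_torques(rk, refk, imp)
    }
    sim <- sim_tick(sim, torques)
    res$e[k, ] <- sim$last$e; res$u[k, ] <- sim$last$u
    res$torques[k, ] <- sim$last$torques
    res$interaction[k, ] <- sim$last$interaction
    res$gap[k] <- sim$last$gap
    res$effort[k] <- sum(sim$last$e^2)
    res <- log_state(res, sim, k + 1)
    if (!is.null(profile)) profile <- shift_profile(profile)
  }
  res$config <- config
  res$target <- sim$target
  res$start <- sim$start
  structure(res, class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  mm <- movement_metrics(x)
  cat(sprintf("Reach simulation: %d steps (%.2f s), robot mode '%s'\n",
              length(x$time), max(x$time), x$config$robot_mode))
  cat(sprintf("  terminal error %.2f mm, straightness %.3f, peak-speed fraction %.2f, effort %.3e\n",
              1000 * mm$terminal_error, mm$straightness, mm$peak_fraction, mm$effort))
  invisible(x)
}

#' Run the center-out reaching experiment
#'
#' Eight (by default) reaches from the central start position to targets
#' equally spaced on a circle, optionally inside a velocity-dependent curl
#' force field.
#'
#' @param config `scenario_config` with `type = "center_out"`
#' @param arm optional `arm_model`
#' @param synergies optional `synergy_set` (learned once and shared)
#' @return list of `simulation_result`, one per target, with the target
#'   angles as names
#' @export
run_center_out <- function(config = scenario_config(type = "center_out"),
                           arm = NULL, synergies = NULL) {
  arm <- arm %||% arm_model_default()
  synergies <- synergies %||% learn_synergies(arm, seed = 1)
  start <- arm$skeleton$base + config$start_offset
  angles <- 2 * pi * (seq_len(config$n_targets) - 1) / config$n_targets
  out <- lapply(angles, function(th) {
    tgt <- start + config$radius * c(cos(th), sin(th))
    cfg <- config
    cfg$type <- "reach"
    cfg$target <- tgt
    simulate_scenario(cfg, arm = arm, synergies = synergies)
  })
  names(out) <- sprintf("%.0f", angles * 180 / pi)
  out
}

#' Movement metrics of a simulated reach
#'
#' Quantifies the canonical descriptors of point-to-point reaching:
#' terminal accuracy, path straightness (peak lateral deviation over
#' straight-line distance), timing of the speed peak within the movement
#' portion (first maximum on ties), mean squared excitation (the
#' neuromuscular effort index), agonist-antagonist co-contraction (mean of
#' the pairwise minima across the three flexor/extensor pairs, with the mean
#' pairwise maximum reported for reference), and the signed area between the
#' hand path and the straight line (positive = counterclockwise deviation).
#'
#' @param result `simulation_result`
#' @param movement_steps number of steps counted as the movement proper
#'   (defaults to N - D; the dwell is excluded from peak timing)
#' @return a `movement_metrics` list
#' @export
movement_metrics <- function(result, movement_steps = NULL) {
  N <- length(result$time)
  stop_if(N < 2, "empty simulation result")
  D <- result$config$D %||% 0
  movement_steps <- movement_steps %||% (N - D)
  target <- result$target
  start <- result$start %||% result$hand_pos[1, ]
  term <- result$hand_pos[N, ]
  terminal_error <- sqrt(sum((term - target)^2))

  axis <- target - start
  Lax <- sqrt(sum(axis^2))
  rel <- sweep(result$hand_pos, 2, start)
  if (Lax > 1e-12) {
    ax <- axis / Lax
    along <- rel %*% ax
    lateral <- rel %*% c(-ax[2], ax[1])
    straightness <- max(abs(lateral)) / Lax
    lateral_area <- sum(0.5 * (lateral[-1] + lateral[-N]) * diff(along))
  } else {
    straightness <- 0
    lateral_area <- 0
  }

  speed <- sqrt(rowSums(result$hand_vel^2))
  mv <- seq_len(min(movement_steps, N))
  peak_fraction <- which.max(speed[mv]) / length(mv)

  eff_steps <- seq_len(N - 1)
  effort <- mean(rowSums(result$e[eff_steps, , drop = FALSE]^2))
  pairs <- list(c(1, 2), c(3, 4), c(5, 6))
  co <- mean(vapply(pairs, function(p) {
    mean(pmin(result$e[eff_steps, p[1]], result$e[eff_steps, p[2]]))
  }, 0))
  ag <- mean(vapply(pairs, function(p) {
    mean(pmax(result$e[eff_steps, p[1]], result$e[eff_steps, p[2]]))
  }, 0))
  structure(list(terminal_error = terminal_error, straightness = straightness,
                 peak_fraction = peak_fraction, effort = effort,
                 cocontraction = co, agonist_mean = ag,
                 lateral_area = lateral_area),
            class = "movement_metrics")
}

#' @export
print.movement_metrics <- function(x, ...) {
  cat(sprintf(paste0("terminal error %.2f mm | straightness %.3f | peak @ %.2f ",
                     "| effort %.3e | co-contraction %.2e (agonist mean %.2e)\n"),
              1000 * x$terminal_error, x$straightness, x$peak_fraction,
              x$effort, x$cocontraction, x$agonist_mean))
  invisible(x)
}
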