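# Robot-side controllers.
#
# The human-aware controller is a receding-horizon (NMPC) scheme: at every
# control tick it rolls out the full closed-loop human model (high-level
# gains, synergy expansion, Hill muscles, coupled robot) for Np steps under
# candidate torque profiles and minimizes the user's predicted neuromuscular
# effort, the mean squared excitation over the horizon. Torques are
# parameterized per joint by a 2nd-order polynomial in the step index, so
# the decision vector has 6 coefficients. The baseline is an end-effector
# impedance controller tracking a time-advanced reference trajectory.

#' NMPC configuration
#'
#' @param Np prediction horizon (steps)
#' @param beta_bound bound on the constant torque coefficients (N m); the
#'   linear and quadratic coefficients are bounded by `beta_bound / Np` and
#'   `beta_bound / Np^2` so the torque stays within about twice the bound
#'   over the horizon
#' @param maxit optimizer iterations per control tick
#' @param tol convergence tolerance on the effort objective
#' @param warm_start reuse the previous tick's solution (shifted) as the
#'   starting point
#' @return an `nmpc_config` object
#' @export
nmpc_config <- function(Np = 50, beta_bound = 20, maxit = 8, tol = 1e-6,
                        warm_start = TRUE) {
  stop_if(Np < 1, "prediction horizon must be at least one step")
  structure(list(Np = as.integer(Np), beta_bound = beta_bound,
                 maxit = maxit, tol = tol, warm_start = isTRUE(warm_start)),
            class = "nmpc_config")
}

#' Polynomial torque profile
#'
#' Torques over the prediction horizon are
#' \eqn{T_j(k) = \beta_{0j} + \beta_{1j} k + \beta_{2j} k^2} for joints
#' j = 1, 2 and step index k counted from 0.
#'
#' @param beta 2x3 coefficient matrix (rows = joints, columns = polynomial
#'   order 0..2), or a length-6 vector (joint-major)
#' @return a `torque_profile` object
#' @export
torque_profile <- function(beta = matrix(0, 2, 3)) {
  if (is.null(dim(beta))) beta <- matrix(beta, 2, 3)
  stop_if(any(!is.finite(beta)) || any(dim(beta) != c(2, 3)), "beta must be a finite 2x3 matrix")
  structure(list(beta = beta), class = "torque_profile")
}

#' Evaluate a torque profile at a horizon step
#'
#' @param profile `torque_profile`
#' @param k step within the horizon (0-based)
#' @return 2-vector of joint torques (N m)
#' @export
evaluate_torque_profile <- function(profile, k) {
  as.numeric(profile$beta %*% c(1, k, k^2))
}

# Shift a profile one step forward in time (for warm starts):
# T'(k) = T(k+1).
shift_profile <- function(profile) {
  b <- profile$beta
  torque_profile(cbind(b[, 1] + b[, 2] + b[, 3], b[, 2] + 2 * b[, 3], b[, 3]))
}

#' Predicted neuromuscular effort of a torque profile
#'
#' Deterministically simulates the full coupled human-robot model forward
#' `Np` steps from a snapshot of the simulation state, applying the
#' profile's torques, with the human controller using its precomputed gain
#' schedule at the corresponding global step indices (clamped at the end of
#' the horizon). Returns the mean squared excitation
#' \eqn{J = \frac{1}{N_p}\sum_k |e_k|^2}. The snapshot is not mutated.
#'
#' @param sim a `reach_sim` snapshot (coupled)
#' @param profile `torque_profile`
#' @param config `nmpc_config`
#' @param engine `"compiled"` (default) evaluates the rollout in the
#'   package's C++ engine; `"reference"` uses the plain-R stepper. The two
#'   agree to near machine precision (asserted in the test suite).
#' @return effort J (dimensionless, >= 0)
#' @export
rollout_objective <- function(sim, profile, config,
                              engine = c("compiled", "reference")) {
  stop_if(is.null(sim$robot), "effort rollout requires a coupled simulation state")
  engine <- match.arg(engine)
  if (engine == "compiled") {
    return(.cpp_rollout_effort(nmpc_snapshot(sim), profile$beta, config$Np))
  }
  sim$noise <- FALSE
  J <- 0
  for (k in seq_len(config$Np) - 1L) {
    sim <- sim_tick(sim, evaluate_torque_profile(profile, k), light = TRUE)
    J <- J + sum(sim$last$e^2)
  }
  J / config$Np
}

# Flat snapshot of a reach_sim for the compiled rollout engine.
nmpc_snapshot <- function(sim) {
  nL <- sim$nL
  list(arm = sim$arm,
       robot = if (is.null(sim$robot)) NULL else unclass(sim$robot),
       field_b = if (is.null(sim$field)) 0 else sim$field$b,
       S = sim$syn$S,
       A = sim$plant$A, B = sim$plant$B,
       target = sim$target,
       n_delay = sim$plant$n_delay, nL = nL,
       L = array(unlist(sim$sol$L), c(2, 6, nL)),
       K = array(unlist(sim$sol$K), c(6, 6, nL)),
       fmax_abstract = sim$params$fmax, dt = sim$params$dt,
       baumgarte = 20,
       q = sim$state$q, qd = sim$state$qd, a = sim$state$a,
       theta = sim$theta, thetad = sim$thetad,
       xhat = sim$belief$xhat, xhat_del = sim$belief$xhat_del,
       buf_y = sim$belief$buf_y, buf_u = sim$belief$buf_u,
       k = sim$k)
}

#' One receding-horizon step of the human-aware controller
#'
#' Minimizes [rollout_objective()] over the 6 polynomial torque
#' coefficients with box-constrained quasi-Newton search (finite-difference
#' gradients), multi-started from the shifted warm start and from the zero
#' profile. The returned profile is never worse than the better of the two
#' starting points; in particular it is never worse than zero torque when no
#' warm start is given.
#'
#' @param sim `reach_sim` snapshot (coupled)
#' @param config `nmpc_config`
#' @param warm_start previous tick's `torque_profile`, already shifted, or
#'   `NULL`
#' @return the optimized `torque_profile`, with the achieved objective in
#'   attribute `objective`
#' @export
nmpc_step <- function(sim, config, warm_start = NULL) {
  bb <- config$beta_bound
  lower <- rep(c(-bb, -bb / config$Np, -bb / config$Np^2), each = 2)
  upper <- -lower
  obj <- function(b) rollout_objective(sim, torque_profile(matrix(b, 2, 3)), config)
  starts <- list(rep(0, 6))
  if (!is.null(warm_start) && config$warm_start) {
    starts <- c(list(pmin(pmax(as.numeric(warm_start$beta), lower), upper)), starts)
  }
  best_b <- starts[[1]]
  best_J <- obj(best_b)
  for (s in starts[-1]) {
    Js <- obj(s)
    if (Js < best_J) { best_J <- Js; best_b <- s }
  }
  if (best_J > config$tol) {
    fit <- tryCatch(
      stats::optim(best_b, obj, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = config$maxit, factr = 1e7)),
      error = function(e) {
        warning("NMPC optimizer failed: ", conditionMessage(e),
                "; keeping best evaluated profile", call. = FALSE)
        NULL
      })
    if (!is.null(fit) && is.finite(fit$value) && fit$value < best_J) {
      best_J <- fit$value
      best_b <- fit$par
    }
  }
  out <- torque_profile(matrix(best_b, 2, 3))
  attr(out, "objective") <- best_J
  out
}

#' Impedance controller parameters
#'
#' @param kp end-effector stiffness (N/m)
#' @param kd end-effector damping (N s/m)
#' @param time_shift how far the reference is advanced in time (s) to pull
#'   the hand toward the target
#' @return an `impedance_params` object
#' @export
impedance_params <- function(kp = 50, kd = 10, time_shift = 0.050) {
  stop_if(kp < 0 || kd < 0, "impedance gains must be non-negative")
  structure(list(kp = kp, kd = kd, time_shift = time_shift),
            class = "impedance_params")
}

#' Impedance controller torques
#'
#' Renders a spring-damper at the end-effector about the reference sample:
#' \eqn{F = k_p (x_{ref} - x) + k_d (\dot x_{ref} - \dot x)},
#' mapped to joint torques through the robot Jacobian transpose.
#'
#' @param robot_kin output of [robot_kinematics()] (`pos`, `vel`, `jacobian`)
#' @param ref_sample list with `pos` and `vel` of the reference at this tick
#' @param params `impedance_params`
#' @return 2-vector of joint torques (N m)
#' @export
impedance_torques <- function(robot_kin, ref_sample, params) {
  f <- params$kp * (ref_sample$pos - robot_kin$pos) +
    params$kd * (ref_sample$vel - robot_kin$vel)
  as.numeric(t(robot_kin$jacobian) %*% f)
}

#' Reference trajectory from a simulation result
#'
#' @param result `simulation_result` (typically the uncoupled free reach)
#' @return a `reference_trajectory` with uniformly sampled hand positions
#'   and velocities
#' @export
reference_from_result <- function(result) {
  structure(list(pos = result$hand_pos, vel = result$hand_vel,
                 dt = diff(result$time[1:2])),
            class = "reference_trajectory")
}

#' Advance a reference trajectory in time
#'
#' Drops the first `shift / dt` samples; queries beyond the end hold the
#' last sample (the target, at rest).
#'
#' @param traj `reference_trajectory`
#' @param shift time advance (s), a multiple of the sampling step
#' @return shifted `reference_trajectory`
#' @export
shift_reference <- function(traj, shift) {
  n <- round(shift / traj$dt)
  stop_if(abs(shift / traj$dt - n) > 1e-9, "shift must be a multiple of the sampling step")
  if (n == 0) return(traj)
  N <- nrow(traj$pos)
  idx <- pmin(seq_len(N) + n, N)
  traj$pos <- traj$pos[idx, , drop = FALSE]
  traj$vel <- traj$vel[idx, , drop = FALSE]
  traj$vel[seq.int(max(1, N - n + 1), N), ] <- 0   # held samples are at rest
  traj
}

# Sample a reference at tick k (1-based), holding the last value.
reference_sample <- function(traj, k) {
  k <- min(k, nrow(traj$pos))
  list(pos = traj$pos[k, ], vel = traj$vel[k, ])
}
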