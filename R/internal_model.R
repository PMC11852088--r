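# High-level decision-making: stochastic optimal feedback control on a
# low-dimensional internal model.
#
# The internal model is a 2-D point mass driven by two "abstract muscles"
# (first-order activation dynamics, push-pull). Its state is
# X = [x, y, xd, yd, ax, ay], expressed target-relative so that the terminal
# state penalty drives the model to rest at the target. Motor noise is
# signal-dependent (standard deviation proportional to |u|), which couples
# the optimal feedback gains to the Kalman gains; the two gain schedules are
# therefore computed by alternating coupled Riccati-type recursions until
# they stop changing (the classical LQG separation principle no longer
# applies under multiplicative noise).

#' Internal model parameters
#'
#' Parameters of the abstract 2-D point-mass internal model and its noise
#' structure. Defaults reproduce the simulation parameter set: point mass
#' 3 kg, activation time constant 30 ms, abstract maximum force 1000 N,
#' 5 ms steps, horizon 221 steps with a 21-step dwell, 50 ms sensory delay,
#' additive process noise diag(2e-7), sensory noise diag(1e-6), internal
#' estimation noise diag(1e-9) injected through the two command channels,
#' and multiplicative command noise of scale 0.2.
#'
#' @param m point mass (kg)
#' @param tau abstract muscle activation time constant (s)
#' @param fmax abstract maximum muscle force (N)
#' @param dt discretization step (s)
#' @param N horizon length (steps)
#' @param D dwell steps with non-zero state penalty at the end of the horizon
#' @param delay sensory delay (s); must be an integer multiple of `dt`
#' @param xi additive process noise covariance (6x6 or scalar diagonal value)
#' @param omega sensory noise covariance (6x6 or scalar diagonal value)
#' @param eta estimation noise covariance on the 2 command channels
#'   (2x2 or scalar diagonal value)
#' @param mult_scale multiplicative (signal-dependent) noise scale matrix
#'   (2x2 or scalar diagonal value)
#' @param Q_dwell state penalty during the dwell (6x6 or scalar diagonal value)
#' @param R control penalty (2x2 or scalar diagonal value)
#' @return an object of class `internal_model_params`
#' @export
internal_model_params <- function(m = 3, tau = 0.030, fmax = 1000,
                                  dt = 0.005, N = 221, D = 21, delay = 0.050,
                                  xi = 2e-7, omega = 1e-6, eta = 1e-9,
                                  mult_scale = 0.2, Q_dwell = 1, R = 1) {
  stop_if(!is.finite(m) || m <= 0, "point mass must be positive")
  stop_if(!is.finite(tau) || tau <= 0, "activation time constant must be positive")
  stop_if(!is.finite(dt) || dt <= 0, "time step must be positive")
  stop_if(!is.finite(fmax) || fmax <= 0, "abstract maximum force must be positive")
  stop_if(!(N > D) || D < 1, "horizon must satisfy N > D >= 1")
  stop_if(delay < 0, "sensory delay must be non-negative")
  nd <- delay / dt
  stop_if(abs(nd - round(nd)) > 1e-9, "delay must be an integer multiple of dt")
  as_cov <- function(x, n, what) {
    if (length(x) == 1) x <- diag(as.numeric(x), n)
    stop_if(!is.matrix(x) || any(dim(x) != n), sprintf("%s must be %dx%d", what, n, n))
    stop_if(!is_psd(x), sprintf("%s must be symmetric positive semi-definite", what))
    x
  }
  p <- list(m = m, tau = tau, fmax = fmax, dt = dt, N = as.integer(N),
            D = as.integer(D), delay = delay, n_delay = as.integer(round(nd)),
            xi = as_cov(xi, 6, "process noise covariance"),
            omega = as_cov(omega, 6, "sensory noise covariance"),
            eta = as_cov(eta, 2, "estimation noise covariance"),
            mult_scale = as_cov(mult_scale, 2, "multiplicative noise scale"),
            Q_dwell = as_cov(Q_dwell, 6, "dwell state penalty"),
            R = as_cov(R, 2, "control penalty"))
  ev <- eigen((p$R + t(p$R)) / 2, symmetric = TRUE, only.values = TRUE)$values
  stop_if(min(ev) <= 0, "control penalty R must be positive definite")
  structure(p, class = "internal_model_params")
}

#' Build the discrete internal plant model
#'
#' Forward-Euler discretization of the point-mass / abstract-muscle dynamics
#' \eqn{m\ddot x = a F_{max}}, \eqn{\tau \dot a = u - a} at step `dt`, with
#' full-state observation (H = identity) and signal-dependent noise entering
#' through the input matrix. The state is target-relative: position
#' components are current minus target, so the dwell penalty drives the state
#' to the origin (at target, at rest, muscles off).
#'
#' @param params `internal_model_params`
#' @param target task-space target point (m, length 2)
#' @return an object of class `internal_plant` with discrete matrices `A`
#'   (6x6), `B` (6x2), `H` (identity), multiplicative-noise channel matrices
#'   `Cmult`, delay steps `n_delay`, and the target
#' @export
build_internal_model <- function(params, target) {
  stopifnot(inherits(params, "internal_model_params"))
  stop_if(length(target) != 2 || any(!is.finite(target)), "target must be a finite 2-vector")
  dt <- params$dt
  A <- diag(6)
  A[1, 3] <- dt; A[2, 4] <- dt
  A[3, 5] <- dt * params$fmax / params$m
  A[4, 6] <- dt * params$fmax / params$m
  A[5, 5] <- 1 - dt / params$tau
  A[6, 6] <- 1 - dt / params$tau
  B <- matrix(0, 6, 2)
  B[5, 1] <- dt / params$tau
  B[6, 2] <- dt / params$tau
  # one noise channel per command: C_i u = scale_i * u_i * B e_i
  Cmult <- lapply(1:2, function(i) {
    Ci <- matrix(0, 6, 2)
    Ci[, i] <- params$mult_scale[i, i] * B[, i]
    Ci
  })
  structure(list(A = A, B = B, H = diag(6), Cmult = Cmult,
                 n_delay = params$n_delay, target = as.numeric(target),
                 state_names = c("x", "y", "xd", "yd", "ax", "ay")),
            class = "internal_plant")
}

#' Build the time-varying quadratic cost schedule
#'
#' The state penalty is zero during the movement and switches to `Q_dwell`
#' (identity by default) for exactly the last `D` steps of the horizon; the
#' control penalty `R` is constant. The controller is thereby asked to arrive
#' and stay at rest at the target during the dwell, with the trajectory
#' itself left free.
#'
#' @param params `internal_model_params`
#' @return an object of class `cost_schedule` with fields `Q` (list of N
#'   6x6 matrices), `R` (2x2), `N`, `D`
#' @export
build_cost_schedule <- function(params) {
  stopifnot(inherits(params, "internal_model_params"))
  stop_if(params$D >= params$N, "dwell must be shorter than the horizon")
  Z <- matrix(0, 6, 6)
  Q <- c(rep(list(Z), params$N - params$D), rep(list(params$Q_dwell), params$D))
  structure(list(Q = Q, R = params$R, N = params$N, D = params$D),
            class = "cost_schedule")
}

#' Solve for the optimal feedback and Kalman gain schedules
#'
#' Computes the time-varying feedback gains \eqn{L^*_k} (so that
#' \eqn{u_k = L^*_k \hat X_k}) and Kalman gains \eqn{K_k} for the internal
#' plant under signal-dependent noise. Because command noise couples control
#' to estimation, the controller recursion (run backward given the current
#' filter) and the filter recursion (run forward given the current
#' controller) are alternated until the gains change by less than `tol`.
#' With the multiplicative scale set to zero the feedback gains reduce
#' exactly to the classical finite-horizon LQR solution and the Kalman
#' recursion to the standard filter Riccati recursion.
#'
#' @param model `internal_plant`
#' @param cost `cost_schedule`
#' @param params `internal_model_params`
#' @param x0 initial target-relative state (used by the filter recursion,
#'   whose command-noise term depends on the estimate magnitude); defaults to
#'   rest at the current position offset implied by the plant target
#' @param tol convergence tolerance on the maximum absolute gain change
#' @param max_iter maximum number of alternations
#' @return an object of class `ofc_solution`: lists `L` and `K` (per step),
#'   `iterations`, `residual`
#' @export
solve_ofc <- function(model, cost, params, x0 = NULL, tol = 1e-9, max_iter = 500) {
  stopifnot(inherits(model, "internal_plant"), inherits(cost, "cost_schedule"))
  N <- cost$N
  A <- model$A; B <- model$B; H <- model$H
  Cm <- model$Cmult
  R <- cost$R
  Oxi <- params$xi
  Oom <- params$omega
  Oeta <- B %*% params$eta %*% t(B)   # estimation noise injected via commands
  if (is.null(x0)) x0 <- c(-model$target, 0, 0, 0, 0)
  nL <- N - 1

  Ls <- rep(list(matrix(0, 2, 6)), nL)
  Ks <- rep(list(matrix(0, 6, 6)), nL)

  backward_pass <- function(Ks) {
    Sx <- cost$Q[[N]]
    Se <- matrix(0, 6, 6)
    Ls <- vector("list", nL)
    for (k in nL:1) {
      G <- R + t(B) %*% Sx %*% B
      for (Ci in Cm) G <- G + t(Ci) %*% (Sx + Se) %*% Ci
      L <- solve(G, t(B) %*% Sx %*% A)
      AK <- A - Ks[[k]] %*% H
      Se_new <- t(A) %*% Sx %*% B %*% L + t(AK) %*% Se %*% AK
      Sx_new <- cost$Q[[k]] + t(A) %*% Sx %*% (A - B %*% L)
      Sx <- (Sx_new + t(Sx_new)) / 2
      Se <- Se_new
      Ls[[k]] <- L
    }
    Ls
  }

  forward_pass <- function(Ls) {
    Se <- Oxi                      # initial estimation-error covariance
    Sh <- tcrossprod(x0)           # E[xhat xhat'] with a known start
    Sxe <- matrix(0, 6, 6)
    Ks <- vector("list", nL)
    for (k in 1:nL) {
      K <- A %*% Se %*% t(H) %*% solve(H %*% Se %*% t(H) + Oom)
      Ks[[k]] <- K
      L <- Ls[[k]]
      ABL <- A - B %*% L
      AKH <- A - K %*% H
      mult <- matrix(0, 6, 6)
      for (Ci in Cm) {
        CL <- Ci %*% L
        mult <- mult + CL %*% Sh %*% t(CL)
      }
      Se_new <- Oxi + Oeta + AKH %*% Se %*% t(A) + mult
      Sh_new <- Oeta + K %*% H %*% Se %*% t(A) + ABL %*% Sh %*% t(ABL) +
        ABL %*% Sxe %*% t(H) %*% t(K) + K %*% H %*% t(Sxe) %*% t(ABL)
      Sxe_new <- ABL %*% Sxe %*% t(AKH) - Oeta
      Se <- (Se_new + t(Se_new)) / 2
      Sh <- (Sh_new + t(Sh_new)) / 2
      Sxe <- Sxe_new
    }
    Ks
  }

  residual <- Inf
  iter <- 0
  repeat {
    iter <- iter + 1
    Ls_new <- backward_pass(Ks)
    Ks_new <- forward_pass(Ls_new)
    dL <- max(vapply(seq_len(nL), function(k) max(abs(Ls_new[[k]] - Ls[[k]])), 0))
    dK <- max(vapply(seq_len(nL), function(k) max(abs(Ks_new[[k]] - Ks[[k]])), 0))
    residual <- max(dL, dK)
    Ls <- Ls_new; Ks <- Ks_new
    if (residual < tol) break
    if (iter >= max_iter) {
      stop(sprintf("gain iteration did not converge: residual %.3e after %d iterations",
                   residual, iter), call. = FALSE)
    }
  }
  for (k in seq_len(nL)) check_finite(Ls[[k]], "feedback gain")
  # store gains in the u = L* xhat convention (minus the recursion's L)
  structure(list(L = lapply(Ls, function(L) -L), K = Ks,
                 iterations = iter, residual = residual,
                 N = N, model = model),
            class = "ofc_solution")
}

#' @export
print.ofc_solution <- function(x, ...) {
  cat(sprintf("Optimal feedback/Kalman gain schedule: %d steps, %d iterations, residual %.2e\n",
              x$N, x$iterations, x$residual))
  invisible(x)
}

#' Initial belief state
#'
#' The belief holds the current state estimate `xhat`, a bookkeeping
#' covariance, and two ring buffers of length `n_delay`: the most recent raw
#' measurements (sensory information in flight, not yet perceivable) and the
#' most recent commands. Internally the Kalman filter runs on the delayed
#' time base (`xhat_del`, the estimate of the state `n_delay` steps ago,
#' which is what the newest perceivable measurement refers to); the current
#' estimate is its forward prediction through the internal model using the
#' buffered commands. This realizes the sensory delay while keeping the
#' estimate itself 6-dimensional.
#'
#' @param xhat initial state estimate (6-vector, target-relative)
#' @param model `internal_plant`
#' @param P initial error covariance (6x6)
#' @return an object of class `belief_state`
#' @export
belief_state <- function(xhat, model, P = diag(1e-6, 6)) {
  stop_if(length(xhat) != 6 || any(!is.finite(xhat)), "estimate must be a finite 6-vector")
  stop_if(!is_psd(P), "belief covariance must be symmetric PSD")
  nd <- model$n_delay
  y0 <- as.numeric(model$H %*% xhat)
  structure(list(xhat = as.numeric(xhat), xhat_del = as.numeric(xhat), P = P,
                 buf_y = if (nd > 0) matrix(rep(y0, nd), nrow = nd, byrow = TRUE) else matrix(0, 0, 6),
                 buf_u = matrix(0, nd, 2),
                 n_delay = nd),
            class = "belief_state")
}

#' Feedback control command
#'
#' \eqn{u_k = L^*_k \hat X_k}: a pure matrix product of the scheduled gain
#' with the current estimate; no saturation at this level (abstract muscles
#' push and pull).
#'
#' @param solution `ofc_solution`
#' @param belief `belief_state`
#' @param k step index (1-based; indices past the schedule end are an error)
#' @return abstract command u (2-vector)
#' @export
control_command <- function(solution, belief, k) {
  stop_if(k < 1 || k > length(solution$L), sprintf("step %d outside gain schedule", k))
  as.numeric(solution$L[[k]] %*% belief$xhat)
}

#' Kalman update of the belief state
#'
#' Pushes the current raw measurement into the delay buffer and forms the
#' innovation between the buffer's oldest entry (the measurement that has
#' just become perceivable, age `n_delay` steps) and the delayed-time-base
#' estimate: \eqn{\hat X^{del}_{j+1} = A\hat X^{del}_j + B u_j +
#' K_k(Y_j - H\hat X^{del}_j) (+ B\eta)}, with \eqn{u_j} the command of the
#' same age taken from the command buffer. The reported current estimate is
#' the forward prediction of the delayed estimate through the internal model
#' using the buffered recent commands; with zero delay the two coincide and
#' the update reduces to the standard Kalman form.
#'
#' @param belief `belief_state`
#' @param u abstract command applied at this step (2-vector)
#' @param measurement current raw sensory vector (6-vector; kinematic
#'   channels from the plant, activation channels self-read from the belief)
#' @param solution `ofc_solution`
#' @param k step index
#' @param eta optional estimation noise sample on the command channels
#'   (2-vector; `NULL` for the noise-free mode)
#' @return updated `belief_state`
#' @export
estimate_state <- function(belief, u, measurement, solution, k, eta = NULL) {
  stop_if(length(measurement) != 6, "measurement must be a 6-vector")
  stop_if(length(u) != 2, "command must be a 2-vector")
  model <- solution$model
  kk <- min(max(k - belief$n_delay, 1), length(solution$K))
  K <- solution$K[[kk]]
  if (belief$n_delay > 0) {
    y_old <- belief$buf_y[1, ]
    u_old <- belief$buf_u[1, ]
    belief$buf_y <- rbind(belief$buf_y[-1, , drop = FALSE], measurement)
    belief$buf_u <- rbind(belief$buf_u[-1, , drop = FALSE], u)
  } else {
    y_old <- measurement
    u_old <- u
  }
  innov <- y_old - as.numeric(model$H %*% belief$xhat_del)
  xdel <- as.numeric(model$A %*% belief$xhat_del + model$B %*% u_old + K %*% innov)
  if (!is.null(eta)) xdel <- xdel + as.numeric(model$B %*% eta)
  check_finite(xdel, "belief state")
  belief$xhat_del <- xdel
  # forward-predict through the buffered commands to the current time
  x <- xdel
  if (belief$n_delay > 0) {
    for (j in seq_len(belief$n_delay)) {
      x <- as.numeric(model$A %*% x + model$B %*% belief$buf_u[j, ])
    }
  }
  belief$xhat <- x
  belief
}

#' Standalone rollout of the internal model
#'
#' Simulates the abstract plant under its own optimal controller and Kalman
#' filter, without the musculoskeletal layer: the "perceived" movement.
#' With `seed` given, process, sensory, multiplicative, and estimation noise
#' are drawn from their stated Gaussians; with `seed = NULL` the rollout is
#' noise-free and deterministic.
#'
#' @param model `internal_plant`
#' @param solution `ofc_solution`
#' @param params `internal_model_params`
#' @param seed integer seed for the stochastic mode, or `NULL` for noise-free
#' @param x0 initial true state (target-relative); defaults to rest at the
#'   start position implied by the target
#' @return list with matrices `X` (true state, N x 6), `Xhat` (estimate),
#'   `U` (commands, (N-1) x 2)
#' @export
simulate_internal <- function(model, solution, params, seed = NULL, x0 = NULL) {
  N <- solution$N
  if (is.null(x0)) x0 <- c(-model$target, 0, 0, 0, 0)
  noisy <- !is.null(seed)
  if (noisy) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  chol_or_zero <- function(S) if (max(abs(S)) == 0) NULL else t(chol(S + 1e-300 * diag(nrow(S))))
  Lxi <- chol_or_zero(params$xi)
  Lom <- chol_or_zero(params$omega)
  Leta <- chol_or_zero(params$eta)
  X <- matrix(0, N, 6); Xh <- matrix(0, N, 6); U <- matrix(0, N - 1, 2)
  x <- x0
  belief <- belief_state(x0, model)
  X[1, ] <- x; Xh[1, ] <- belief$xhat
  for (k in 1:(N - 1)) {
    u <- control_command(solution, belief, k)
    U[k, ] <- u
    y <- as.numeric(model$H %*% x)
    if (noisy && !is.null(Lom)) y <- y + as.numeric(Lom %*% rnorm(6))
    eta <- if (noisy && !is.null(Leta)) as.numeric(Leta %*% rnorm(2)) else NULL
    belief <- estimate_state(belief, u, y, solution, k, eta = eta)
    xnext <- as.numeric(model$A %*% x + model$B %*% u)
    if (noisy) {
      for (i in seq_along(model$Cmult)) {
        xnext <- xnext + rnorm(1) * as.numeric(model$Cmult[[i]] %*% u)
      }
      if (!is.null(Lxi)) xnext <- xnext + as.numeric(Lxi %*% rnorm(6))
    }
    x <- xnext
    X[k + 1, ] <- x
    Xh[k + 1, ] <- belief$xhat
  }
  list(X = X, Xhat = Xh, U = U)
}

# Quadratic cost of a rolled-out trajectory under a cost schedule.
internal_cost <- function(traj, cost) {
  N <- cost$N
  J <- 0
  for (k in 1:N) J <- J + as.numeric(t(traj$X[k, ]) %*% cost$Q[[k]] %*% traj$X[k, ])
  for (k in 1:(N - 1)) J <- J + as.numeric(t(traj$U[k, ]) %*% cost$R %*% traj$U[k, ])
  J
}

# Save/restore the global RNG state so seeded helpers do not disturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
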