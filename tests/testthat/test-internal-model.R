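# High-level module: internal model, cost, coupled gain recursions, belief.

test_that("the discrete internal plant matches the hand discretization", {
  p <- internal_model_params()
  mdl <- build_internal_model(p, target = c(0.12, 0))
  # velocity <- activation coupling: dt * Fmax / m
  expect_equal(mdl$A[3, 5], 0.005 * 1000 / 3, tolerance = 1e-12)
  expect_equal(mdl$A[4, 6], 0.005 * 1000 / 3, tolerance = 1e-12)
  expect_equal(mdl$A[1, 3], 0.005)
  expect_equal(mdl$A[5, 5], 1 - 0.005 / 0.030, tolerance = 1e-12)
  expect_equal(mdl$B[5, 1], 0.005 / 0.030, tolerance = 1e-12)
  expect_true(all(mdl$H == diag(6)))
  # equilibrium: at target at rest, zero input keeps the state at zero
  expect_equal(as.numeric(mdl$A %*% rep(0, 6) + mdl$B %*% c(0, 0)), rep(0, 6))
  # Euler consistency: (A - I)/dt approaches the continuous system matrix
  for (dt in c(1e-3, 1e-4, 1e-5)) {
    pp <- internal_model_params(dt = dt, N = 21, D = 2, delay = 0)
    md <- build_internal_model(pp, c(0, 0))
    Acont <- matrix(0, 6, 6)
    Acont[1, 3] <- Acont[2, 4] <- 1
    Acont[3, 5] <- Acont[4, 6] <- 1000 / 3
    Acont[5, 5] <- Acont[6, 6] <- -1 / 0.030
    expect_lt(max(abs((md$A - diag(6)) / dt - Acont)), 1e-9)
  }
  expect_error(internal_model_params(dt = 0), "positive")
  expect_error(internal_model_params(tau = -1), "positive")
  expect_error(internal_model_params(m = 0), "positive")
})

test_that("the cost schedule has exactly D trailing identity penalties", {
  p <- internal_model_params()   # N = 221, D = 21
  cs <- build_cost_schedule(p)
  nz <- vapply(cs$Q, function(Q) any(Q != 0), TRUE)
  expect_equal(sum(!nz), 200)
  expect_equal(sum(nz), 21)
  expect_true(all(which(nz) > 200))
  for (k in which(nz)) expect_equal(cs$Q[[k]], diag(6))
  expect_equal(sum(vapply(cs$Q, function(Q) sum(diag(Q)), 0)), 6 * 21)
  # D = N - 1 leaves only the first step unpenalized
  p2 <- internal_model_params(N = 10, D = 9, delay = 0)
  nz2 <- vapply(build_cost_schedule(p2)$Q, function(Q) any(Q != 0), TRUE)
  expect_equal(which(!nz2), 1L)
  expect_error(internal_model_params(N = 10, D = 10), "N > D")
})

test_that("without multiplicative noise the feedback gains are the classical LQR solution", {
  p <- internal_model_params(mult_scale = 0, delay = 0, eta = 0)
  mdl <- build_internal_model(p, target = c(0.12, 0))
  cs <- build_cost_schedule(p)
  sol <- solve_ofc(mdl, cs, p)
  want <- lqr_gains(mdl$A, mdl$B, cs$Q, cs$R)
  diffs <- vapply(seq_along(want), function(k) max(abs(sol$L[[k]] - want[[k]])), 0)
  expect_lt(max(diffs), 1e-8)
})

test_that("the Kalman gain schedule converges to the DARE solution", {
  # stationary case: constant Q would not matter; gains converge along the
  # schedule to the algebraic-Riccati fixed point
  p <- internal_model_params(mult_scale = 0, delay = 0, eta = 0, N = 221)
  mdl <- build_internal_model(p, target = c(0.12, 0))
  sol <- solve_ofc(mdl, build_cost_schedule(p), p)
  Kinf <- dare_kalman(mdl$A, mdl$H, p$xi, p$omega)
  expect_lt(max(abs(sol$K[[length(sol$K)]] - Kinf)), 1e-8)
})

test_that("zero state penalties give zero feedback gains", {
  p <- internal_model_params(N = 41, D = 5, delay = 0, Q_dwell = 0)
  mdl <- build_internal_model(p, c(0.1, 0))
  sol <- solve_ofc(mdl, build_cost_schedule(p), p)
  expect_true(all(vapply(sol$L, function(L) max(abs(L)), 0) < 1e-12))
})

test_that("signal-dependent noise does not enlarge the terminal-step gains", {
  p0 <- internal_model_params(mult_scale = 0)
  p1 <- internal_model_params(mult_scale = 0.2)
  mdl0 <- build_internal_model(p0, c(0.12, 0))
  mdl1 <- build_internal_model(p1, c(0.12, 0))
  s0 <- solve_ofc(mdl0, build_cost_schedule(p0), p0)
  s1 <- solve_ofc(mdl1, build_cost_schedule(p1), p1)
  nL <- length(s0$L)
  expect_lte(max(abs(s1$L[[nL]])), max(abs(s0$L[[nL]])) + 1e-12)
})

test_that("control_command is the scheduled linear readout of the belief", {
  p <- fast_params()
  mdl <- build_internal_model(p, c(0.1, 0.05))
  sol <- solve_ofc(mdl, build_cost_schedule(p), p)
  bel <- belief_state(rep(0, 6), mdl)
  expect_equal(control_command(sol, bel, 3), c(0, 0))
  bel$xhat <- c(1, 0, 0, 0, 0, 0)
  expect_equal(control_command(sol, bel, 7), as.numeric(sol$L[[7]][, 1]))
  expect_error(control_command(sol, bel, 0), "schedule")
  expect_error(control_command(sol, bel, p$N + 5), "schedule")
})

test_that("with zero Kalman gain the belief is a pure prediction", {
  p <- fast_params(delay = 0)
  mdl <- build_internal_model(p, c(0.1, 0))
  sol <- solve_ofc(mdl, build_cost_schedule(p), p)
  for (k in seq_along(sol$K)) sol$K[[k]] <- matrix(0, 6, 6)
  bel <- belief_state(c(0.1, -0.05, 0.2, 0, 0.01, 0), mdl)
  u <- c(0.3, -0.2)
  bel2 <- estimate_state(bel, u, rnorm(6), sol, 1)
  expect_equal(bel2$xhat, as.numeric(mdl$A %*% bel$xhat + mdl$B %*% u),
               tolerance = 1e-12)
})

test_that("the noise-free estimator converges to the true state without delay", {
  p <- internal_model_params(delay = 0, mult_scale = 0, eta = 0)
  mdl <- build_internal_model(p, c(0.12, 0))
  sol <- solve_ofc(mdl, build_cost_schedule(p), p)
  x <- c(-0.12, 0, 0, 0, 0, 0)
  bel <- belief_state(x + c(0.02, -0.01, 0.05, 0, 0, 0), mdl)  # wrong prior
  for (k in 1:200) {
    u <- control_command(sol, bel, k)
    y <- as.numeric(mdl$H %*% x)
    bel <- estimate_state(bel, u, y, sol, k)
    x <- as.numeric(mdl$A %*% x + mdl$B %*% u)
  }
  expect_lt(max(abs(bel$xhat - x)), 1e-6)
})

test_that("the noise-free internal rollout reaches all eight center-out targets", {
  p <- internal_model_params()
  for (th in 2 * pi * (0:7) / 8) {
    tgt <- 0.12 * c(cos(th), sin(th))
    mdl <- build_internal_model(p, tgt)
    sol <- solve_ofc(mdl, build_cost_schedule(p), p)
    tr <- simulate_internal(mdl, sol, p)
    expect_lt(sqrt(sum(tr$X[p$N, 1:2]^2)), 1e-3)          # < 1 mm
    expect_lt(sqrt(sum(tr$X[p$N, 3:4]^2)), 1e-3)          # < 1 mm/s
    # single-peaked speed profile over the movement portion
    speed <- sqrt(rowSums(tr$X[1:(p$N - p$D), 3:4]^2))
    ds <- diff(speed)
    ds <- ds[abs(ds) > 1e-12]
    expect_equal(sum(diff(sign(ds)) != 0), 1)
  }
})

test_that("zero target displacement gives an identically zero rollout", {
  p <- fast_params()
  mdl <- build_internal_model(p, c(0, 0))
  sol <- solve_ofc(mdl, build_cost_schedule(p), p)
  tr <- simulate_internal(mdl, sol, p, x0 = rep(0, 6))
  expect_true(all(tr$X == 0))
  expect_true(all(tr$U == 0))
})

test_that("the optimal controller beats zero control and random gain policies", {
  p <- internal_model_params(delay = 0)
  mdl <- build_internal_model(p, c(0.12, 0))
  cs <- build_cost_schedule(p)
  sol <- solve_ofc(mdl, cs, p)
  rollout_with_gains <- function(Lfun) {
    x <- c(-0.12, 0, 0, 0, 0, 0)
    X <- matrix(0, p$N, 6); U <- matrix(0, p$N - 1, 2)
    X[1, ] <- x
    for (k in 1:(p$N - 1)) {
      u <- as.numeric(Lfun(k) %*% x)    # full state feedback, noise-free
      U[k, ] <- u
      x <- as.numeric(mdl$A %*% x + mdl$B %*% u)
      X[k + 1, ] <- x
    }
    reacharm:::internal_cost(list(X = X, U = U), cs)
  }
  J_opt <- rollout_with_gains(function(k) sol$L[[k]])
  J_zero <- rollout_with_gains(function(k) matrix(0, 2, 6))
  expect_lte(J_opt, J_zero)
  set.seed(11)
  for (i in 1:100) {
    Lr <- matrix(rnorm(12, sd = 0.5), 2, 6)
    expect_lte(J_opt, rollout_with_gains(function(k) Lr) + 1e-12)
  }
})

test_that("seeded internal rollouts are bitwise reproducible and noise differs across seeds", {
  p <- fast_params()
  mdl <- build_internal_model(p, c(0.1, -0.05))
  sol <- solve_ofc(mdl, build_cost_schedule(p), p)
  t1 <- simulate_internal(mdl, sol, p, seed = 42)
  t2 <- simulate_internal(mdl, sol, p, seed = 42)
  t3 <- simulate_internal(mdl, sol, p, seed = 43)
  expect_identical(t1, t2)
  expect_false(identical(t1$X, t3$X))
  # stochastic trajectories actually differ from the noise-free one
  t0 <- simulate_internal(mdl, sol, p)
  expect_gt(max(abs(t1$X - t0$X)), 0)
})

test_that("parameter validation rejects inconsistent noise and delay settings", {
  expect_error(internal_model_params(delay = 0.007), "multiple")
  expect_error(internal_model_params(xi = matrix(1:36, 6)), "positive semi-definite")
  bad_R <- matrix(0, 2, 2)
  expect_error(internal_model_params(R = bad_R), "positive definite")
})
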