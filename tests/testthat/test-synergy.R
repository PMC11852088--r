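# Mid-level module: static load sharing, synergy learning, NNLS expansion.

test_that("optimal static activations reproduce the requested hand force", {
  q <- test_arm$reference_q
  expect_equal(optimal_static_activations(test_arm, q, c(0, 0)), rep(0, 6))
  Phi <- reacharm:::arm_statics_map(q, test_arm, return_matrix = TRUE)
  set.seed(21)
  for (i in 1:25) {
    f <- runif(2, -30, 30)
    a <- optimal_static_activations(test_arm, q, f)
    expect_true(all(a >= 0 & a <= 1))
    expect_lt(max(abs(as.numeric(Phi %*% a) - f)), 1e-6)
  }
})

test_that("doubling a feasible force does not shrink the activation norm", {
  q <- test_arm$reference_q
  set.seed(22)
  for (i in 1:10) {
    f <- runif(2, -20, 20)
    a1 <- optimal_static_activations(test_arm, q, f)
    a2 <- optimal_static_activations(test_arm, q, 2 * f)
    expect_gte(sqrt(sum(a2^2)), sqrt(sum(a1^2)) - 1e-10)
  }
})

test_that("infeasible forces raise an error naming the feasible magnitude", {
  q <- test_arm$reference_q
  err <- tryCatch(optimal_static_activations(test_arm, q, c(5000, 0)),
                  error = function(e) conditionMessage(e))
  expect_match(err, "infeasible")
  expect_match(err, "maximum achievable")
  # the reported bound is itself achievable within its resolution
  mag <- as.numeric(sub(".* is ([0-9.]+) N", "\\1", err))
  expect_true(is.finite(mag) && mag > 0)
  a <- optimal_static_activations(test_arm, q, c(0.9 * mag, 0))
  expect_true(all(a <= 1))
})

test_that("the learned synergy set is non-negative, normalized, and reconstructs the samples", {
  syn <- test_syn
  expect_true(all(syn$S >= 0))
  expect_equal(apply(syn$S, 2, max), rep(1, 4))
  expect_gte(syn$recon_r2, 0.90)
  expect_equal(qr(syn$B)$rank, 2)
  # deterministic given the seed
  syn2 <- learn_synergies(test_arm, seed = 1)
  expect_identical(syn$S, syn2$S)
  # the positive cone of the basis covers every direction
  for (th in seq(0, 2 * pi, length.out = 64)) {
    co <- decompose_command(c(cos(th), sin(th)), syn$B)
    expect_lt(attr(co, "residual"), 1e-9)
  }
})

test_that("a full-rank factorization reconstructs the sampled activations", {
  syn <- learn_synergies(test_arm, n_directions = 4, n_synergies = 4, seed = 2)
  expect_gte(syn$recon_r2, 1 - 1e-4)
})

test_that("the stored basis is the statics map of the synergies", {
  syn <- test_syn
  B0 <- task_basis(syn, test_arm, syn$reference_q)
  expect_lt(max(abs(B0 - syn$B)), 1e-12)
  # at any posture each column equals the statics map applied to S e_i
  q <- syn$reference_q + c(0.2, -0.3)
  B1 <- task_basis(syn, test_arm, q)
  for (i in 1:4) {
    expect_equal(B1[, i], reacharm:::arm_statics_map(q, test_arm, syn$S[, i]),
                 tolerance = 1e-12)
  }
  # basis verifies against the musculoskeletal statics to tight tolerance
  Phi <- reacharm:::arm_statics_map(syn$reference_q, test_arm, return_matrix = TRUE)
  expect_lt(max(abs(Phi %*% syn$S - syn$B)), 1e-9)
  # doubling all maximum isometric forces doubles the basis
  arm2 <- test_arm
  arm2$muscles$fmax <- 2 * arm2$muscles$fmax
  arm2 <- reacharm:::.arm_cache_geometry(arm2)
  expect_equal(task_basis(syn, arm2, syn$reference_q), 2 * B0, tolerance = 1e-12)
})

test_that("velocity compensation vanishes at rest and equals the Coriolis term otherwise", {
  st0 <- arm_state(test_arm$reference_q)
  expect_identical(compensate_velocity(c(0.02, -0.01), st0, test_arm, 1000),
                   c(0.02, -0.01) * 1000)
  st <- arm_state(test_arm$reference_q, qd = c(1.5, -2))
  comp <- compensate_velocity(c(0, 0), st, test_arm, 1000)
  # oracle: J^-T times the velocity-product torques of the Lagrangian model
  Tfun <- function(q, qd) {
    v1 <- test_arm$skeleton$d1 * qd[1] * c(-sin(q[1]), cos(q[1]))
    ve <- test_arm$skeleton$l1 * qd[1] * c(-sin(q[1]), cos(q[1]))
    v2 <- ve + test_arm$skeleton$d2 * (qd[1] + qd[2]) * c(-sin(q[1] + q[2]), cos(q[1] + q[2]))
    vh <- ve + test_arm$skeleton$l2 * (qd[1] + qd[2]) * c(-sin(q[1] + q[2]), cos(q[1] + q[2]))
    0.5 * (test_arm$skeleton$m1 * sum(v1^2) + test_arm$skeleton$I1 * qd[1]^2 +
             test_arm$skeleton$m2 * sum(v2^2) + test_arm$skeleton$I2 * (qd[1] + qd[2])^2 +
             test_arm$hand_mass * sum(vh^2))
  }
  # c(q,qd) qd = d/dt(dT/dqd) - dT/dq with qdd = 0
  h <- 1e-6
  dTdqd <- function(q, qd) fd_grad(function(v) Tfun(q, v), qd, h)
  term1 <- (dTdqd(st$q + h * st$qd, st$qd) - dTdqd(st$q - h * st$qd, st$qd)) / (2 * h)
  term2 <- fd_grad(function(q) Tfun(q, st$qd), st$q, h)
  cv_oracle <- term1 - term2
  J <- hand_jacobian(st$q, test_arm)
  want <- as.numeric(solve(t(J), cv_oracle))
  expect_lt(max(abs(comp - want)), 1e-4 * max(1, max(abs(want))))
  # additivity: command and compensation superpose
  both <- compensate_velocity(c(0.02, -0.01), st, test_arm, 1000)
  expect_equal(both, c(20, -10) + comp, tolerance = 1e-12)
})

test_that("NNLS decomposition matches the exhaustive active-set oracle", {
  B <- test_syn$B
  set.seed(23)
  for (i in 1:100) {
    # in-cone commands: random non-negative combinations of the basis
    f <- as.numeric(B %*% runif(4, 0, 0.3))
    co <- decompose_command(f, B)
    expect_true(all(co >= 0))
    expect_lt(attr(co, "residual"), 1e-10)
    oracle <- nnls_oracle(B, f)
    expect_lt(abs(attr(co, "residual")^2 - oracle$value), 1e-10)
  }
  # out-of-cone commands still agree with the oracle on the residual
  for (i in 1:50) {
    f <- rnorm(2, sd = 50)
    co <- decompose_command(f, B)
    oracle <- nnls_oracle(B, f)
    expect_lt(abs(attr(co, "residual")^2 - oracle$value), 1e-8)
  }
})

test_that("decomposition handles basis columns and degenerate inputs", {
  B <- test_syn$B
  co0 <- decompose_command(c(0, 0), B)
  expect_equal(as.numeric(co0), rep(0, 4))
  for (i in 1:4) {
    co <- decompose_command(B[, i], B)
    expect_lt(attr(co, "residual"), 1e-10)
  }
  expect_error(decompose_command(c(1, 0), matrix(c(1, 0, 2, 0), 2, 2)), "span")
})

test_that("excitation expansion is a clipped non-negative map", {
  e0 <- expand_to_excitations(test_syn, rep(0, 4))
  expect_equal(as.numeric(e0), rep(0, 6))
  e1 <- expand_to_excitations(test_syn, c(1, 0, 0, 0))
  expect_equal(as.numeric(e1), pmin(pmax(test_syn$S[, 1], 0), 1))
  set.seed(24)
  for (i in 1:50) {
    co <- runif(4, 0, 3)
    e <- expand_to_excitations(test_syn, co)
    expect_true(all(e >= 0 & e <= 1))
    pre <- attr(e, "pre_clip")
    expect_true(all(pre >= 0))
    expect_equal(as.numeric(e), pmin(pre, 1))
  }
  expect_error(expand_to_excitations(test_syn, c(-0.1, 0, 0, 0)), "non-negative")
})

test_that("pracma's NNLS agrees on well-conditioned in-cone decompositions", {
  # cross-check of the in-package Lawson-Hanson engine against pracma
  B <- test_syn$B
  set.seed(25)
  for (i in 1:20) {
    f <- as.numeric(B %*% runif(4, 0.05, 0.3))
    ours <- reacharm:::nnls_solve(B, f)
    theirs <- tryCatch(pracma::lsqnonneg(B, f), error = function(e) NULL)
    if (!is.null(theirs)) {
      expect_lt(abs(ours$resid_norm2 - theirs$resid.norm), 1e-10)
    }
  }
})

test_that("static excitation round trip keeps the commanded force direction", {
  # decompose + expand, applied isometrically, recovers the force direction
  q <- test_arm$reference_q
  Phi <- reacharm:::arm_statics_map(q, test_arm, return_matrix = TRUE)
  basis <- Phi %*% test_syn$S
  for (th in 2 * pi * (0:31) / 32) {
    dirv <- c(cos(th), sin(th))
    fmax_dir <- reacharm:::.max_feasible_force(Phi, dirv, tol = 0.5)
    f <- 0.25 * fmax_dir * dirv
    e <- expand_to_excitations(test_syn, decompose_command(f, basis))
    achieved <- as.numeric(Phi %*% e)
    cosang <- sum(achieved * f) / sqrt(sum(achieved^2) * sum(f^2))
    expect_gte(cosang, 0.95)
  }
})

test_that("a +x force command at reference posture is flexor-dominated and mirrored", {
  # agonist-antagonist structure: compare summed flexor vs extensor drive
  q <- test_arm$reference_q
  Phi <- reacharm:::arm_statics_map(q, test_arm, return_matrix = TRUE)
  basis <- Phi %*% test_syn$S
  e_pos <- expand_to_excitations(test_syn, decompose_command(c(20, 0), basis))
  e_neg <- expand_to_excitations(test_syn, decompose_command(c(-20, 0), basis))
  # muscles pulling the hand toward +x at this posture (from the statics map)
  pull_x <- Phi[1, ]
  drive_pos <- sum(e_pos * (pull_x > 0)) - sum(e_pos * (pull_x < 0))
  drive_neg <- sum(e_neg * (pull_x > 0)) - sum(e_neg * (pull_x < 0))
  expect_gt(drive_pos, 0)
  expect_lt(drive_neg, 0)
})

test_that("synergy sets survive a plain-text round trip", {
  path <- tempfile(fileext = ".txt")
  write_synergies(test_syn, path)
  back <- read_synergies(path)
  expect_equal(back$S, test_syn$S, tolerance = 1e-15)
  expect_equal(back$B, test_syn$B, tolerance = 1e-15)
  expect_equal(back$reference_q, test_syn$reference_q, tolerance = 1e-15)
  expect_equal(back$n_synergies, test_syn$n_synergies)
})
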