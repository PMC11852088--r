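# Robot dynamics, inverse kinematics, curl field, and the rigid coupling.

test_that("robot dynamics is at rest without inputs and matches the Lagrangian oracle", {
  r <- robot_params()
  expect_equal(robot_dynamics(r, c(0.5, 1.0), c(0, 0)), c(0, 0))
  set.seed(31)
  for (i in 1:50) {
    th <- runif(2, -2, 2); thd <- runif(2, -3, 3)
    tq <- runif(2, -3, 3); f <- runif(2, -15, 15)
    got <- robot_dynamics(r, th, thd, tq, f)
    want <- lagrangian_accel(r, th, thd, tq, f)
    expect_lt(max(abs(got - want)), 1e-5)
  }
})

test_that("robot inverse kinematics round-trips on both branches", {
  r <- robot_params(base = c(0, 0.75))
  expect_equal(robot_inverse_kinematics(r, r$base + c(0.6, 0)), c(0, 0),
               tolerance = 1e-9)
  set.seed(32)
  for (i in 1:50) {
    ang <- runif(1, -pi, pi)
    pt <- r$base + runif(1, 0.1, 0.55) * c(cos(ang), sin(ang))
    for (br in c("up", "down")) {
      th <- robot_inverse_kinematics(r, pt, br)
      expect_lt(sqrt(sum((robot_kinematics(r, th)$pos - pt)^2)), 1e-9)
    }
  }
  expect_error(robot_inverse_kinematics(r, r$base + c(0.6 + 1e-3, 0)), "unreachable")
})

test_that("the curl field is velocity-proportional and perpendicular", {
  f3 <- curl_field(3)
  expect_equal(curl_field_force(f3, c(0, 0)), c(0, 0))
  expect_equal(curl_field_force(f3, c(0.1, 0)), c(0, -0.3), tolerance = 1e-12)
  expect_equal(curl_field_force(curl_field(-3), c(0.1, 0)), c(0, 0.3), tolerance = 1e-12)
  set.seed(33)
  for (i in 1:20) {
    v <- rnorm(2)
    expect_lt(abs(sum(curl_field_force(f3, v) * v)), 1e-12)
    expect_equal(sqrt(sum(curl_field_force(f3, v)^2)), 3 * sqrt(sum(v^2)),
                 tolerance = 1e-12)
  }
})

make_coupled_fixture <- function(qd = c(0, 0), thetad = NULL) {
  r <- robot_params(base = test_arm$skeleton$base + c(0, 0.75))
  start <- test_arm$skeleton$base + c(0, 0.40)
  q <- twolink_ik(test_arm$skeleton, start, "up")
  th <- robot_inverse_kinematics(r, start, "down")
  if (is.null(thetad)) {
    # consistent joint velocities: same hand velocity on both chains
    vh <- twolink_jacobian(test_arm$skeleton, q) %*% qd
    thetad <- as.numeric(solve(twolink_jacobian(r, th), vh))
  }
  list(robot = r, state = arm_state(q, qd), theta = th, thetad = thetad)
}

test_that("a symmetric rest with zero inputs produces no motion and no interaction force", {
  fx <- make_coupled_fixture()
  acc <- coupled_accelerations(test_arm, fx$state, rep(0, 6), fx$robot,
                               fx$theta, fx$thetad)
  expect_equal(acc$qdd, c(0, 0), tolerance = 1e-10)
  expect_equal(acc$thetadd, c(0, 0), tolerance = 1e-10)
  expect_equal(acc$interaction, c(0, 0), tolerance = 1e-10)
  expect_lt(acc$gap, 1e-12)
})

test_that("applying the interaction force to the free bodies reproduces the coupled solution", {
  set.seed(34)
  for (i in 1:10) {
    fx <- make_coupled_fixture(qd = runif(2, -1, 1))
    st <- fx$state
    st$a <- runif(6, 0, 0.4)
    mf <- muscle_forces(st, test_arm)
    tq <- runif(2, -2, 2)
    acc <- coupled_accelerations(test_arm, st, mf, fx$robot, fx$theta, fx$thetad,
                                 torques = tq)
    # uncoupled limit: each free body under the constraint force
    qdd_free <- arm_dynamics(st, mf, test_arm, hand_force = acc$interaction)
    thdd_free <- robot_dynamics(fx$robot, fx$theta, fx$thetad, tq, -acc$interaction)
    expect_lt(max(abs(qdd_free - acc$qdd)), 1e-9)
    expect_lt(max(abs(thdd_free - acc$thetadd)), 1e-9)
  }
})

test_that("the coupled passive system conserves energy and keeps the constraint", {
  fx <- make_coupled_fixture(qd = c(0.6, -0.4))
  z <- c(fx$state$q, fx$state$qd, fx$theta, fx$thetad)
  deriv <- function(z) {
    st <- arm_state(z[1:2], z[3:4])
    acc <- coupled_accelerations(test_arm, st, rep(0, 6), fx$robot, z[5:6], z[7:8])
    c(z[3:4], acc$qdd, z[7:8], acc$thetadd)
  }
  E <- function(z) {
    reacharm:::arm_kinetic_energy(test_arm, z[1:2], z[3:4]) +
      reacharm:::twolink_kinetic_energy(fx$robot, z[5:6], z[7:8])
  }
  E0 <- E(z)
  max_gap <- 0
  for (k in 1:200) {
    z <- reacharm:::rk4_step(z, deriv, 0.005)
    gap <- sqrt(sum((twolink_fk(test_arm$skeleton, z[1:2])$pos -
                       twolink_fk(fx$robot, z[5:6])$pos)^2))
    max_gap <- max(max_gap, gap)
  }
  expect_lt(abs(E(z) - E0), 1e-6)
  expect_lt(max_gap, 1e-6)
})

test_that("the constraint force balances both free bodies along a driven coupled run", {
  cfg <- scenario_config(N = 61, D = 11, robot_mode = "off",
                         target = test_arm$skeleton$base + c(-0.08, 0.42))
  sim <- reacharm:::sim_init(cfg, arm = test_arm, synergies = test_syn)
  saw_force <- FALSE
  for (k in 1:40) {
    sim <- step_closed_loop(sim, c(0.3, -0.2))
    expect_lt(sim$last$gap, 1e-6)
    lam <- sim$last$interaction
    expect_true(all(is.finite(lam)))
    if (max(abs(lam)) > 0.01) saw_force <- TRUE
    # action-reaction: accelerations from +lam on the arm and -lam on the
    # robot match the coupled solution (checked at a thinned set of ticks)
    if (k %% 10 == 0) {
      st <- sim$state
      mf <- muscle_forces(st, test_arm)
      acc <- coupled_accelerations(test_arm, st, mf, sim$robot, sim$theta,
                                   sim$thetad, torques = c(0.3, -0.2))
      qdd_free <- arm_dynamics(st, mf, test_arm, hand_force = acc$interaction)
      thdd_free <- robot_dynamics(sim$robot, sim$theta, sim$thetad,
                                  c(0.3, -0.2), -acc$interaction)
      expect_lt(max(abs(qdd_free - acc$qdd)), 1e-8)
      expect_lt(max(abs(thdd_free - acc$thetadd)), 1e-8)
    }
  }
  expect_true(saw_force)
})
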