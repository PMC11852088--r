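# Planar two-link rigid-body chain: closed-form kinematics and dynamics.
# Shared by the musculoskeletal arm (shoulder/elbow) and the robot; both are
# revolute-revolute chains moving in a horizontal plane, so gravity exerts no
# joint torque. Angle convention: q[1] measured from the world +x axis,
# q[2] relative to the first link, counterclockwise positive, radians.

#' Two-link chain parameter set
#'
#' Bundles the geometric and inertial parameters of a planar revolute-revolute
#' chain. Lengths in m, masses in kg, centre-of-mass distances in m (measured
#' from the proximal joint along the link), inertias in kg m^2 about the link
#' centre of mass, base position in world coordinates (m).
#'
#' @param l1,l2 link lengths (m)
#' @param m1,m2 link masses (kg)
#' @param d1,d2 centre-of-mass distances from the proximal joint (m)
#' @param I1,I2 link moments of inertia about the centre of mass (kg m^2)
#' @param base world position of the proximal joint (length-2, m)
#' @return an object of class `twolink_params`
#' @export
twolink_params <- function(l1, l2, m1, m2, d1, d2, I1, I2, base = c(0, 0)) {
  vals <- c(l1 = l1, l2 = l2, m1 = m1, m2 = m2, d1 = d1, d2 = d2, I1 = I1, I2 = I2)
  stop_if(any(!is.finite(vals)) || any(vals <= 0), "two-link parameters must be positive and finite")
  stop_if(length(base) != 2 || any(!is.finite(base)), "base must be a finite 2-vector")
  structure(list(l1 = l1, l2 = l2, m1 = m1, m2 = m2, d1 = d1, d2 = d2,
                 I1 = I1, I2 = I2, base = as.numeric(base)),
            class = "twolink_params")
}

#' Forward kinematics of a two-link chain
#'
#' @param p `twolink_params`
#' @param q joint angles (rad, length 2)
#' @param qd joint velocities (rad/s, length 2)
#' @return list with `pos` (endpoint, m), `vel` (m/s), `elbow` (m)
#' @export
twolink_fk <- function(p, q, qd = c(0, 0)) {
  c1 <- cos(q[1]); s1 <- sin(q[1])
  c12 <- cos(q[1] + q[2]); s12 <- sin(q[1] + q[2])
  elbow <- p$base + p$l1 * c(c1, s1)
  pos <- elbow + p$l2 * c(c12, s12)
  J <- twolink_jacobian(p, q)
  list(pos = pos, vel = as.numeric(J %*% qd), elbow = elbow)
}

#' Endpoint Jacobian of a two-link chain
#'
#' @inheritParams twolink_fk
#' @return 2x2 Jacobian (m/rad)
#' @export
twolink_jacobian <- function(p, q) {
  s1 <- sin(q[1]); c1 <- cos(q[1])
  s12 <- sin(q[1] + q[2]); c12 <- cos(q[1] + q[2])
  matrix(c(-p$l1 * s1 - p$l2 * s12, -p$l2 * s12,
            p$l1 * c1 + p$l2 * c12,  p$l2 * c12),
         nrow = 2, byrow = TRUE)
}

# d(J)/dt %*% qd, needed at the acceleration level of the coupling constraint.
twolink_jdot_qd <- function(p, q, qd) {
  s1 <- sin(q[1]); c1 <- cos(q[1])
  s12 <- sin(q[1] + q[2]); c12 <- cos(q[1] + q[2])
  w1 <- qd[1]; w12 <- qd[1] + qd[2]
  # time derivative of each Jacobian entry, times qd
  c(-p$l1 * c1 * w1 * qd[1] - p$l2 * c12 * w12 * (qd[1] + qd[2]),
    -p$l1 * s1 * w1 * qd[1] - p$l2 * s12 * w12 * (qd[1] + qd[2]))
}

#' Mass matrix of a two-link chain
#'
#' @inheritParams twolink_fk
#' @return 2x2 symmetric positive-definite mass matrix (kg m^2)
#' @export
twolink_mass_matrix <- function(p, q) {
  c2 <- cos(q[2])
  m11 <- p$I1 + p$I2 + p$m1 * p$d1^2 + p$m2 * (p$l1^2 + p$d2^2 + 2 * p$l1 * p$d2 * c2)
  m12 <- p$I2 + p$m2 * (p$d2^2 + p$l1 * p$d2 * c2)
  m22 <- p$I2 + p$m2 * p$d2^2
  matrix(c(m11, m12, m12, m22), 2, 2)
}

# Velocity-product (Coriolis/centrifugal) joint torques C(q, qd) qd.
twolink_velocity_torques <- function(p, q, qd) {
  h <- p$m2 * p$l1 * p$d2 * sin(q[2])
  c(-h * qd[2] * (2 * qd[1] + qd[2]), h * qd[1]^2)
}

#' Joint accelerations of a two-link chain
#'
#' Solves the chain's equations of motion
#' \eqn{M(q)\ddot q + c(q,\dot q) = \tau + J^T F} for \eqn{\ddot q}.
#' No gravity term: the chain moves in a horizontal plane.
#'
#' @inheritParams twolink_fk
#' @param tau joint torques (N m, length 2)
#' @param endpoint_force external force applied at the endpoint (N, length 2)
#' @return joint accelerations (rad/s^2)
#' @export
twolink_accel <- function(p, q, qd, tau = c(0, 0), endpoint_force = c(0, 0)) {
  M <- twolink_mass_matrix(p, q)
  cv <- twolink_velocity_torques(p, q, qd)
  rhs <- tau + as.numeric(t(twolink_jacobian(p, q)) %*% endpoint_force) - cv
  as.numeric(solve(M, rhs))
}

#' Closed-form inverse kinematics of a two-link chain
#'
#' @inheritParams twolink_fk
#' @param point target endpoint in world coordinates (m)
#' @param elbow `"up"` (joint 2 angle positive, counterclockwise) or `"down"`
#' @return joint angles (rad)
#' @export
twolink_ik <- function(p, point, elbow = c("up", "down")) {
  elbow <- match.arg(elbow)
  r <- as.numeric(point) - p$base
  d <- sqrt(sum(r^2))
  reach <- p$l1 + p$l2
  inner <- abs(p$l1 - p$l2)
  if (d > reach + 1e-12 || d < inner - 1e-12) {
    stop(sprintf("point unreachable: distance %.4f m outside workspace [%.4f, %.4f] m (%.4f m past boundary)",
                 d, inner, reach, max(d - reach, inner - d)), call. = FALSE)
  }
  c2 <- (d^2 - p$l1^2 - p$l2^2) / (2 * p$l1 * p$l2)
  c2 <- min(1, max(-1, c2))
  q2 <- acos(c2)
  if (elbow == "down") q2 <- -q2
  q1 <- atan2(r[2], r[1]) - atan2(p$l2 * sin(q2), p$l1 + p$l2 * cos(q2))
  c(q1, q2)
}

# Kinetic energy, used by conservation tests and diagnostics.
twolink_kinetic_energy <- function(p, q, qd) {
  as.numeric(0.5 * t(qd) %*% twolink_mass_matrix(p, q) %*% qd)
}
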