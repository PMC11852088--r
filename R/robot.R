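# Two-link planar robot, rigid hand/end-effector coupling, and environment
# force fields.
#
# The robot is a revolute-revolute chain sharing the two-link math of the
# human skeleton. Coupling is a 2-D position constraint between the human
# hand and the robot end-effector (a revolute attachment transmits force but
# no torque); the constraint force is obtained from the Lagrange multiplier
# of the acceleration-level constraint with Baumgarte stabilization.

#' Robot parameter set
#'
#' Defaults: two 0.3 m links of 0.5 kg each, centre of mass at mid-link,
#' inertia 5e-3 kg m^2, base 0.75 m anterior (+y) to the human shoulder.
#'
#' @param l1,l2 link lengths (m)
#' @param m1,m2 link masses (kg)
#' @param d1,d2 centre-of-mass distances (m)
#' @param I1,I2 link inertias about the centre of mass (kg m^2)
#' @param base world position of the robot base (m)
#' @return a `twolink_params` object tagged as a robot
#' @export
robot_params <- function(l1 = 0.3, l2 = 0.3, m1 = 0.5, m2 = 0.5,
                         d1 = 0.15, d2 = 0.15, I1 = 5e-3, I2 = 5e-3,
                         base = c(0, 0.75)) {
  p <- twolink_params(l1, l2, m1, m2, d1, d2, I1, I2, base)
  class(p) <- c("robot_params", class(p))
  p
}

#' Robot joint accelerations
#'
#' @param robot `robot_params`
#' @param theta joint angles (rad)
#' @param thetad joint velocities (rad/s)
#' @param torques motor torques (N m, length 2)
#' @param endpoint_force external force at the end-effector (N, world frame)
#' @return joint accelerations (rad/s^2)
#' @export
robot_dynamics <- function(robot, theta, thetad, torques = c(0, 0),
                           endpoint_force = c(0, 0)) {
  twolink_accel(robot, theta, thetad, tau = torques, endpoint_force = endpoint_force)
}

#' Robot end-effector kinematics
#'
#' @inheritParams robot_dynamics
#' @return list with `pos`, `vel`, `jacobian`
#' @export
robot_kinematics <- function(robot, theta, thetad = c(0, 0)) {
  fk <- twolink_fk(robot, theta, thetad)
  list(pos = fk$pos, vel = fk$vel, jacobian = twolink_jacobian(robot, theta))
}

#' Robot inverse kinematics
#'
#' @param robot `robot_params`
#' @param point target end-effector position (m, world frame)
#' @param elbow `"up"` or `"down"` solution branch
#' @return joint angles (rad)
#' @export
robot_inverse_kinematics <- function(robot, point, elbow = c("up", "down")) {
  twolink_ik(robot, point, match.arg(elbow))
}

#' Curl force field parameters
#'
#' A velocity-dependent field \eqn{F = b \begin{pmatrix}0&1\\-1&0\end{pmatrix} v},
#' always perpendicular to the hand velocity. Positive `b` gives a clockwise
#' field, negative counterclockwise; `b = 0` disables the field.
#'
#' @param b field gain (N s/m)
#' @return a `curl_field` object
#' @export
curl_field <- function(b = 0) {
  stop_if(!is.finite(b), "field gain must be finite")
  structure(list(b = b, rot = matrix(c(0, -1, 1, 0), 2, 2)), class = "curl_field")
}

#' Curl-field force at a hand velocity
#'
#' @param field `curl_field`
#' @param velocity hand velocity (m/s, length 2)
#' @return perturbing force (N, length 2), perpendicular to `velocity`
#' @export
curl_field_force <- function(field, velocity) {
  field$b * as.numeric(field$rot %*% velocity)
}

#' Accelerations and interaction force of the coupled human-robot system
#'
#' Solves the two free-body equations together with the acceleration-level
#' coupling constraint (hand acceleration = end-effector acceleration, with
#' Baumgarte feedback on position and velocity drift) as one linear system in
#' \eqn{(\ddot q, \ddot\theta, \lambda)}. The multiplier \eqn{\lambda} is the
#' interaction force applied to the human hand; the robot end-effector
#' receives its exact negation.
#'
#' @param arm `arm_model`
#' @param state `arm_state`
#' @param muscle_f 6-vector of muscle forces (N)
#' @param robot `robot_params`
#' @param theta,thetad robot joint state
#' @param torques robot motor torques (N m)
#' @param field `curl_field` applied at the hand (optional)
#' @param baumgarte stabilization gain (1/s); position gain is its square
#' @param geom optional precomputed `muscle_geometry`
#' @return list with `qdd`, `thetadd`, `interaction` (force on the human
#'   hand, N), `gap` (current hand/end-effector distance, m)
#' @export
coupled_accelerations <- function(arm, state, muscle_f, robot, theta, thetad,
                                  torques = c(0, 0), field = NULL,
                                  baumgarte = 20, geom = NULL) {
  skel <- arm$skeleton
  if (is.null(geom)) geom <- muscle_geometry(state$q, arm, state$qd)
  Jh <- twolink_jacobian(skel, state$q)
  Jr <- twolink_jacobian(robot, theta)
  fk_h <- twolink_fk(skel, state$q, state$qd)
  fk_r <- twolink_fk(robot, theta, thetad)

  tau_h <- as.numeric(t(geom$moment_arms) %*% muscle_f)
  f_ext <- if (is.null(field)) c(0, 0) else curl_field_force(field, fk_h$vel)

  Mh <- arm_mass_matrix(arm, state$q)
  Mr <- twolink_mass_matrix(robot, theta)
  ch <- arm_velocity_torques(arm, state$q, state$qd)
  cr <- twolink_velocity_torques(robot, theta, thetad)

  # constraint: p_h(q) - p_r(theta) = 0, differentiated twice plus Baumgarte
  gap_vec <- fk_h$pos - fk_r$pos
  gapd_vec <- fk_h$vel - fk_r$vel
  bias <- twolink_jdot_qd(skel, state$q, state$qd) -
    twolink_jdot_qd(robot, theta, thetad) +
    2 * baumgarte * gapd_vec + baumgarte^2 * gap_vec

  # unknowns: [qdd (2), thetadd (2), lambda (2)]; lambda acts + on hand, - on robot
  KKT <- matrix(0, 6, 6)
  KKT[1:2, 1:2] <- Mh
  KKT[1:2, 5:6] <- -t(Jh)
  KKT[3:4, 3:4] <- Mr
  KKT[3:4, 5:6] <- t(Jr)
  KKT[5:6, 1:2] <- Jh
  KKT[5:6, 3:4] <- -Jr
  rhs <- c(tau_h + as.numeric(t(Jh) %*% f_ext) - ch,
           torques - cr,
           -bias)
  sol <- tryCatch(solve(KKT, rhs),
                  error = function(e) stop("coupled system is singular (both chains at a kinematic singularity)",
                                           call. = FALSE))
  list(qdd = sol[1:2], thetadd = sol[3:4], interaction = sol[5:6],
       gap = sqrt(sum(gap_vec^2)))
}
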