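# Two-link, six-muscle planar musculoskeletal arm with Hill-type muscles.
#
# The skeleton is a shoulder-elbow chain in a horizontal plane (no gravity
# torque). Six muscles act through straight origin-insertion lines: a
# mono-articular flexor/extensor pair at each joint plus a bi-articular pair.
# Muscle force F = a * fl * fv * Fmax (pull-only); activation follows
# first-order excitation dynamics with separate activation/deactivation time
# constants. Tendon compliance is neglected.

#' Default six-muscle arm fixture
#'
#' Returns the bundled synthetic musculoskeletal arm parameter set: a planar
#' shoulder-elbow linkage (upper arm 0.30 m / 1.9 kg, forearm 0.33 m / 1.1 kg)
#' with six Hill-type muscles whose straight-line paths give moment arms of
#' roughly 3-7 cm at the reference posture. Attachment coordinates are expressed in the frame of the
#' parent segment (`torso` = world with the shoulder at `shoulder_pos`,
#' `upper` = x axis along the upper arm from the shoulder, `fore` = x axis
#' along the forearm from the elbow). Optimal fiber lengths default to the
#' muscle lengths at `reference_q` so that the force-length curve peaks at the
#' reference posture; pass `l0` explicitly to override.
#'
#' All values are a documented synthetic stand-in (no individual-subject
#' anatomy is reproduced); every field can be overridden via `...` or a config
#' file.
#'
#' @param shoulder_pos world position of the shoulder (m)
#' @param reference_q posture (rad) at which optimal fiber lengths are set
#' @param ... named overrides for any fixture field
#' @return an object of class `arm_model`
#' @export
arm_model_default <- function(shoulder_pos = c(0, 0),
                              reference_q = NULL,
                              ...) {
  skel <- twolink_params(l1 = 0.30, l2 = 0.33, m1 = 1.9, m2 = 1.1,
                         d1 = 0.13, d2 = 0.16, I1 = 0.025, I2 = 0.045,
                         base = shoulder_pos)
  if (is.null(reference_q)) {
    # hand 0.40 m anterior (+y) to the shoulder, elbow flexed counterclockwise
    reference_q <- twolink_ik(skel, shoulder_pos + c(0, 0.40), elbow = "up")
  }
  muscles <- data.frame(
    name   = c("sh_flex", "sh_ext", "el_flex", "el_ext", "bi_flex", "bi_ext"),
    frame_org = c("torso", "torso", "upper", "upper", "torso", "torso"),
    org_x  = c(-0.021,  0.021, 0.170, 0.150, -0.025,  0.025),
    org_y  = c( 0.028, -0.028, 0.025, -0.020, 0.035, -0.035),
    frame_ins = c("upper", "upper", "fore", "fore", "fore", "fore"),
    ins_x  = c( 0.120,  0.120, 0.055, -0.035, 0.075, -0.030),
    ins_y  = c( 0.000,  0.000, 0.015,  0.000, 0.012, -0.010),
    fmax   = c(800, 800, 700, 700, 1000, 1000),
    stringsAsFactors = FALSE
  )
  model <- list(
    skeleton = skel,
    muscles = muscles,
    hand_mass = 1.8,         # point mass at the hand (kg): hand plus grasped
                             # load; makes the endpoint inertia consistent
                             # with the 3 kg point mass the high-level
                             # internal model assumes
    fl_width = 0.4,          # force-length bell width (dimensionless)
    v_max = 10,              # max shortening velocity (l0 per second)
    fv_max = 1.5,            # eccentric force plateau
    tau_act = 0.015,         # activation time constant (s)
    tau_deact = 0.050,       # deactivation time constant (s)
    reference_q = reference_q,
    l0 = NULL
  )
  dots <- list(...)
  for (nm in names(dots)) {
    stop_if(!nm %in% names(model), sprintf("unknown arm fixture field '%s'", nm))
    model[[nm]] <- dots[[nm]]
  }
  class(model) <- "arm_model"
  model <- .arm_cache_geometry(model)
  if (is.null(model$l0)) {
    model$l0 <- muscle_geometry(model$reference_q, model, use_l0 = FALSE)$lengths
  }
  stop_if(any(model$l0 <= 0), "optimal fiber lengths must be positive")
  model
}

# Precompute attachment matrices (2 x n) and frame codes (0 torso, 1 upper
# arm, 2 forearm) so the geometry kernel can run vectorized over muscles.
.arm_cache_geometry <- function(model) {
  mus <- model$muscles
  code <- function(f) match(f, c("torso", "upper", "fore")) - 1L
  model$geom_cache <- list(
    org = rbind(mus$org_x, mus$org_y),
    ins = rbind(mus$ins_x, mus$ins_y),
    forg = code(mus$frame_org),
    fins = code(mus$frame_ins),
    fmax = mus$fmax
  )
  model
}

#' @export
print.arm_model <- function(x, ...) {
  cat("Planar 2-link, 6-muscle arm\n")
  cat(sprintf("  links: %.2f m / %.2f m, masses %.2f / %.2f kg\n",
              x$skeleton$l1, x$skeleton$l2, x$skeleton$m1, x$skeleton$m2))
  cat(sprintf("  reference posture: (%.1f, %.1f) deg\n",
              x$reference_q[1] * 180 / pi, x$reference_q[2] * 180 / pi))
  cat(sprintf("  muscles: %s\n", paste(x$muscles$name, collapse = ", ")))
  invisible(x)
}

#' Arm state constructor
#'
#' @param q joint angles (rad, length 2)
#' @param qd joint velocities (rad/s, length 2)
#' @param a muscle activations (length 6, each in [0, 1])
#' @return an `arm_state` list
#' @export
arm_state <- function(q, qd = c(0, 0), a = rep(0, 6)) {
  stop_if(length(q) != 2 || length(qd) != 2 || length(a) != 6, "bad arm state dimensions")
  stop_if(any(a < -1e-12) || any(a > 1 + 1e-12), "activations must lie in [0, 1]")
  structure(list(q = as.numeric(q), qd = as.numeric(qd), a = clip01(as.numeric(a))),
            class = "arm_state")
}

#' Muscle path geometry at a posture
#'
#' Computes straight-line muscle lengths, lengthening velocities, and the
#' moment-arm matrix at joint angles `q`. Moment arms are the analytic
#' derivatives \eqn{R_{ij} = -\partial l_i / \partial q_j}; lengthening
#' velocity is \eqn{\dot l = -(R \dot q)}.
#'
#' @param q joint angles (rad)
#' @param model `arm_model`
#' @param qd joint velocities (rad/s)
#' @param use_l0 internal flag; when `FALSE` skips normalized quantities
#'   (used while bootstrapping optimal fiber lengths)
#' @return list with `lengths` (m), `velocities` (m/s, lengthening positive),
#'   `moment_arms` (6x2, m), and when available `lnorm` (l / l0)
#' @export
muscle_geometry <- function(q, model, qd = c(0, 0), use_l0 = TRUE) {
  gc <- model$geom_cache
  skel <- model$skeleton
  c1 <- cos(q[1]); s1 <- sin(q[1])
  c12 <- cos(q[1] + q[2]); s12 <- sin(q[1] + q[2])
  bx <- skel$base[1]; by <- skel$base[2]
  ex <- bx + skel$l1 * c1; ey <- by + skel$l1 * s1
  world <- function(P, fr) {
    # world coordinates of attachment points, vectorized over muscles
    px <- ifelse(fr == 0L, bx + P[1, ],
          ifelse(fr == 1L, bx + c1 * P[1, ] - s1 * P[2, ],
                           ex + c12 * P[1, ] - s12 * P[2, ]))
    py <- ifelse(fr == 0L, by + P[2, ],
          ifelse(fr == 1L, by + s1 * P[1, ] + c1 * P[2, ],
                           ey + s12 * P[1, ] + c12 * P[2, ]))
    rbind(px, py)
  }
  Porg <- world(gc$org, gc$forg)
  Pins <- world(gc$ins, gc$fins)
  dx <- Pins[1, ] - Porg[1, ]
  dy <- Pins[2, ] - Porg[2, ]
  lengths <- sqrt(dx^2 + dy^2)
  stop_if(any(lengths < 1e-9), "degenerate zero-length muscle path")
  ux <- dx / lengths; uy <- dy / lengths
  # dP/dq1 = rot90(P - base) when the point sits on a moving segment;
  # dP/dq2 = rot90(P - elbow) when it sits on the forearm
  dq1 <- function(P, fr) {
    on <- fr >= 1L
    rbind(ifelse(on, -(P[2, ] - by), 0), ifelse(on, P[1, ] - bx, 0))
  }
  dq2 <- function(P, fr) {
    on <- fr == 2L
    rbind(ifelse(on, -(P[2, ] - ey), 0), ifelse(on, P[1, ] - ex, 0))
  }
  d1 <- dq1(Pins, gc$fins) - dq1(Porg, gc$forg)
  d2 <- dq2(Pins, gc$fins) - dq2(Porg, gc$forg)
  # dl/dq_j = u . (dPins/dq_j - dPorg/dq_j); moment arm is its negative
  R <- cbind(-(ux * d1[1, ] + uy * d1[2, ]),
             -(ux * d2[1, ] + uy * d2[2, ]))
  out <- list(lengths = lengths,
              velocities = as.numeric(-(R %*% qd)),
              moment_arms = R)
  if (use_l0 && !is.null(model$l0)) out$lnorm <- lengths / model$l0
  out
}

#' Active force-length scaling factor
#'
#' Gaussian bell centred on the optimal fiber length:
#' \eqn{f_l = \exp(-((l/l_0 - 1)/w)^2)}.
#'
#' @param lnorm normalized fiber length l / l0 (dimensionless, > 0)
#' @param width bell width w (dimensionless)
#' @return scalar(s) in (0, 1]
#' @export
force_length <- function(lnorm, width = 0.4) {
  stop_if(any(lnorm <= 0), "normalized length must be positive")
  exp(-((lnorm - 1) / width)^2)
}

#' Force-velocity scaling factor
#'
#' Hill hyperbola on the shortening side (`vnorm` in [-1, 0], zero force at
#' the maximal shortening velocity) joined C1-continuously to a saturating
#' eccentric branch that plateaus at `fv_max` for fast lengthening.
#' `vnorm` is the lengthening velocity normalized by the maximal shortening
#' velocity (negative = shortening).
#'
#' @param vnorm normalized lengthening velocity v / v_max
#' @param fv_max eccentric plateau (dimensionless)
#' @param k shortening curvature constant (dimensionless)
#' @return non-negative scalar(s), non-decreasing in `vnorm`
#' @export
force_velocity <- function(vnorm, fv_max = 1.5, k = 0.25) {
  slope0 <- 1 + 1 / k   # concentric-side slope at vnorm = 0
  ifelse(vnorm <= 0,
         pmax(0, (1 + vnorm) / (1 - vnorm / k)),
         fv_max - (fv_max - 1) * exp(-slope0 * vnorm / (fv_max - 1)))
}

#' Muscle activation dynamics
#'
#' First-order excitation-to-activation dynamics with activation-dependent
#' rates: activation is fast (time constant `tau_act`, accelerated at low
#' activation) and deactivation slower (`tau_deact`).
#'
#' @param a activation (in [0, 1], length 6 or scalar)
#' @param e neural excitation (in [0, 1], same length)
#' @param tau_act,tau_deact activation / deactivation time constants (s)
#' @return da/dt (1/s)
#' @export
activation_rate <- function(a, e, tau_act = 0.015, tau_deact = 0.050) {
  ifelse(e > a,
         (e - a) / (tau_act * (0.5 + 1.5 * a)),
         (e - a) * (0.5 + 1.5 * a) / tau_deact)
}

#' Hill-type muscle forces
#'
#' \eqn{F_i = a_i f_l(l_i/l_{0,i}) f_v(\dot l_i / (v_{max} l_{0,i})) F_{max,i}}.
#' Forces are always non-negative (muscles pull only).
#'
#' @param state `arm_state`
#' @param model `arm_model`
#' @param geom optional precomputed `muscle_geometry` result
#' @return 6-vector of muscle forces (N)
#' @export
muscle_forces <- function(state, model, geom = NULL) {
  if (is.null(geom)) geom <- muscle_geometry(state$q, model, state$qd)
  fl <- force_length(geom$lengths / model$l0, model$fl_width)
  vnorm <- geom$velocities / (model$v_max * model$l0)
  fv <- force_velocity(vnorm, model$fv_max)
  pmax(0, state$a * fl * fv * model$geom_cache$fmax)
}

# Arm-level generalized inertia: the two links plus the point hand mass
# reflected through the Jacobian.
arm_mass_matrix <- function(model, q) {
  M <- twolink_mass_matrix(model$skeleton, q)
  if (model$hand_mass > 0) {
    J <- twolink_jacobian(model$skeleton, q)
    M <- M + model$hand_mass * crossprod(J)
  }
  M
}

# Arm-level velocity-product torques, including the hand-mass contribution
# (m_h J' (dJ/dt) qd).
arm_velocity_torques <- function(model, q, qd) {
  cv <- twolink_velocity_torques(model$skeleton, q, qd)
  if (model$hand_mass > 0) {
    J <- twolink_jacobian(model$skeleton, q)
    cv <- cv + model$hand_mass *
      as.numeric(t(J) %*% twolink_jdot_qd(model$skeleton, q, qd))
  }
  cv
}

# Kinetic energy of the arm including the hand mass.
arm_kinetic_energy <- function(model, q, qd) {
  as.numeric(0.5 * t(qd) %*% arm_mass_matrix(model, q) %*% qd)
}

#' Arm joint accelerations
#'
#' Rigid-body dynamics of the two-link arm (including the point hand mass)
#' driven by muscle forces through the moment-arm matrix and an optional
#' external force at the hand.
#'
#' @param state `arm_state`
#' @param forces 6-vector of muscle forces (N)
#' @param model `arm_model`
#' @param hand_force external force applied at the hand (N, world frame)
#' @param geom optional precomputed `muscle_geometry` result
#' @return joint accelerations (rad/s^2)
#' @export
arm_dynamics <- function(state, forces, model, hand_force = c(0, 0), geom = NULL) {
  if (is.null(geom)) geom <- muscle_geometry(state$q, model, state$qd)
  J <- twolink_jacobian(model$skeleton, state$q)
  tau <- as.numeric(t(geom$moment_arms) %*% forces) +
    as.numeric(t(J) %*% hand_force)
  rhs <- tau - arm_velocity_torques(model, state$q, state$qd)
  as.numeric(solve(arm_mass_matrix(model, state$q), rhs))
}

#' Hand position and velocity
#'
#' @param q joint angles (rad)
#' @param qd joint velocities (rad/s)
#' @param model `arm_model`
#' @return list with `pos` and `vel` (m, m/s, world frame)
#' @export
forward_kinematics <- function(q, qd = c(0, 0), model) {
  fk <- twolink_fk(model$skeleton, q, qd)
  list(pos = fk$pos, vel = fk$vel)
}

#' Hand Jacobian
#'
#' @param q joint angles (rad)
#' @param model `arm_model`
#' @return 2x2 Jacobian (m/rad)
#' @export
hand_jacobian <- function(q, model) {
  twolink_jacobian(model$skeleton, q)
}

# Isometric statics map: hand force produced by activations `a` at posture q
# with fv = 1 (no movement). Returns the 2-vector hand force; `Phi` gives the
# full 2x6 linear map when requested.
arm_statics_map <- function(q, model, a = NULL, return_matrix = FALSE, geom = NULL) {
  if (is.null(geom)) geom <- muscle_geometry(q, model)
  J <- twolink_jacobian(model$skeleton, q)
  stop_if(abs(det(J)) < 1e-8, "singular hand Jacobian at this posture")
  fl <- force_length(geom$lengths / model$l0, model$fl_width)
  # tau = R' diag(fl * Fmax) a ; hand force F solves J' F = tau
  Phi <- solve(t(J), t(geom$moment_arms * (fl * model$geom_cache$fmax)))
  if (return_matrix) return(Phi)
  as.numeric(Phi %*% a)
}
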