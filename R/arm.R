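#' Three-link planar arm model
#'
#' The documented substitute plant for the torque-correction benchmark: a
#' planar arm of three revolute joints moving in a vertical plane (gravity
#' along -y), with an optional point-mass payload at the end effector.
#' Link inertias default to uniform rods (`m L^2 / 12` about the COM).
#'
#' @param masses Link masses, kg.
#' @param lengths Link lengths, m.
#' @param coms Distance of each COM from the proximal joint, m.
#' @param inertias Link inertias about the COM, kg m^2.
#' @param payload Point mass at the end effector, kg.
#' @param gravity m/s^2.
#' @param base_angle Orientation (rad, from the +x axis) of the arm's zero
#'   configuration; the default hangs the chain vertically downward, so
#'   gravity provides a restoring torque around the working poses (the
#'   usual home pose of manipulator benchmarks).
#' @return List of class `cereb_arm`.
#' @export
planar_arm <- function(masses = c(2, 1.5, 1),
                       lengths = c(0.4, 0.4, 0.3),
                       coms = lengths / 2,
                       inertias = masses * lengths^2 / 12,
                       payload = 0, gravity = 9.81,
                       base_angle = -pi / 2) {
  stopifnot(length(masses) == 3, length(lengths) == 3)
  structure(list(masses = masses, lengths = lengths, coms = coms,
                 inertias = inertias, payload = payload, gravity = gravity,
                 base_angle = base_angle),
            class = "cereb_arm")
}

#' Inverse dynamics of the planar arm
#'
#' Joint torques for a prescribed motion, via the recursive Newton-Euler
#' algorithm (gravity included, friction excluded).
#'
#' @param arm A [planar_arm()].
#' @param q,qd,qdd Joint angles (rad), velocities, accelerations; vectors of
#'   length 3 or matrices with one row per time step.
#' @return Torques (N m), same shape as `q`.
#' @export
arm_inverse_dynamics <- function(arm, q, qd, qdd) {
  if (is.matrix(q)) {
    out <- t(vapply(seq_len(nrow(q)), function(i)
      cpp_arm_rnea(q[i, ], qd[i, ], qdd[i, ], unclass(arm)), numeric(3)))
    dimnames(out) <- dimnames(q)
    return(out)
  }
  cpp_arm_rnea(q, qd, qdd, unclass(arm))
}

#' Crude inverse dynamics (payload-blind feed-forward torques)
#'
#' The baseline controller computes torques for the desired motion from the
#' arm model *without* the payload; the resulting mismatch when the real
#' plant carries a load is what the cerebellar module must learn to
#' correct.
#'
#' @param arm The true arm (its payload is ignored).
#' @param q,qd,qdd Desired joint state (vectors or per-step matrices).
#' @return Feed-forward torques.
#' @export
crude_inverse_dynamics <- function(arm, q, qd, qdd) {
  crude <- arm
  crude$payload <- 0
  arm_inverse_dynamics(crude, q, qd, qdd)
}

#' Step the simulated plant forward
#'
#' Semi-implicit Euler integration of the arm's forward dynamics with
#' viscous joint friction, using internal substeps within each control
#' step.
#'
#' @param arm A [planar_arm()] (payload included).
#' @param state List with `q` and `qd` (length-3 each).
#' @param torque Applied joint torques (N m).
#' @param dt Control step, seconds.
#' @param friction Viscous coefficient, N m s.
#' @param n_substeps Internal substeps.
#' @return Updated state list.
#' @export
step_plant <- function(arm, state, torque, dt = 0.002, friction = 0.1,
                       n_substeps = 10) {
  stopifnot(all(is.finite(torque)), all(is.finite(state$q)))
  out <- cpp_arm_fd_step(state$q, state$qd, torque, unclass(arm), friction,
                         dt, as.integer(n_substeps))
  list(q = out$q, qd = out$qd)
}

#' Mechanical energy of the arm (audit oracle)
#'
#' Kinetic plus gravitational potential energy, computed directly from the
#' planar kinematics (independently of the Newton-Euler code paths).
#'
#' @param arm A [planar_arm()].
#' @param q,qd Joint angles and velocities.
#' @return List with `kinetic`, `potential`, `total` (J).
#' @export
arm_energy <- function(arm, q, qd) {
  th <- arm$base_angle + cumsum(q)
  w <- cumsum(qd)
  jx <- jy <- vx <- vy <- 0
  ke <- pe <- 0
  for (i in 1:3) {
    cx <- cos(th[i]); sx <- sin(th[i])
    # COM position and velocity (v = v_joint + w x r)
    rcx <- arm$coms[i] * cx; rcy <- arm$coms[i] * sx
    vcx <- vx - w[i] * rcy; vcy <- vy + w[i] * rcx
    ke <- ke + 0.5 * arm$masses[i] * (vcx^2 + vcy^2) +
      0.5 * arm$inertias[i] * w[i]^2
    pe <- pe + arm$masses[i] * arm$gravity * (jy + rcy)
    rx <- arm$lengths[i] * cx; ry <- arm$lengths[i] * sx
    vx <- vx - w[i] * ry; vy <- vy + w[i] * rx
    jx <- jx + rx; jy <- jy + ry
  }
  if (arm$payload > 0) {
    ke <- ke + 0.5 * arm$payload * (vx^2 + vy^2)
    pe <- pe + arm$payload * arm$gravity * jy
  }
  list(kinetic = ke, potential = pe, total = ke + pe)
}

#' Eight-shaped benchmark joint trajectory
#'
#' Desired joint state `Q_n(t) = A_n sin(phi(u) + C_n)` with composite
#' phase `phi(u) = -4 pi u^3 + 6 pi u^2`, `u = t / duration`: a smooth
#' 1 s figure-of-eight in joint space with zero initial and final joint
#' velocity (`phi'(0) = phi'(1) = 0`, `phi(1) = 2 pi`).
#'
#' @param t Time(s) within the trial, seconds (vectorized).
#' @param config List with `amplitudes` (rad), `phases` (rad, default
#'   `n * pi / 4`), `duration` (s).
#' @return List of matrices `q`, `qd`, `qdd` (rows = times, columns =
#'   joints).
#' @export
desired_joint_state <- function(t, config = trajectory_config()) {
  if (any(t < 0 | t > config$duration)) stop("t outside the trial")
  u <- t / config$duration
  phi <- -4 * pi * u^3 + 6 * pi * u^2
  dphi <- (-12 * pi * u^2 + 12 * pi * u) / config$duration
  ddphi <- (-24 * pi * u + 12 * pi) / config$duration^2
  A <- config$amplitudes; C <- config$phases
  q <- outer(phi, C, "+")
  list(q = sweep(sin(q), 2, A, "*"),
       qd = sweep(cos(q) * dphi, 2, A, "*"),
       qdd = sweep(-sin(q) * dphi^2 + cos(q) * ddphi, 2, A, "*"))
}

#' @rdname desired_joint_state
#' @param amplitudes Joint amplitudes `A_n`, rad.
#' @param duration Trial duration, seconds.
#' @export
trajectory_config <- function(amplitudes = c(0.4, 0.3, 0.2), duration = 1) {
  stopifnot(duration > 0)
  structure(list(amplitudes = amplitudes,
                 phases = seq_along(amplitudes) * pi / 4,
                 duration = duration),
            class = "trajectory_config")
}

#' Set-point reference curve
#'
#' The twin-Gaussian reference
#' `r(t) = exp(-(t - T/4)^2 / sigma_ref^2) - exp(-(t - 3T/4)^2 / sigma_ref^2)`,
#' antisymmetric about `T/2`: one positive and one negative lobe per
#' period, demanding balanced agonist/antagonist corrective action.
#'
#' @param t Time(s) in `[0, T]`, seconds.
#' @param config List with `sigma_ref` (s) and `period` (s).
#' @return Reference values.
#' @export
reference_variable <- function(t, config = reference_config()) {
  T <- config$period; s2 <- config$sigma_ref^2
  exp(-(t - T / 4)^2 / s2) - exp(-(t - 3 * T / 4)^2 / s2)
}

#' @rdname reference_variable
#' @param sigma_ref Gaussian width, s.
#' @param period Curve period `T`, s.
#' @export
reference_config <- function(sigma_ref = 0.1, period = 1) {
  stopifnot(sigma_ref > 0, sigma_ref < period)
  structure(list(sigma_ref = sigma_ref, period = period),
            class = "reference_config")
}
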