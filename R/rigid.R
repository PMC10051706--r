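#' Monte-Carlo mass properties of a union of spheres
#'
#' Rigid multi-sphere (CMS) clusters are unions of heavily overlapping
#' spheres, so volume, center of mass and inertia tensor are estimated by
#' uniform rejection sampling in the union's bounding box: a sample counts
#' once if it falls inside any sphere (union semantics, overlap is not double
#' counted).
#'
#' @param centers n x 3 matrix of sphere centers (m).
#' @param radii Length-n radii (m).
#' @param density Material density (kg/m^3).
#' @param n_samples Number of samples (>= 1e4; default 1e6).
#' @param seed Integer RNG seed (required, for reproducibility).
#' @return List with `volume` (m^3), `mass` (kg), `com` (3-vector), `inertia`
#'   (3x3 tensor about the com), `n_inside`, and `volume_se` (Monte-Carlo
#'   standard error of the volume).
#' @export
monte_carlo_mass_properties <- function(centers, radii, density,
                                        n_samples = 1e6, seed) {
  centers <- matrix(as.numeric(centers), ncol = 3)
  if (nrow(centers) == 0L) stop("no spheres supplied")
  if (n_samples < 1e4) stop("n_samples must be at least 1e4")
  if (missing(seed)) stop("an explicit seed is required")
  lo <- apply(centers - radii, 2, min)
  hi <- apply(centers + radii, 2, max)
  box_vol <- prod(hi - lo)

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))

  pts <- cbind(
    stats::runif(n_samples, lo[1], hi[1]),
    stats::runif(n_samples, lo[2], hi[2]),
    stats::runif(n_samples, lo[3], hi[3])
  )
  inside <- rep(FALSE, n_samples)
  for (k in seq_len(nrow(centers))) {
    d2 <- (pts[, 1] - centers[k, 1])^2 + (pts[, 2] - centers[k, 2])^2 +
      (pts[, 3] - centers[k, 3])^2
    inside <- inside | (d2 <= radii[k]^2)
  }
  n_in <- sum(inside)
  if (n_in == 0L) stop("no samples fell inside the union: degenerate geometry or too few samples")
  p <- n_in / n_samples
  volume <- box_vol * p
  volume_se <- box_vol * sqrt(p * (1 - p) / n_samples)
  mass <- density * volume
  pin <- pts[inside, , drop = FALSE]
  com <- colMeans(pin)
  rel <- sweep(pin, 2, com)
  r2 <- rowSums(rel^2)
  # inertia of the sampled point cloud, each point carrying mass/n_in
  ixx <- mean(r2 - rel[, 1]^2); iyy <- mean(r2 - rel[, 2]^2)
  izz <- mean(r2 - rel[, 3]^2)
  ixy <- -mean(rel[, 1] * rel[, 2]); ixz <- -mean(rel[, 1] * rel[, 3])
  iyz <- -mean(rel[, 2] * rel[, 3])
  inertia <- mass * matrix(c(
    ixx, ixy, ixz,
    ixy, iyy, iyz,
    ixz, iyz, izz
  ), 3, 3)
  list(
    volume = volume, mass = mass, com = com, inertia = inertia,
    n_inside = n_in, volume_se = volume_se
  )
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Aggregate member forces into a rigid-body force and torque
#'
#' The total force on a rigid cluster is the sum of the forces acting on its
#' member sub-spheres; the total torque about the center of mass adds each
#' contact's moment arm plus any member torques:
#' \deqn{F = \sum_k F_k, \qquad
#'       \tau = \sum_k (x_k - x_{com}) \times F_k + \tau_k.}
#'
#' @param com Center of mass (3-vector).
#' @param forces n x 3 matrix of member forces (N).
#' @param contact_points n x 3 matrix of application points (m).
#' @param torques Optional n x 3 matrix of member torques (N m).
#' @return List with `force` and `torque` (3-vectors).
#' @export
aggregate_force_torque <- function(com, forces, contact_points,
                                   torques = NULL) {
  forces <- matrix(as.numeric(forces), ncol = 3)
  contact_points <- matrix(as.numeric(contact_points), ncol = 3)
  f_tot <- colSums(forces)
  rel <- sweep(contact_points, 2, com)
  tau <- colSums(cbind(
    rel[, 2] * forces[, 3] - rel[, 3] * forces[, 2],
    rel[, 3] * forces[, 1] - rel[, 1] * forces[, 3],
    rel[, 1] * forces[, 2] - rel[, 2] * forces[, 1]
  ))
  if (!is.null(torques)) tau <- tau + colSums(matrix(as.numeric(torques), ncol = 3))
  list(force = f_tot, torque = tau)
}

quat_normalize <- function(q) q / sqrt(sum(q^2))

quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

quat_mult <- function(a, b) {
  c(
    a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1]
  )
}

#' Rigid-body state for a CMS cluster
#'
#' @param com Center of mass (m).
#' @param vel Center-of-mass velocity (m/s).
#' @param quat Orientation unit quaternion (w, x, y, z); identity by default.
#' @param omega_body Angular velocity in the body (principal) frame (rad/s).
#' @param offsets n x 3 member offsets in the body frame (m).
#' @param radii Member radii (m).
#' @param mass Total mass (kg).
#' @param inertia_body Principal moments (length-3) or 3x3 body-frame inertia.
#' @return List of class `mcdem_rigid_state`.
#' @export
rigid_state <- function(com, vel = c(0, 0, 0), quat = c(1, 0, 0, 0),
                        omega_body = c(0, 0, 0), offsets, radii, mass,
                        inertia_body) {
  if (is.matrix(inertia_body)) {
    ev <- eigen(inertia_body, symmetric = TRUE)
    # rotate offsets into the principal frame
    offsets <- as.matrix(offsets) %*% ev$vectors
    inertia_body <- ev$values
    quat <- quat_normalize(quat)
  }
  structure(
    list(
      com = com, vel = vel, quat = quat_normalize(quat),
      omega_body = omega_body, offsets = as.matrix(offsets),
      radii = radii, mass = mass, inertia_body = as.numeric(inertia_body)
    ),
    class = "mcdem_rigid_state"
  )
}

#' Advance a rigid body one timestep
#'
#' Velocity-Verlet translation of the center of mass plus a leapfrog
#' quaternion scheme for the rotation: Euler's equations are integrated in the
#' body frame and the quaternion advanced with the mid-step angular velocity,
#' then renormalized. Member sub-sphere positions are recomputed exactly from
#' the body-frame offsets, so intra-body distances are preserved to rounding.
#'
#' The force and torque are treated as constant over the step (gather them
#' from the contact evaluation at the current configuration).
#'
#' @param state An `mcdem_rigid_state`.
#' @param force Total force on the body (N, world frame).
#' @param torque Total torque about the com (N m, world frame).
#' @param dt Timestep (s).
#' @return Updated state; member world positions are available via
#'   [rigid_member_positions()].
#' @export
rigid_body_step <- function(state, force, torque, dt) {
  if (any(!is.finite(force)) || any(!is.finite(torque))) {
    stop("non-finite force/torque on rigid body")
  }
  acc <- force / state$mass
  state$com <- state$com + state$vel * dt + 0.5 * acc * dt^2
  state$vel <- state$vel + acc * dt

  ib <- state$inertia_body
  rot <- quat_to_matrix(state$quat)
  tau_b <- drop(t(rot) %*% torque)
  w <- state$omega_body
  # half-kick in the body frame (Euler's equations)
  wd <- (tau_b - cross3(w, ib * w)) / ib
  w_half <- w + 0.5 * dt * wd
  # rotate quaternion with the half-step body-frame angular velocity
  wmag <- sqrt(sum(w_half^2))
  if (wmag > 0) {
    axis <- w_half / wmag
    ang <- wmag * dt / 2
    dq <- c(cos(ang), sin(ang) * axis)
    state$quat <- quat_normalize(quat_mult(state$quat, dq))
  }
  # second half-kick with the torque re-expressed in the new body frame
  rot2 <- quat_to_matrix(state$quat)
  tau_b2 <- drop(t(rot2) %*% torque)
  wd2 <- (tau_b2 - cross3(w_half, ib * w_half)) / ib
  state$omega_body <- w_half + 0.5 * dt * wd2
  state
}

#' World-frame member positions of a rigid body
#' @param state An `mcdem_rigid_state`.
#' @return n x 3 matrix of member centers.
#' @export
rigid_member_positions <- function(state) {
  rot <- quat_to_matrix(state$quat)
  sweep(state$offsets %*% t(rot), 2, state$com, `+`)
}

#' Kinetic energy and angular momentum of a rigid body
#' @param state An `mcdem_rigid_state`.
#' @return List with `kinetic` (J) and `angular_momentum` (world frame, kg m^2/s).
#' @export
rigid_conserved <- function(state) {
  ib <- state$inertia_body
  w <- state$omega_body
  rot <- quat_to_matrix(state$quat)
  list(
    kinetic = 0.5 * state$mass * sum(state$vel^2) + 0.5 * sum(ib * w^2),
    angular_momentum = drop(rot %*% (ib * w)) +
      state$mass * cross3(state$com, state$vel)
  )
}
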