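#' Contact geometry between two spheres
#'
#' Computes the kinematic quantities a pair force law needs from the state of
#' two spheres. The contact normal points from sphere j to sphere i.
#'
#' @param x_i,x_j Sphere centers (length-3 numeric).
#' @param r_i,r_j Radii (m).
#' @param v_i,v_j Translational velocities (m/s).
#' @param w_i,w_j Angular velocities (rad/s).
#' @return A list of class `mcdem_contact_geometry` with `normal` (unit,
#'   j to i), `overlap_n`, `rel_velocity_n` (the scalar approach rate
#'   d(delta_n)/dt, positive while closing), `rel_velocity_t` (3-vector,
#'   perpendicular to the normal) and `contact_point` (midpoint of the overlap
#'   region). `overlap_n < 0` means no contact.
#' @export
contact_geometry <- function(x_i, x_j, r_i, r_j,
                             v_i = c(0, 0, 0), v_j = c(0, 0, 0),
                             w_i = c(0, 0, 0), w_j = c(0, 0, 0)) {
  d <- x_i - x_j
  dist <- sqrt(sum(d^2))
  if (dist == 0) stop("coincident sphere centers: contact normal undefined")
  n <- d / dist
  overlap <- r_i + r_j - dist
  cp <- x_i - (r_i - overlap / 2) * n
  # velocity of the material points at the contact
  v_ci <- v_i + cross3(w_i, cp - x_i)
  v_cj <- v_j + cross3(w_j, cp - x_j)
  v_rel <- v_ci - v_cj
  vn <- sum((v_i - v_j) * n)     # center approach rate: -d(dist)/dt
  vt <- v_rel - sum(v_rel * n) * n
  structure(
    list(
      normal = n, overlap_n = overlap,
      rel_velocity_n = -vn, rel_velocity_t = vt, contact_point = cp
    ),
    class = "mcdem_contact_geometry"
  )
}

# note: rel_velocity_n is d(delta_n)/dt = -(d/dt)|x_i - x_j|, POSITIVE while
# the spheres approach, so `+ gamma_n * rel_velocity_n` stiffens the contact
# on approach and softens it on rebound (dissipative both ways).

cross3 <- function(a, b) {
  c(
    a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1]
  )
}

#' Hertzian normal contact force
#'
#' \deqn{F_n = k_n \delta_n^{3/2} + \gamma_n \dot\delta_n}
#' with \eqn{k_n = \frac{4}{3} E^* \sqrt{R^*}}, applied along the contact
#' normal on sphere i. The damping term uses the approach rate
#' \eqn{\dot\delta_n > 0} while the spheres close, so damping opposes the
#' relative motion. The total is clamped at zero: the Hertz law carries no
#' tension.
#'
#' @param geom An `mcdem_contact_geometry` (its `rel_velocity_n` is
#'   d(delta_n)/dt, positive while the spheres approach).
#' @param pair An `mcdem_pair`.
#' @param restitution Coefficient of restitution used to derive the damping
#'   coefficient; 1 (default) gives the undamped Hertz force.
#' @return Force 3-vector acting on sphere i (N). Zero when `overlap_n <= 0`.
#' @examples
#' m <- default_materials()$rubber
#' p <- effective_pair_properties(m, m, 0.01, 0.01)
#' g <- contact_geometry(c(0, 0, 0.0199), c(0, 0, 0), 0.01, 0.01)
#' hertz_normal_force(g, p)  # ~35 N at 1 mm overlap
#' @export
hertz_normal_force <- function(geom, pair, restitution = 1) {
  if (geom$overlap_n <= 0) return(c(0, 0, 0))
  gam <- damping_coefficients(pair, restitution, geom$overlap_n)[["gamma_n"]]
  fn <- pair$normal_stiffness * geom$overlap_n^1.5 +
    gam * geom$rel_velocity_n
  if (fn < 0) fn <- 0
  fn * geom$normal
}

#' Tangential (Mindlin) contact force with Coulomb cap
#'
#' Elastic tangential force from the accumulated tangential spring, plus
#' viscous damping, capped by Coulomb friction \eqn{|F_t| \le \mu |F_n|}.
#' Two stiffness variants are supported:
#' * `"mindlin"` (default): \eqn{F_t = -k_t(\delta_n)\,\xi} with the no-slip
#'   Mindlin stiffness \eqn{k_t = 8 G^* \sqrt{R^* \delta_n}} (linear in the
#'   spring \eqn{\xi}).
#' * `"as_printed"`: \eqn{|F_t| = k_t |\xi|^{3/2}} with
#'   \eqn{k_t = 8 G^* \sqrt{R^*}} (a 3/2 power law in the accumulated
#'   tangential displacement).
#'
#' When the cap binds, the returned force sits exactly on the friction cone
#' and the stored spring is rescaled so that the elastic force alone equals
#' the cap (prevents wind-up).
#'
#' @param geom An `mcdem_contact_geometry`.
#' @param hist Tangential history: a list with `spring` (3-vector, metres).
#'   Use [tangential_history()] to create an empty one.
#' @param pair An `mcdem_pair`.
#' @param normal_force_mag Magnitude of the current normal force (N).
#' @param mu Sliding friction coefficient.
#' @param dt Timestep used to advance the spring by `rel_velocity_t * dt` (s).
#'   `dt = 0` evaluates the force for the stored spring without advancing it.
#' @param restitution Restitution used for the tangential damping coefficient.
#' @param law `"mindlin"` or `"as_printed"`.
#' @return List with `force` (3-vector on sphere i) and `hist` (updated
#'   history, spring projected onto the current tangent plane and rescaled if
#'   sliding).
#' @export
tangential_force <- function(geom, hist, pair, normal_force_mag, mu,
                             dt = 0, restitution = 1,
                             law = c("mindlin", "as_printed")) {
  law <- match.arg(law)
  n <- geom$normal
  s <- hist$spring
  s <- s - sum(s * n) * n                 # rotate into current tangent plane
  s <- s + geom$rel_velocity_t * dt
  if (normal_force_mag <= 0) {
    hist$spring <- c(0, 0, 0)
    return(list(force = c(0, 0, 0), hist = hist))
  }
  smag <- sqrt(sum(s^2))
  if (law == "mindlin") {
    kt <- pair$tangential_stiffness_coeff * sqrt(geom$overlap_n)
    f_el <- -kt * s
  } else {
    kt <- pair$tangential_stiffness_coeff
    f_el <- if (smag > 0) -kt * smag^1.5 * (s / smag) else c(0, 0, 0)
  }
  gam <- damping_coefficients(pair, restitution, geom$overlap_n)[["gamma_t"]]
  f <- f_el - gam * geom$rel_velocity_t
  fmag <- sqrt(sum(f^2))
  cap <- mu * normal_force_mag
  if (fmag > cap) {
    f <- f * (cap / fmag)
    # rescale the spring so the elastic force alone sits on the cone
    if (law == "mindlin") {
      if (kt > 0) s <- -f / kt
    } else if (smag > 0 && kt > 0) {
      s <- -(cap / kt)^(2 / 3) * f / cap
    }
  }
  hist$spring <- s
  list(force = f, hist = hist)
}

#' Empty tangential contact history
#' @return A list with a zero `spring` vector.
#' @export
tangential_history <- function() list(spring = c(0, 0, 0))

#' Constant-directional-torque rolling friction
#'
#' \deqn{\tau = -\frac{\omega_{rel}}{|\omega_{rel}|}\,\mu_r R^* |F_n|}
#' with \eqn{\omega_{rel} = \omega_i - \omega_j}; the torque on sphere j is
#' equal and opposite. Below `tol` relative angular velocity the torque is
#' zero (the prefactor is undefined at zero).
#'
#' @param omega_i,omega_j Angular velocities (rad/s).
#' @param mu_r Rolling friction coefficient.
#' @param pair An `mcdem_pair` (supplies R*).
#' @param normal_force_mag Magnitude of the normal force (N).
#' @param tol Cutoff on `|omega_rel|` (rad/s).
#' @return Torque 3-vector acting on sphere i (N m).
#' @export
rolling_torque <- function(omega_i, omega_j, mu_r, pair, normal_force_mag,
                           tol = 1e-12) {
  w <- omega_i - omega_j
  wmag <- sqrt(sum(w^2))
  if (wmag < tol || normal_force_mag <= 0 || mu_r <= 0) return(c(0, 0, 0))
  -(w / wmag) * mu_r * pair$eff_radius * normal_force_mag
}
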