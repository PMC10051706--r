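#' Simulation domain
#'
#' Axis-aligned box with optional periodic axes. Pair geometry across periodic
#' axes uses the minimum-image convention.
#'
#' @param lo,hi Length-3 lower/upper corners (m).
#' @param periodic Logical length-3: which axes wrap.
#' @return List of class `mcdem_domain`.
#' @export
sim_domain <- function(lo = c(-1, -1, -1), hi = c(1, 1, 1),
                       periodic = c(FALSE, FALSE, FALSE)) {
  stopifnot(length(lo) == 3, length(hi) == 3, all(hi > lo))
  structure(list(lo = as.numeric(lo), hi = as.numeric(hi),
                 periodic = as.logical(periodic)),
            class = "mcdem_domain")
}

#' Plane wall
#'
#' An infinite plane with its unit normal pointing toward the particles. A
#' moving plate is modelled by a constant `velocity`; the plane's reference
#' point translates with it every step. Contact reactions are accumulated per
#' wall and reported in the run records.
#'
#' @param normal Unit normal (toward the interior).
#' @param point Any point on the plane (m).
#' @param velocity Plate velocity (m/s).
#' @param material 1-based index into the state's material list.
#' @return List of class `mcdem_wall`.
#' @export
plane_wall <- function(normal, point, velocity = c(0, 0, 0), material = 1) {
  n <- as.numeric(normal)
  n <- n / sqrt(sum(n^2))
  structure(list(normal = n, point = as.numeric(point),
                 velocity = as.numeric(velocity),
                 material = as.integer(material)),
            class = "mcdem_wall")
}

#' Contact model selection
#'
#' @param normal `"hertz"` (nonlinear elastic spring-dashpot) or
#'   `"elastoplastic"` (three-branch adhesive elastic-plastic law with the
#'   non-local stress term).
#' @param tangential_law `"mindlin"` (linear no-slip Mindlin spring, default)
#'   or `"as_printed"` (3/2-power tangential law).
#' @param f0 Pull-off force (N), elastoplastic only.
#' @param k1_scale Multiplier on the Young's-modulus-derived loading stiffness
#'   k1 (the calibration knob: the loading stiffness need not be tied to the
#'   elastic modulus).
#' @param k2_ratio k2/k1 (>= 1).
#' @param kc_ratio kc/k1 (>= 0).
#' @param beta Non-local prefactor.
#' @return List of class `mcdem_model`.
#' @export
contact_model <- function(normal = c("hertz", "elastoplastic"),
                          tangential_law = c("mindlin", "as_printed"),
                          f0 = 0, k1_scale = 1, k2_ratio = 5,
                          kc_ratio = 0, beta = 0) {
  normal <- match.arg(normal)
  tangential_law <- match.arg(tangential_law)
  structure(
    list(
      normal = normal, tangential_law = tangential_law,
      ep = list(f0 = f0, k1_scale = k1_scale, k2_ratio = k2_ratio,
                kc_ratio = kc_ratio, beta = beta)
    ),
    class = "mcdem_model"
  )
}

#' Friction/restitution tables for a material list
#'
#' Builds the per-material-pair coefficient matrices. By default each entry is
#' the geometric mean of the two materials' coefficients; individual pairs can
#' be overridden.
#'
#' @param materials List of `mcdem_material`.
#' @param what One of "sliding_friction", "rolling_friction", "restitution".
#' @return Symmetric matrix.
#' @export
pair_table <- function(materials,
                       what = c("sliding_friction", "rolling_friction",
                                "restitution")) {
  what <- match.arg(what)
  vals <- vapply(materials, `[[`, numeric(1), what)
  sqrt(outer(vals, vals))
}

#' Assemble a DEM state
#'
#' The state is the full input of one engine run: sphere kinematics, body
#' structure, bonds, walls, domain, materials and model. It is advanced by
#' [dem_run()], which returns the updated state plus time-series records.
#'
#' @param x N x 3 sphere centers (m).
#' @param r Radii (m).
#' @param materials List of `mcdem_material` (walls index into the same list).
#' @param material_id Length-N 1-based material index (default all 1).
#' @param v,w Velocities / angular velocities (N x 3, default zero).
#' @param mass Per-sphere masses; default solid-sphere from density.
#' @param body Length-N body id (0 = free sphere).
#' @param body_kind Per body id: 1 = BMS (deformable), 2 = CMS (rigid).
#' @param cms List of rigid-body descriptors (see [make_cms_body()]).
#' @param bonds Bond table from [create_bonds()].
#' @param bond_pars An `mcdem_bond_params` (required when bonds are present).
#' @param walls List of [plane_wall()].
#' @param domain An [sim_domain()].
#' @param gravity 3-vector (m/s^2).
#' @param model An [contact_model()].
#' @param pair_mu,pair_mur,pair_cor Optional explicit pair coefficient
#'   matrices; default via [pair_table()].
#' @return List of class `mcdem_state`.
#' @export
dem_state <- function(x, r, materials, material_id = NULL, v = NULL, w = NULL,
                      mass = NULL, body = NULL, body_kind = integer(),
                      cms = list(), bonds = NULL, bond_pars = NULL,
                      walls = list(), domain = sim_domain(),
                      gravity = c(0, 0, 0),
                      model = contact_model("hertz"),
                      pair_mu = NULL, pair_mur = NULL, pair_cor = NULL) {
  x <- matrix(as.numeric(x), ncol = 3)
  n <- nrow(x)
  r <- rep_len(as.numeric(r), n)
  if (is.null(material_id)) material_id <- rep(1L, n)
  if (is.null(v)) v <- matrix(0, n, 3)
  if (is.null(w)) w <- matrix(0, n, 3)
  if (is.null(mass)) {
    dens <- vapply(materials, `[[`, numeric(1), "density")
    mass <- dens[material_id] * 4 / 3 * pi * r^3
  }
  if (is.null(body)) body <- rep(0L, n)
  if (is.null(bonds)) bonds <- empty_bond_table()
  if (nrow(bonds) > 0 && is.null(bond_pars)) {
    stop("bond_pars required when bonds are present")
  }
  if (is.null(bond_pars)) bond_pars <- bond_params(1, 1, 1, 0)
  if (is.null(pair_mu)) pair_mu <- pair_table(materials, "sliding_friction")
  if (is.null(pair_mur)) pair_mur <- pair_table(materials, "rolling_friction")
  if (is.null(pair_cor)) pair_cor <- pair_table(materials, "restitution")
  pair_damp <- apply(pair_cor, c(1, 2), cor_damping_coefficient)
  structure(
    list(
      x = x, v = matrix(as.numeric(v), ncol = 3),
      w = matrix(as.numeric(w), ncol = 3),
      r = r, m = rep_len(as.numeric(mass), n),
      mat = as.integer(material_id), body = as.integer(body),
      body_kind = as.integer(body_kind), cms = cms,
      bonds = bonds,
      bond_params = unclass(bond_pars),
      walls = lapply(walls, unclass),
      domain = unclass(domain), gravity = as.numeric(gravity),
      materials = lapply(materials, unclass),
      pair_mu = pair_mu, pair_mur = pair_mur, pair_cor = pair_cor,
      pair_damp = pair_damp,
      model = unclass(model),
      history = list(i = integer(), j = integer(), sx = numeric(),
                     sy = numeric(), sz = numeric(), d0 = numeric()),
      pressures = rep(0, n), time = 0
    ),
    class = "mcdem_state"
  )
}

#' Rigid (CMS) body descriptor
#'
#' Computes mass properties by Monte-Carlo sampling of the sphere union and
#' returns the descriptor consumed by [dem_state()]. Offsets are expressed in
#' the principal (body) frame.
#'
#' @param members 1-based indices of the member spheres in the state.
#' @param centers n x 3 member centers (m, world frame at creation).
#' @param radii Member radii.
#' @param density Material density (kg/m^3).
#' @param body_id The body id shared by the members.
#' @param n_samples Monte-Carlo samples.
#' @param seed RNG seed for the Monte-Carlo estimate.
#' @param vel,omega Initial com velocity / body-frame angular velocity.
#' @param fix_rotation,fix_lateral Constrain the body like a guided
#'   compression rig: suppress tumbling and/or lateral center-of-mass motion.
#'   A rigid bumpy cluster squeezed between frictional plates is dynamically
#'   unstable to rolling ejection; the single-particle compression protocol
#'   holds it in place.
#' @return List consumed by the engine (members, offsets, mass, inertia,
#'   quat, com, vcom, omega_body, body_id).
#' @export
make_cms_body <- function(members, centers, radii, density, body_id,
                          n_samples = 2e5, seed = 1,
                          vel = c(0, 0, 0), omega = c(0, 0, 0),
                          fix_rotation = FALSE, fix_lateral = FALSE) {
  mp <- monte_carlo_mass_properties(centers, radii, density,
                                    n_samples = n_samples, seed = seed)
  ev <- eigen(mp$inertia, symmetric = TRUE)
  axes <- ev$vectors
  if (det(axes) < 0) axes[, 3] <- -axes[, 3]
  offsets <- sweep(matrix(centers, ncol = 3), 2, mp$com) %*% axes
  # quaternion of the rotation matrix `axes` (body->world)
  q <- matrix_to_quat(axes)
  list(
    members = as.integer(members), offsets = offsets,
    mass = mp$mass, inertia = ev$values, quat = q,
    com = mp$com, vcom = as.numeric(vel), omega_body = as.numeric(omega),
    body_id = as.integer(body_id),
    fix_rotation = fix_rotation, fix_lateral = fix_lateral
  )
}

matrix_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    k <- which.max(c(R[1, 1], R[2, 2], R[3, 3]))
    if (k == 1) {
      s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
      q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
             (R[1, 3] + R[3, 1]) / s)
    } else if (k == 2) {
      s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
      q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
             (R[2, 3] + R[3, 2]) / s)
    } else {
      s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
      q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
             (R[2, 3] + R[3, 2]) / s, 0.25 * s)
    }
  }
  q / sqrt(sum(q^2))
}

#' Advance a DEM state
#'
#' Velocity-Verlet time integration with per-step force evaluation: free and
#' BMS sub-spheres receive translational and spin updates; CMS bodies are
#' integrated as rigid bodies (quaternion leapfrog); walls translate with
#' their velocities; positions wrap across periodic axes. Contact histories
#' (tangential springs, plastic overlaps) and the lagged per-particle
#' pressures persist inside the state across calls.
#'
#' @param state An `mcdem_state`.
#' @param dt Timestep (s); see [critical_timestep()].
#' @param n_steps Number of steps.
#' @param record_every Record the time series every this many steps
#'   (0 = no records).
#' @param neighbor `"cell"` (linked-cell search) or `"brute"` (all pairs).
#'   Both produce identical trajectories.
#' @return List with `state` (advanced copy) and `records`: `time`, `ke`
#'   (total kinetic energy, J), `wall_force` (n_rec x n_walls x 3 array, N)
#'   and `wall_point` (same shape; a point on each wall, m).
#' @export
dem_run <- function(state, dt, n_steps, record_every = 0,
                    neighbor = c("cell", "brute")) {
  neighbor <- match.arg(neighbor)
  out <- cpp_dem_run(state, dt, as.integer(n_steps),
                     as.integer(record_every), neighbor == "cell")
  state$x <- out$x
  state$v <- out$v
  state$w <- out$w
  if (nrow(state$bonds) > 0) {
    state$bonds$ox <- out$bond_offsets$ox
    state$bonds$oy <- out$bond_offsets$oy
    state$bonds$oz <- out$bond_offsets$oz
  }
  state$history <- out$history
  state$cms <- out$cms
  state$walls <- out$walls
  state$pressures <- out$pressures
  state$stress <- out$stress
  state$forces <- out$forces
  state$wall_forces <- out$wall_forces
  state$time <- out$time
  nw <- length(state$walls)
  n_rec <- length(out$rec_time)
  records <- list(
    time = out$rec_time, ke = out$rec_ke,
    wall_force = if (nw > 0 && n_rec > 0) {
      array(out$rec_wall_force[, seq_len(3 * nw), drop = FALSE],
            dim = c(n_rec, 3, nw))
    },
    wall_point = if (nw > 0 && n_rec > 0) {
      array(out$rec_wall_point[, seq_len(3 * nw), drop = FALSE],
            dim = c(n_rec, 3, nw))
    }
  )
  list(state = state, records = records)
}

#' Candidate neighbor pairs
#'
#' All sphere pairs whose surface gap is below `skin` (a superset of the true
#' contacts), with minimum-image geometry across periodic axes. The
#' linked-cell search and the brute-force scan return the identical, sorted
#' pair list.
#'
#' @param x N x 3 centers.
#' @param r Radii.
#' @param domain An [sim_domain()].
#' @param skin Search skin (m); default 0.2 x smallest radius.
#' @param method `"cell"` or `"brute"`.
#' @return 2-column integer matrix of 1-based pairs (i < j), sorted.
#' @export
neighbor_pairs <- function(x, r, domain = sim_domain(),
                           skin = 0.2 * min(r),
                           method = c("cell", "brute")) {
  method <- match.arg(method)
  x <- matrix(as.numeric(x), ncol = 3)
  if (nrow(x) == 0) return(matrix(integer(), ncol = 2))
  cpp_neighbor_pairs(x, rep_len(as.numeric(r), nrow(x)),
                     domain$lo, domain$hi, domain$periodic,
                     skin, method == "cell")
}

#' Critical (Rayleigh) timestep
#'
#' Rayleigh surface-wave time of the smallest, stiffest sphere:
#' \deqn{t_R = \frac{\pi r \sqrt{\rho / G}}{0.1631\,\nu + 0.8766},}
#' the stability bound of explicit DEM integration. The returned timestep is
#' `safety_factor * min(t_R)`.
#'
#' @param r Radii (m).
#' @param materials List of `mcdem_material`.
#' @param material_id Per-sphere material index (default all 1).
#' @param safety_factor Fraction of the Rayleigh time (default 0.15).
#' @return Timestep (s).
#' @export
critical_timestep <- function(r, materials, material_id = NULL,
                              safety_factor = 0.15) {
  if (length(r) == 0) stop("at least one sphere required")
  if (inherits(materials, "mcdem_material")) materials <- list(materials)
  if (is.null(material_id)) material_id <- rep(1L, length(r))
  tr <- vapply(seq_along(r), function(i) {
    mat <- materials[[material_id[i]]]
    g <- shear_modulus(mat)
    pi * r[i] * sqrt(mat$density / g) /
      (0.1631 * mat$poisson_ratio + 0.8766)
  }, numeric(1))
  safety_factor * min(tr)
}

#' Static wall contact forces
#'
#' Evaluates the contact forces of the current configuration (a zero-step
#' engine evaluation) and returns per-sphere forces plus the accumulated
#' reaction on every wall.
#'
#' @param state An `mcdem_state`.
#' @return List with `forces` (N x 3), `wall_forces` (n_walls x 3) and
#'   `pressures`.
#' @export
wall_contact_forces <- function(state) {
  out <- dem_run(state, dt = 1e-12, n_steps = 0)
  nw <- length(state$walls)
  list(
    forces = out$state$forces,
    wall_forces = if (nw > 0) {
      matrix(out$state$wall_forces, nrow = nw, ncol = 3, byrow = TRUE)
    } else {
      matrix(numeric(), ncol = 3)
    },
    pressures = out$state$pressures
  )
}

#' Axial stress on a plate
#'
#' @param wall_reaction Reaction force on the plate (3-vector or magnitude of
#'   its normal component, N).
#' @param normal Plate normal (used when a 3-vector reaction is given).
#' @param cross_section Die cross-section area (m^2).
#' @return Stress (Pa).
#' @export
measure_axial_stress <- function(wall_reaction, cross_section,
                                 normal = c(0, 0, 1)) {
  if (cross_section <= 0) stop("cross-section must be positive")
  f <- if (length(wall_reaction) == 3) {
    abs(sum(wall_reaction * normal))
  } else {
    abs(wall_reaction)
  }
  f / cross_section
}
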