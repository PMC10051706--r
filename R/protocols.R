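#' Build a rigid (CMS) multi-sphere ball representation
#'
#' Greedy largest-inscribed-sphere filling of a solid ball: interior grid
#' points are ranked by their distance to the surface, and spheres (radius =
#' that distance, so each touches the surface from inside) are placed at the
#' best uncovered point until `target_count` spheres exist. Overlaps are
#' allowed -- the cluster is rigid. Different counts give different surface
#' bumpiness, which is exactly what the CMS sensitivity study probes.
#'
#' @param radius Ball radius (m).
#' @param target_count Number of sub-spheres.
#' @param material An `mcdem_material`.
#' @param n_grid Grid points across the diameter (default 40).
#' @param seed Seed for the grid jitter.
#' @param min_radius_frac Smallest sphere as a fraction of the largest.
#' @param max_radius_frac Largest sphere as a fraction of the ball radius
#'   (default 0.45).
#' @return List of class `mcdem_cms_rep`: `centers`, `radii`, `radius`,
#'   `material`, `count`.
#' @export
build_cms_ball <- function(radius, target_count, material, n_grid = 40,
                           seed = 1, min_radius_frac = 0.02,
                           max_radius_frac = 0.45) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))
  h <- 2 * radius / n_grid
  gs <- seq(-radius + h / 2, radius - h / 2, by = h) +
    stats::runif(1, -h / 4, h / 4)
  grid <- as.matrix(expand.grid(gs, gs, gs))
  colnames(grid) <- NULL
  dctr <- sqrt(rowSums(grid^2))
  keep <- dctr < radius - h / 4
  grid <- grid[keep, , drop = FALSE]
  # cap the inscribed radius: practical sphere-fitting tools represent a body
  # with many moderate spheres rather than one giant central sphere (whose
  # smooth plate contact would mask the multi-contact artifacts the CMS
  # sensitivity study is about)
  dsurf <- pmin(radius - dctr[keep], max_radius_frac * radius)
  fill <- greedy_sphere_fill(grid, dsurf, coverage = 1.01,
                             max_count = target_count,
                             min_radius_frac = min_radius_frac)
  if (fill$count < target_count) {
    stop(sprintf("grid supports only %d spheres; raise n_grid", fill$count))
  }
  structure(
    list(centers = fill$centers, radii = fill$radii, radius = radius,
         material = material, count = fill$count),
    class = "mcdem_cms_rep"
  )
}

greedy_sphere_fill <- function(points, dsurf, coverage, max_count,
                               min_radius_frac) {
  covered <- rep(FALSE, nrow(points))
  centers <- matrix(numeric(), ncol = 3)
  radii <- numeric(0)
  rmax_placed <- 0
  while (mean(covered) < coverage && length(radii) < max_count) {
    cand <- which(!covered)
    if (length(cand) == 0) break
    k <- cand[which.max(dsurf[cand])]
    r_new <- dsurf[k]
    if (rmax_placed > 0 && r_new < min_radius_frac * rmax_placed) break
    rmax_placed <- max(rmax_placed, r_new)
    centers <- rbind(centers, points[k, ])
    radii <- c(radii, r_new)
    d2 <- (points[, 1] - points[k, 1])^2 + (points[, 2] - points[k, 2])^2 +
      (points[, 3] - points[k, 3])^2
    covered <- covered | (d2 <= r_new^2)
  }
  list(centers = centers, radii = radii, count = length(radii),
       coverage = mean(covered))
}

#' Quasi-static compression of a single multi-sphere ball between two plates
#'
#' The ball (a deformable BMS agglomerate or a rigid CMS cluster) starts
#' exactly touching two horizontal plates at z = +-R. Both plates close
#' symmetrically at `plate_speed` (total approach rate) up to a diameter
#' deformation of `max_deformation = delta / 2R`, then reopen at the same
#' rate. The force on the top plate is recorded against the deformation.
#'
#' @param body An `mcdem_bms_body` (from [build_bms_ball()]) or
#'   `mcdem_cms_rep` (from [build_cms_ball()]).
#' @param wall_material An `mcdem_material` for the plates.
#' @param max_deformation Target delta/2R (default 0.4).
#' @param plate_speed Total closing speed (m/s). Default 1e-3 of the
#'   particle material's sound speed sqrt(E/rho) (quasi-static).
#' @param model An [contact_model()]. Default Hertz for BMS; for CMS pass the
#'   multi-contact model.
#' @param bond_pars Bond parameters (BMS only; defaults from the body are not
#'   stored, so pass the same `mcdem_bond_params` used to build it).
#' @param dt Timestep; default [critical_timestep()] of the sub-spheres,
#'   shrunk by `1/sqrt(k1_scale)` when the loading stiffness is scaled up.
#' @param unload Also record the unloading branch (default TRUE).
#' @param n_record Approximate number of samples per branch.
#' @return A `data.frame` (class `mcdem_compression`) with columns `time`,
#'   `deformation` (delta/2R), `force` (N, top plate), `phase`
#'   ("LOADING"/"UNLOADING").
#' @export
run_single_sphere_compression <- function(body, wall_material,
                                          max_deformation = 0.4,
                                          plate_speed = NULL,
                                          model = contact_model("hertz"),
                                          bond_pars = NULL, dt = NULL,
                                          unload = TRUE, n_record = 400) {
  is_bms <- inherits(body, "mcdem_bms_body")
  mat_p <- body$material
  materials <- list(mat_p, wall_material)
  R <- body$radius
  if (is_bms) {
    x <- body$x
    r <- body$r
    n <- nrow(x)
    if (is.null(bond_pars)) {
      bond_pars <- bms_bond_params(mat_p, body$sub_radius)
    }
    st <- dem_state(
      x = x, r = r, materials = materials,
      material_id = rep(1L, n), mass = body$mass,
      body = rep(1L, n), body_kind = 1L,
      bonds = body$bonds, bond_pars = bond_pars,
      domain = sim_domain(lo = c(-4, -4, -4) * R, hi = c(4, 4, 4) * R),
      model = model
    )
  } else {
    x <- body$centers
    r <- body$radii
    n <- nrow(x)
    cms <- make_cms_body(seq_len(n), x, r, mat_p$density, body_id = 1L,
                         seed = 7, fix_rotation = TRUE, fix_lateral = TRUE)
    st <- dem_state(
      x = x, r = r, materials = materials,
      material_id = rep(1L, n),
      body = rep(1L, n), body_kind = 2L, cms = list(cms),
      domain = sim_domain(lo = c(-4, -4, -4) * R, hi = c(4, 4, 4) * R),
      model = model
    )
  }
  if (is.null(plate_speed)) {
    plate_speed <- 1e-3 * sqrt(mat_p$young_modulus / mat_p$density)
  }
  # plates start exactly touching the body's actual z extent (the lattice
  # clipping makes the built agglomerate slightly smaller than the nominal
  # ball; the characteristic diameter D is the built extent)
  z_top <- max(x[, 3] + r)
  z_bot <- min(x[, 3] - r)
  D <- z_top - z_bot
  half <- plate_speed / 2
  st$walls <- list(
    unclass(plane_wall(c(0, 0, 1), c(0, 0, z_bot), c(0, 0, half),
                       material = 2)),
    unclass(plane_wall(c(0, 0, -1), c(0, 0, z_top), c(0, 0, -half),
                       material = 2))
  )
  if (is.null(dt)) {
    dt <- critical_timestep(r, materials) / sqrt(model$ep$k1_scale)
    if (is_bms && nrow(st$bonds) > 0) {
      k_bond <- (bond_pars$knb + bond_pars$ktb) * max(st$bonds$area)
      dt <- min(dt, 0.15 * sqrt(min(st$m) / (12 * k_bond)))
    }
  }
  travel <- max_deformation * D
  n_steps <- ceiling(travel / (plate_speed * dt))
  rec <- max(1, floor(n_steps / n_record))

  out <- dem_run(st, dt, n_steps, record_every = rec)
  res <- compression_records(out$records, D, phase = "LOADING")
  if (unload) {
    st2 <- out$state
    st2$walls[[1]]$velocity <- c(0, 0, -half)
    st2$walls[[2]]$velocity <- c(0, 0, half)
    out2 <- dem_run(st2, dt, n_steps, record_every = rec)
    res2 <- compression_records(out2$records, D, phase = "UNLOADING")
    res <- rbind(res, res2)
    out <- out2
  }
  attr(res, "state") <- out$state
  attr(res, "diameter") <- D
  class(res) <- c("mcdem_compression", class(res))
  res
}

compression_records <- function(records, D, phase) {
  h <- records$wall_point[, 3, 2] - records$wall_point[, 3, 1]  # top - bottom
  data.frame(
    time = records$time,
    deformation = (D - h) / D,
    force = abs(records$wall_force[, 3, 2]),
    phase = phase
  )
}

#' Random sequential insertion of non-overlapping spheres
#'
#' @param radii Per-particle placement radii (bounding radii for clusters).
#' @param lo,hi Insertion box corners.
#' @param periodic Periodicity flags for minimum-image overlap checks.
#' @param seed RNG seed.
#' @param max_tries Attempts per particle before giving up.
#' @return n x 3 matrix of centers.
#' @export
insert_spheres_rsa <- function(radii, lo, hi, periodic = c(TRUE, TRUE, FALSE),
                               seed, max_tries = 20000) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))
  n <- length(radii)
  x <- matrix(NA_real_, n, 3)
  span <- hi - lo
  for (k in seq_len(n)) {
    placed <- FALSE
    for (t in seq_len(max_tries)) {
      p <- lo + stats::runif(3) * span
      # keep clear of non-periodic faces
      for (ax in which(!periodic)) {
        p[ax] <- lo[ax] + radii[k] +
          stats::runif(1) * (span[ax] - 2 * radii[k])
      }
      if (k > 1) {
        d <- sweep(x[seq_len(k - 1), , drop = FALSE], 2, p)
        for (ax in which(periodic)) {
          d[, ax] <- d[, ax] - span[ax] * round(d[, ax] / span[ax])
        }
        if (any(rowSums(d^2) < (radii[seq_len(k - 1)] + radii[k])^2)) next
      }
      x[k, ] <- p
      placed <- TRUE
      break
    }
    if (!placed) {
      stop("random insertion failed; enlarge the box height or reduce count")
    }
  }
  x
}

random_rotation <- function() {
  # QR of a Gaussian matrix gives a Haar-ish rotation
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Gravity filling of a die
#'
#' Particles (spheres sampled from a PSD fit, or copies of non-spherical BMS
#' templates) are inserted at random non-overlapping positions over the die
#' volume and settle under gravity until the kinetic energy per particle is
#' negligible. The die has a periodic x/y cross-section and a bottom plate.
#'
#' During filling the Young's moduli are scaled by `stiffness_scale`
#' (default 0.01): settling forces are tiny, the resulting overlaps stay below
#' ~0.5% of a radius, and the Rayleigh timestep grows by
#' `1/sqrt(stiffness_scale)`. Diameters are additionally capped at half the
#' periodic box length so the minimum-image convention stays valid.
#'
#' @param n Number of particles (default 150).
#' @param fit An `mcdem_psd_fit` in micrometres (default: upper-anchored fit
#'   of the MCC quantiles with the 180 um truncation).
#' @param materials List(particle, wall) materials; default MCC set.
#' @param cross_section Box side of the square die (m). Default 1 mm.
#' @param templates Optional list of unit-size sphere-cluster templates
#'   (each `list(centers, radii)` scaled so the longest box dimension is 1)
#'   for non-spherical BMS bodies; cycled over the particles.
#' @param bond_pars Bond parameters for template bodies.
#' @param seed Integer seed (insertion + PSD sampling).
#' @param stiffness_scale Young's-modulus scaling during filling (default 0.1;
#'   deeper reductions make impact overlaps so deep that the rotational
#'   tangential mode outruns the Rayleigh stability estimate).
#' @param pair_mu,pair_mur,pair_cor Pair coefficient matrices; defaults are
#'   the MCC particle/wall tables.
#' @param ke_tol Settling threshold: mean KE per particle below
#'   `ke_tol * m * g * d` ends the fill.
#' @param max_steps Hard cap on settling steps.
#' @return List of class `mcdem_fill`: `state` (settled, still with scaled
#'   stiffness), `packing_fraction`, `height` (bed height, m),
#'   `diameters` (sampled, m), `materials_full` (unscaled materials),
#'   `cross_section`, `seed`.
#' @export
run_gravity_fill <- function(n = 150, fit = NULL, materials = NULL,
                             cross_section = 1e-3, templates = NULL,
                             bond_pars = NULL, seed = 1,
                             stiffness_scale = 0.1,
                             pair_mu = NULL, pair_mur = NULL, pair_cor = NULL,
                             ke_tol = 1e-8, max_steps = 8e5) {
  if (is.null(fit)) fit <- fit_lognormal_to_quantiles(mcc_psd())
  if (is.null(materials)) {
    dm <- default_materials()
    materials <- list(dm$mcc, dm$mcc_wall)
  }
  if (is.null(pair_mu)) {
    pair_mu <- matrix(c(materials[[1]]$sliding_friction,
                        materials[[2]]$sliding_friction,
                        materials[[2]]$sliding_friction,
                        materials[[2]]$sliding_friction), 2, 2)
  }
  if (is.null(pair_mur)) {
    pair_mur <- matrix(c(materials[[1]]$rolling_friction,
                         materials[[2]]$rolling_friction,
                         materials[[2]]$rolling_friction,
                         materials[[2]]$rolling_friction), 2, 2)
  }
  if (is.null(pair_cor)) {
    pair_cor <- matrix(c(materials[[1]]$restitution,
                         materials[[2]]$restitution,
                         materials[[2]]$restitution,
                         materials[[2]]$restitution), 2, 2)
  }
  mats_scaled <- lapply(materials, function(m) {
    m$young_modulus <- m$young_modulus * stiffness_scale
    m
  })
  L <- cross_section
  dmax_allowed <- L / 2
  d <- sample_diameters(fit, n, seed = seed) * 1e-6  # um -> m
  d <- pmin(d, dmax_allowed)
  solid <- if (is.null(templates)) sum(4 / 3 * pi * (d / 2)^3) else NA

  if (is.null(templates)) {
    # spherical bed
    # dilute rain: the insertion cloud holds ~10% solids so particles deposit
    # sequentially, emulating die filling by pouring rather than flash
    # sedimentation of a dense cloud (which arrests in a looser state)
    h_est <- sum(4 / 3 * pi * (d / 2)^3) / (L^2 * 0.1)
    zlo <- 0
    zhi <- max(h_est, 5 * max(d))
    xpos <- insert_spheres_rsa(d / 2, lo = c(0, 0, zlo + max(d) / 2),
                               hi = c(L, L, zhi), seed = seed + 1)
    st <- dem_state(
      x = xpos, r = d / 2, materials = mats_scaled,
      material_id = rep(1L, n),
      walls = list(plane_wall(c(0, 0, 1), c(0, 0, 0), material = 2)),
      domain = sim_domain(lo = c(0, 0, -1e-3), hi = c(L, L, zhi + 1e-3),
                          periodic = c(TRUE, TRUE, FALSE)),
      gravity = c(0, 0, -9.81),
      model = contact_model("hertz"),
      pair_mu = pair_mu, pair_mur = pair_mur, pair_cor = pair_cor
    )
    masses <- st$m
  } else {
    if (is.null(bond_pars)) bond_pars <- bond_params(8e8, 9e8, 1.15, 0.05)
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(restore_rng(old), add = TRUE)
    set.seed(as.integer(seed) + 2L)
    xs <- NULL; rs <- NULL; bodyv <- integer(0); bound <- numeric(n)
    parts <- vector("list", n)
    for (k in seq_len(n)) {
      tpl <- templates[[(k - 1) %% length(templates) + 1]]
      rot <- random_rotation()
      ctr <- tpl$centers %*% t(rot) * d[k]
      rr <- tpl$radii * d[k]
      parts[[k]] <- list(centers = ctr, radii = rr)
      bound[k] <- max(sqrt(rowSums(ctr^2)) + rr)
    }
    solid_one <- vapply(parts, function(p) {
      sum(4 / 3 * pi * p$radii^3)
    }, numeric(1))
    h_est <- sum(solid_one) / (L^2 * 0.35)
    pos <- insert_spheres_rsa(bound, lo = c(0, 0, max(bound)),
                              hi = c(L, L, max(5 * h_est, 8 * max(bound))),
                              seed = seed + 1)
    for (k in seq_len(n)) {
      ck <- sweep(parts[[k]]$centers, 2, pos[k, ], `+`)
      xs <- rbind(xs, ck)
      rs <- c(rs, parts[[k]]$radii)
      bodyv <- c(bodyv, rep(k, nrow(ck)))
    }
    bonds <- create_bonds(xs, rs, bond_pars, body = bodyv)
    # per-body mass matches the true density times the sub-sphere union (the
    # lattice packs ~60-70%, so sub-sphere densities are compensated)
    masses <- materials[[1]]$density * 4 / 3 * pi * rs^3 / 0.65
    st <- dem_state(
      x = xs, r = rs, materials = mats_scaled,
      material_id = rep(1L, length(rs)), mass = masses,
      body = bodyv, body_kind = rep(1L, n),
      bonds = bonds, bond_pars = bond_pars,
      walls = list(plane_wall(c(0, 0, 1), c(0, 0, 0), material = 2)),
      domain = sim_domain(lo = c(0, 0, -1e-3),
                          hi = c(L, L, max(5 * h_est, 8 * max(bound)) + 1e-3),
                          periodic = c(TRUE, TRUE, FALSE)),
      gravity = c(0, 0, -9.81),
      model = contact_model("hertz"),
      pair_mu = pair_mu, pair_mur = pair_mur, pair_cor = pair_cor
    )
    solid <- sum(solid_one)
  }

  dt <- critical_timestep(st$r, mats_scaled, st$mat, safety_factor = 0.1)
  mgd <- mean(st$m) * 9.81 * mean(2 * st$r)
  chunk <- 5000L
  steps <- 0L
  calm <- 0L
  h_prev <- Inf
  repeat {
    out <- dem_run(st, dt, chunk, record_every = chunk)
    st <- out$state
    steps <- steps + chunk
    ke_per <- out$records$ke / nrow(st$x)
    h_now <- max(st$x[, 3] + st$r)
    # primary: kinetic energy negligible; secondary: bed height frozen and
    # kinetic energy far below the gravitational scale (quiescent creep)
    settled <- ke_per < ke_tol * mgd ||
      (abs(h_prev - h_now) < 1e-7 * h_now && ke_per < 1e-6 * mgd)
    h_prev <- h_now
    calm <- if (settled) calm + 1L else 0L
    if (calm >= 3L || steps >= max_steps) break
  }
  if (steps >= max_steps) {
    warning("settling step cap reached before the kinetic energy threshold")
  }
  height <- max(st$x[, 3] + st$r)
  pf <- solid / (L^2 * height)
  structure(
    list(state = st, packing_fraction = pf, height = height,
         diameters = d, materials_full = materials, cross_section = L,
         seed = seed, settle_steps = steps),
    class = "mcdem_fill"
  )
}

#' Uniaxial die compaction of a settled bed
#'
#' Adds a top plate at the bed height and drives it down at `plate_speed`
#' until the engineering strain `1 - h/h0` reaches `target_strain`, then (by
#' default) reverses it until the plate returns. Stress is the top-plate
#' normal reaction divided by the die cross-section. The compaction stage
#' restores the full (unscaled) Young's moduli and starts from fresh contact
#' histories.
#'
#' @param fill An `mcdem_fill` from [run_gravity_fill()].
#' @param target_strain Maximum engineering strain (default 0.57).
#' @param model Contact model; default the multi-contact elastic-plastic law
#'   with `beta = 1.3` and `k2_ratio = 5`.
#' @param plate_speed Plate speed (m/s); default 0.03.
#' @param dt Timestep; default Rayleigh-based on the full-stiffness material,
#'   shrunk by `1/sqrt(k1_scale)`.
#' @param unload Record the unloading branch.
#' @param n_record Approximate samples per branch.
#' @return A `data.frame` (class `mcdem_compression`) with `time`, `strain`,
#'   `stress` (Pa), `phase`; the final state is in `attr(, "state")`.
#' @export
run_uniaxial_compaction <- function(fill, target_strain = 0.57,
                                    model = contact_model(
                                      "elastoplastic", beta = 1.3,
                                      k2_ratio = 5
                                    ),
                                    plate_speed = 0.03, dt = NULL,
                                    unload = TRUE, n_record = 300) {
  st <- fill$state
  st$materials <- lapply(fill$materials_full, unclass)
  st$model <- unclass(model)
  st$history <- list(i = integer(), j = integer(), sx = numeric(),
                     sy = numeric(), sz = numeric(), d0 = numeric())
  st$pressures <- rep(0, nrow(st$x))
  h0 <- fill$height
  L <- fill$cross_section
  st$walls <- list(
    st$walls[[1]],
    unclass(plane_wall(c(0, 0, -1), c(0, 0, h0), c(0, 0, -plate_speed),
                       material = 2))
  )
  if (is.null(dt)) {
    dt <- critical_timestep(st$r, fill$materials_full, st$mat) /
      sqrt(max(1, st$model$ep$k1_scale))
  }
  travel <- target_strain * h0
  n_steps <- ceiling(travel / (plate_speed * dt))
  rec <- max(1, floor(n_steps / n_record))
  out <- dem_run(st, dt, n_steps, record_every = rec)
  res <- compaction_records(out$records, h0, L, phase = "LOADING")
  if (unload) {
    st2 <- out$state
    st2$walls[[2]]$velocity <- c(0, 0, plate_speed)
    out2 <- dem_run(st2, dt, n_steps, record_every = rec)
    res <- rbind(res,
                 compaction_records(out2$records, h0, L, phase = "UNLOADING"))
    out <- out2
  }
  attr(res, "state") <- out$state
  attr(res, "h0") <- h0
  class(res) <- c("mcdem_compression", class(res))
  res
}

compaction_records <- function(records, h0, L, phase) {
  h <- records$wall_point[, 3, 2] - records$wall_point[, 3, 1]
  data.frame(
    time = records$time,
    strain = 1 - h / h0,
    stress = abs(records$wall_force[, 3, 2]) / L^2,
    phase = phase
  )
}

#' Calibrate the loading stiffness to a target compaction stress
#'
#' The loading branch stiffness of the multi-contact elastic-plastic law is a
#' calibration parameter (it need not follow from the Young's modulus). This
#' routine runs loading-only compactions of the given bed and adjusts
#' `k1_scale` by secant iteration in log-log space until the axial stress at
#' `target_strain` is within `tol` of `target_stress`.
#'
#' @param fill An `mcdem_fill`.
#' @param target_stress Target stress at `target_strain` (Pa, default 30 MPa).
#' @param target_strain Strain at which the target applies (default 0.57).
#' @param model Base contact model (its `k1_scale` is the starting point).
#' @param tol Relative tolerance on the achieved stress (default 0.05).
#' @param max_iter Secant iterations (default 6).
#' @param ... Passed to [run_uniaxial_compaction()].
#' @return List with `k1_scale`, `stress` (achieved, Pa), `iterations`, and
#'   `result` (the final loading curve).
#' @export
calibrate_compaction <- function(fill, target_stress = 30e6,
                                 target_strain = 0.57,
                                 model = contact_model("elastoplastic",
                                                       beta = 1.3,
                                                       k2_ratio = 5),
                                 tol = 0.05, max_iter = 6, ...) {
  stress_at <- function(k1s) {
    m <- model
    m$ep$k1_scale <- k1s
    res <- run_uniaxial_compaction(fill, target_strain = target_strain,
                                   model = m, unload = FALSE, ...)
    load <- res[res$phase == "LOADING", ]
    stats::approx(load$strain, load$stress, xout = target_strain,
                  rule = 2)$y
  }
  k1 <- model$ep$k1_scale
  s1 <- stress_at(k1)
  it <- 1L
  if (abs(s1 - target_stress) / target_stress <= tol) {
    return(list(k1_scale = k1, stress = s1, iterations = it,
                result = NULL))
  }
  k2 <- k1 * target_stress / s1
  repeat {
    s2 <- stress_at(k2)
    it <- it + 1L
    if (abs(s2 - target_stress) / target_stress <= tol || it >= max_iter) break
    # secant in log-log space (stress is near power-law in k1)
    slope <- (log(s2) - log(s1)) / (log(k2) - log(k1))
    k_new <- exp(log(k2) + (log(target_stress) - log(s2)) / slope)
    k1 <- k2; s1 <- s2
    k2 <- max(1e-3, min(1e3, k_new))
  }
  list(k1_scale = k2, stress = s2, iterations = it, result = NULL)
}

#' Packing fraction of a sphere set in a box region
#'
#' Solid volume divided by region volume. For non-overlapping spheres the
#' solid volume is the analytic sum; when overlaps exist (CMS unions) a
#' Monte-Carlo union estimate is used.
#'
#' @param x N x 3 centers.
#' @param r Radii.
#' @param region List with `lo`, `hi` (box corners, m).
#' @param method `"auto"`, `"analytic"` or `"mc"`.
#' @param n_samples Monte-Carlo samples.
#' @param seed Seed for the Monte-Carlo path.
#' @return Packing fraction in `[0, 1]`.
#' @export
packing_fraction <- function(x, r, region, method = c("auto", "analytic", "mc"),
                             n_samples = 2e5, seed = 1) {
  method <- match.arg(method)
  x <- matrix(as.numeric(x), ncol = 3)
  r <- rep_len(as.numeric(r), nrow(x))
  vol_region <- prod(region$hi - region$lo)
  if (vol_region <= 0) stop("empty region")
  if (method == "auto") {
    prs <- neighbor_pairs(x, r, sim_domain(region$lo - 1, region$hi + 1),
                          skin = 0)
    method <- if (nrow(prs) > 0) "mc" else "analytic"
  }
  if (method == "analytic") {
    return(sum(4 / 3 * pi * r^3) / vol_region)
  }
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))
  pts <- cbind(
    stats::runif(n_samples, region$lo[1], region$hi[1]),
    stats::runif(n_samples, region$lo[2], region$hi[2]),
    stats::runif(n_samples, region$lo[3], region$hi[3])
  )
  inside <- rep(FALSE, n_samples)
  for (k in seq_len(nrow(x))) {
    d2 <- (pts[, 1] - x[k, 1])^2 + (pts[, 2] - x[k, 2])^2 +
      (pts[, 3] - x[k, 3])^2
    inside <- inside | (d2 <= r[k]^2)
  }
  mean(inside)
}
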