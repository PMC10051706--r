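#' Bond stiffness parameters
#'
#' Bonds are linear springs distributed over the bond cross-section: the
#' printed stiffness densities (N/m^3) multiply the cross-section area
#' `Ab = pi * rb^2` (bond radius `rb = min(ri, rj)`) to give a spring constant
#' in N/m. Bonds are permanent (no strength threshold) and carry a normal and
#' a tangential spring plus a small viscous term.
#'
#' @param normal_stiffness_density k_nb (N/m^3).
#' @param tangential_stiffness_density k_tb (N/m^3).
#' @param bond_multiplier m_b >= 1: two spheres are bonded when their center
#'   distance is below `(ri + rj) * m_b`.
#' @param damping_ratio Fraction of critical damping applied to the relative
#'   motion across each bond (dimensionless, >= 0).
#' @return List of class `mcdem_bond_params`.
#' @export
bond_params <- function(normal_stiffness_density,
                        tangential_stiffness_density,
                        bond_multiplier = 1.15,
                        damping_ratio = 0.05) {
  stopifnot(
    normal_stiffness_density > 0, tangential_stiffness_density > 0,
    bond_multiplier >= 1, damping_ratio >= 0
  )
  structure(
    list(
      knb = as.numeric(normal_stiffness_density),
      ktb = as.numeric(tangential_stiffness_density),
      mb = as.numeric(bond_multiplier),
      damping_ratio = as.numeric(damping_ratio)
    ),
    class = "mcdem_bond_params"
  )
}

#' Modulus-derived bond stiffness for a BMS body
#'
#' Truss-consistent bond stiffness densities: a bond of length `L0 = 2 r_sub`
#' and cross-section `Ab = pi r_sub^2` behaves like a rod of the material,
#' `k = E Ab / L0`, i.e. stiffness density `knb = E / L0` (N/m^3). A lattice
#' of such bonds has an effective Young's modulus close to the material's,
#' which is what makes a bonded agglomerate mimic the solid elastic sphere it
#' replaces. The tangential density defaults to the same value (near-isotropic
#' lattice response).
#'
#' @param material An `mcdem_material`.
#' @param sub_radius Sub-sphere radius (m).
#' @param kt_ratio ktb/knb (default 1).
#' @param bond_multiplier,damping_ratio Passed to [bond_params()].
#' @return An `mcdem_bond_params`.
#' @export
bms_bond_params <- function(material, sub_radius, kt_ratio = 1,
                            bond_multiplier = 1.15, damping_ratio = 0.05) {
  knb <- material$young_modulus / (2 * sub_radius)
  bond_params(knb, kt_ratio * knb, bond_multiplier, damping_ratio)
}

#' Create bonds by the distance criterion
#'
#' One-shot bonding: a bond is created for every pair (i, j) with
#' `|x_i - x_j| < (r_i + r_j) * m_b`. Each bond snapshots its rest length and
#' rest normal at creation. Bonding is restricted to pairs within the same
#' body when `body` ids are supplied and `restrict_within_body` is TRUE.
#'
#' @param x N x 3 matrix of sphere centers (m).
#' @param r Length-N radii (m).
#' @param params An `mcdem_bond_params` (supplies `mb`).
#' @param body Optional length-N integer body ids.
#' @param restrict_within_body Only bond spheres sharing a body id.
#' @return A data frame with one row per bond: `i`, `j` (i < j, 1-based),
#'   `rest_length`, `bond_radius`, `area`, rest normal `nx, ny, nz` (unit,
#'   j to i) and zeroed tangential offset `ox, oy, oz`.
#' @export
create_bonds <- function(x, r, params, body = NULL,
                         restrict_within_body = !is.null(body)) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2L) return(empty_bond_table())
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  if (restrict_within_body && !is.null(body)) {
    keep <- body[i] == body[j]
    i <- i[keep]; j <- j[keep]
  }
  d <- x[i, , drop = FALSE] - x[j, , drop = FALSE]
  dist <- sqrt(rowSums(d^2))
  hit <- dist < (r[i] + r[j]) * params$mb
  if (any(hit & dist == 0)) {
    stop("coincident sphere centers within bonding range: normal undefined")
  }
  i <- i[hit]; j <- j[hit]; d <- d[hit, , drop = FALSE]; dist <- dist[hit]
  if (length(i) == 0L) return(empty_bond_table())
  nrm <- d / dist
  rb <- pmin(r[i], r[j])
  data.frame(
    i = i, j = j, rest_length = dist, bond_radius = rb, area = pi * rb^2,
    nx = nrm[, 1], ny = nrm[, 2], nz = nrm[, 3],
    ox = 0, oy = 0, oz = 0
  )
}

empty_bond_table <- function() {
  data.frame(
    i = integer(), j = integer(), rest_length = numeric(),
    bond_radius = numeric(), area = numeric(),
    nx = numeric(), ny = numeric(), nz = numeric(),
    ox = numeric(), oy = numeric(), oz = numeric()
  )
}

#' Elastic bond force between two sub-spheres
#'
#' Normal spring `F_n = -knb * Ab * (L - L0)` along the current center line
#' (attractive when stretched), a tangential spring on the accumulated
#' tangential offset (advanced by the relative tangential velocity at the bond
#' midpoint, re-projected onto the current normal plane each step) and viscous
#' damping proportional to the relative velocity. Forces are equal and
#' opposite; the force is zero at the creation geometry. In a dynamic BMS body
#' the engine applies this law while the pair is separated and hands over to
#' the contact model when the spheres overlap.
#'
#' @param bond One-row slice of a [create_bonds()] table (or a list with the
#'   same fields).
#' @param x_i,x_j Current centers; `i`/`j` as in the bond.
#' @param v_i,v_j Velocities.
#' @param w_i,w_j Angular velocities.
#' @param params An `mcdem_bond_params`.
#' @param m_i,m_j Masses (kg), used for the damping scale.
#' @param dt Timestep to advance the tangential offset (s); 0 evaluates only.
#' @return List with `force_i`, `force_j` (3-vectors, N) and `bond` (updated
#'   tangential offset).
#' @export
bond_force <- function(bond, x_i, x_j, v_i = c(0, 0, 0), v_j = c(0, 0, 0),
                       w_i = c(0, 0, 0), w_j = c(0, 0, 0),
                       params, m_i = 1, m_j = 1, dt = 0) {
  d <- x_i - x_j
  len <- sqrt(sum(d^2))
  nrm <- d / len
  ab <- bond$area
  kn <- params$knb * ab
  kt <- params$ktb * ab
  mstar <- m_i * m_j / (m_i + m_j)

  u <- len - bond$rest_length
  f_n <- -kn * u * nrm

  mid <- (x_i + x_j) / 2
  v_rel <- (v_i + cross3(w_i, mid - x_i)) - (v_j + cross3(w_j, mid - x_j))
  vn <- sum((v_i - v_j) * nrm)
  vt <- v_rel - sum(v_rel * nrm) * nrm

  xi <- c(bond$ox, bond$oy, bond$oz)
  xi <- xi - sum(xi * nrm) * nrm
  xi <- xi + vt * dt
  f_t <- -kt * xi

  cn <- 2 * params$damping_ratio * sqrt(kn * mstar)
  ct <- 2 * params$damping_ratio * sqrt(kt * mstar)
  f_d <- -cn * vn * nrm - ct * vt

  f <- f_n + f_t + f_d
  bond$ox <- xi[1]; bond$oy <- xi[2]; bond$oz <- xi[3]
  list(force_i = f, force_j = -f, bond = bond)
}

# fixed incommensurate rotation (irrational axis/angle) used to de-align
# lattice planes from the laboratory axes
tilt_rotation <- function() {
  axis <- c(1, sqrt(2), sqrt(3))
  axis <- axis / sqrt(sum(axis^2))
  ang <- 0.41
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
}

# hexagonal close packing of pitch `a`, covering [-half, half]^3
hcp_lattice <- function(a, half) {
  dy <- a * sqrt(3) / 2
  dz <- a * sqrt(2 / 3)
  ks <- seq(floor(-half / dz), ceiling(half / dz))
  pts <- lapply(ks, function(k) {
    # B layers sit over the centroids of A-layer triangles: offset
    # (a/2, a*sqrt(3)/6) so every inter-layer neighbor is at distance a
    yoff <- if (k %% 2 == 0) 0 else a * sqrt(3) / 6
    xoff_k <- if (k %% 2 == 0) 0 else a / 2
    js <- seq(floor((-half - yoff) / dy), ceiling((half - yoff) / dy))
    do.call(rbind, lapply(js, function(jj) {
      xoff <- xoff_k + (if (jj %% 2 == 0) 0 else a / 2)
      is <- seq(floor((-half - xoff) / a), ceiling((half - xoff) / a))
      cbind(is * a + xoff, jj * dy + yoff, k * dz)
    }))
  })
  do.call(rbind, pts)
}

#' Build a deformable bonded multi-sphere (BMS) ball
#'
#' Replaces a solid elastic sphere of radius `radius` by an agglomerate of
#' equal, touching (non-overlapping) sub-spheres on a hexagonal close packing,
#' clipped to lie entirely inside the ball, and bonds every touching pair with
#' the distance criterion (rest length = lattice pitch). The lattice pitch is
#' chosen so the kept sub-sphere count falls within 10% of `target_count`.
#' Sub-sphere masses are scaled so the body mass equals the solid sphere's
#' mass (the lattice fills only ~60-70% of the volume; the density is
#' compensated so the dynamics see the right inertia).
#'
#' @param radius Ball radius R (m).
#' @param target_count Desired number of sub-spheres (>= 10).
#' @param material An `mcdem_material` for the sub-spheres.
#' @param params An `mcdem_bond_params`.
#' @param conform_surface Project the outermost sub-sphere shell radially onto
#'   the circumscribed sphere (so every surface sub-sphere is tangent to the
#'   nominal surface from inside). This smooths the agglomerate's envelope:
#'   without it the clipped lattice is bumpy and its plate contact noticeably
#'   softer and noisier. Default TRUE.
#' @export
build_bms_ball <- function(radius, target_count, material, params,
                           conform_surface = TRUE) {
  stopifnot(target_count >= 10)
  # nominal sub-radius from close-packing fraction, then scan for best count
  r0 <- radius * (0.74 / target_count)^(1 / 3)
  cand <- r0 * seq(0.75, 1.35, by = 0.005)
  counts <- vapply(cand, function(rs) {
    pts <- hcp_lattice(2 * rs, radius)
    sum(sqrt(rowSums(pts^2)) <= radius - rs)
  }, integer(1))
  best <- which.min(abs(counts - target_count))
  if (abs(counts[best] - target_count) > 0.1 * target_count) {
    stop(sprintf(
      "cannot reach %d sub-spheres within 10%%; achievable counts near target: %s",
      target_count, paste(sort(unique(counts[abs(counts - target_count) <
        0.5 * target_count])), collapse = ", ")
    ))
  }
  rs <- cand[best]
  pts <- hcp_lattice(2 * rs, radius)
  keep <- sqrt(rowSums(pts^2)) <= radius - rs
  x <- pts[keep, , drop = FALSE]
  # tilt the lattice so no dense plane aligns with the compression axis:
  # an axis-aligned clip would present flat facets to the plates and
  # overestimate the initial contact stiffness
  x <- x %*% t(tilt_rotation())
  if (conform_surface) {
    d <- sqrt(rowSums(x^2))
    sel <- d > radius - 1.6 * rs
    x[sel, ] <- x[sel, ] * ((radius - rs) / d[sel])
  }
  n <- nrow(x)
  bonds <- create_bonds(x, rep(rs, n), params)
  mass <- material$density * 4 / 3 * pi * radius^3 / n
  structure(
    list(
      x = x, r = rep(rs, n), mass = rep(mass, n), bonds = bonds,
      radius = radius, sub_radius = rs, material = material
    ),
    class = "mcdem_bms_body"
  )
}

#' Connected components of a bond graph
#'
#' Breadth-first search over the bond edge list. Used to verify that a built
#' BMS body is a single connected component and has no unbonded sub-spheres.
#'
#' @param n Number of spheres.
#' @param bonds A [create_bonds()] table.
#' @return Integer vector of component labels (1-based) per sphere.
#' @export
bond_components <- function(n, bonds) {
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds$i[k]; j <- bonds$j[k]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      for (u in adj[[v]]) {
        if (comp[u] == 0L) {
          comp[u] <- cur
          queue <- c(queue, u)
        }
      }
    }
  }
  comp
}
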