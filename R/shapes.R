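#' Triangulated surface mesh
#'
#' A closed (watertight) triangle mesh with outward-oriented faces and
#' positive enclosed volume.
#'
#' @param vertices V x 3 numeric matrix (m).
#' @param faces F x 3 integer matrix of 1-based vertex indices.
#' @param provenance Free-text description of where the mesh came from.
#' @param validate Check watertightness and volume sign (default TRUE).
#' @return Object of class `mcdem_trimesh`.
#' @export
trimesh <- function(vertices, faces, provenance = "", validate = TRUE) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  faces <- matrix(as.integer(faces), ncol = 3)
  m <- structure(
    list(vertices = vertices, faces = faces, provenance = provenance),
    class = "mcdem_trimesh"
  )
  if (validate) {
    open_e <- open_edges(m)
    if (nrow(open_e) > 0) {
      stop(sprintf(
        "mesh is not watertight: %d open/over-shared edge(s), e.g. (%s)",
        nrow(open_e),
        paste(apply(utils::head(open_e, 5), 1, paste, collapse = "-"),
              collapse = ", ")
      ))
    }
    if (mesh_volume(m) <= 0) {
      stop("mesh has non-positive enclosed volume: faces not outward-oriented")
    }
  }
  m
}

#' @export
print.mcdem_trimesh <- function(x, ...) {
  cat(sprintf(
    "<mcdem_trimesh> %d vertices, %d faces, volume %.4g%s\n",
    nrow(x$vertices), nrow(x$faces), mesh_volume(x),
    if (nzchar(x$provenance)) paste0(" [", x$provenance, "]") else ""
  ))
  invisible(x)
}

# edges not shared by exactly two faces (undirected)
open_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(key)
  bad <- names(tab)[tab != 2]
  if (length(bad) == 0) {
    return(matrix(integer(), ncol = 2))
  }
  do.call(rbind, lapply(strsplit(bad, " "), as.integer))
}

#' Enclosed volume of a closed mesh (divergence theorem)
#' @param mesh An `mcdem_trimesh`.
#' @return Signed volume (m^3), positive for outward-oriented faces.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  sum(
    a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) +
    a[, 2] * (b[, 3] * cc[, 1] - b[, 1] * cc[, 3]) +
    a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
  ) / 6
}

#' Unit icosphere mesh
#'
#' Icosahedron subdivided `subdiv` times, vertices projected onto the unit
#' sphere. Watertight and outward-oriented by construction.
#'
#' @param subdiv Number of 4-to-1 subdivisions (0 gives the icosahedron).
#' @return An `mcdem_trimesh` with radius-1 vertices.
#' @export
icosphere <- function(subdiv = 3) {
  phi <- (1 + sqrt(5)) / 2
  v <- matrix(c(
    -1, phi, 0, 1, phi, 0, -1, -phi, 0, 1, -phi, 0,
    0, -1, phi, 0, 1, phi, 0, -1, -phi, 0, 1, -phi,
    phi, 0, -1, phi, 0, 1, -phi, 0, -1, -phi, 0, 1
  ), ncol = 3, byrow = TRUE)
  v <- v / sqrt(rowSums(v^2))
  f <- matrix(c(
    1, 12, 6, 1, 6, 2, 1, 2, 8, 1, 8, 11, 1, 11, 12,
    2, 6, 10, 6, 12, 5, 12, 11, 3, 11, 8, 7, 8, 2, 9,
    4, 10, 5, 4, 5, 3, 4, 3, 7, 4, 7, 9, 4, 9, 10,
    5, 10, 6, 3, 5, 12, 7, 3, 11, 9, 7, 8, 10, 9, 2
  ), ncol = 3, byrow = TRUE)
  for (s in seq_len(subdiv)) {
    nv <- nrow(v)
    edges <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    ekey <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    uk <- unique(ekey)
    mididx <- match(ekey, uk) + nv
    ue <- do.call(rbind, strsplit(uk, " "))
    mid <- (v[as.integer(ue[, 1]), , drop = FALSE] +
            v[as.integer(ue[, 2]), , drop = FALSE]) / 2
    mid <- mid / sqrt(rowSums(mid^2))
    v <- rbind(v, mid)
    nf <- nrow(f)
    m12 <- mididx[seq_len(nf)]
    m23 <- mididx[nf + seq_len(nf)]
    m31 <- mididx[2 * nf + seq_len(nf)]
    f <- rbind(
      cbind(f[, 1], m12, m31),
      cbind(f[, 2], m23, m12),
      cbind(f[, 3], m31, m23),
      cbind(m12, m23, m31)
    )
  }
  trimesh(v, f, provenance = sprintf("icosphere(subdiv=%d)", subdiv))
}

#' Principal-axis bounding box dimensions
#'
#' Side lengths of the bounding box aligned with the principal axes of the
#' vertex (or sphere-center) point set, sorted descending. For sphere clusters
#' the extents are dilated by the sphere radii. This is the "Feret box" used
#' by the shape descriptors.
#'
#' @param x An `mcdem_trimesh`, or a list with `centers` (n x 3) and `radii`
#'   for a sphere cluster.
#' @return Named numeric vector `c(L, I, S)` with `L >= I >= S`.
#' @export
bounding_box_dimensions <- function(x) {
  if (inherits(x, "mcdem_trimesh")) {
    pts <- x$vertices
    rad <- rep(0, nrow(pts))
    centered <- sweep(pts, 2, colMeans(pts))
    if (qr(centered)$rank < 3) {
      stop("degenerate geometry: fewer than 4 non-coplanar points")
    }
  } else {
    pts <- matrix(as.numeric(x$centers), ncol = 3)
    rad <- rep_len(as.numeric(x$radii), nrow(pts))
    centered <- sweep(pts, 2, colMeans(pts))
  }
  cv <- crossprod(centered) / max(1, nrow(pts) - 1)
  axes <- eigen(cv, symmetric = TRUE)$vectors
  proj <- centered %*% axes
  dims <- vapply(1:3, function(k) {
    max(proj[, k] + rad) - min(proj[, k] - rad)
  }, numeric(1))
  dims <- sort(dims, decreasing = TRUE)
  if (dims[3] <= 0) stop("degenerate geometry: zero smallest box side")
  c(L = dims[1], I = dims[2], S = dims[3])
}

#' Shape descriptors from box dimensions
#'
#' Aspect ratio `S/L`, elongation `I/L` and flatness `S/I` from the sorted
#' principal-box side lengths. The identity
#' `aspect_ratio = elongation * flatness` holds by construction.
#'
#' @param L,I,S Box side lengths with `L >= I >= S > 0`, or a single length-3
#'   vector as first argument.
#' @return List of class `mcdem_shape_descriptors` with fields `L`, `I`, `S`,
#'   `aspect_ratio`, `elongation`, `flatness`.
#' @export
shape_descriptors <- function(L, I, S) {
  if (length(L) == 3 && missing(I)) {
    S <- L[[3]]; I <- L[[2]]; L <- L[[1]]
  }
  stopifnot(L >= I, I >= S, S > 0)
  structure(
    list(
      L = L, I = I, S = S,
      aspect_ratio = S / L, elongation = I / L, flatness = S / I
    ),
    class = "mcdem_shape_descriptors"
  )
}

#' Generate a random star-shaped particle with target shape descriptors
#'
#' Perturbs a unit icosphere with a seeded smooth random radial field
#' (a sum of `n_modes` spatial cosine harmonics with amplitude proportional to
#' `irregularity`), then iteratively rescales the mesh along its principal
#' axes until the measured box descriptors hit the targets. With
#' `irregularity = 0` the result is an exact ellipsoid. The output is
#' deterministic for a fixed seed.
#'
#' Give either `elongation` and `flatness` (aspect ratio is their product), or
#' `aspect_ratio` alone (split symmetrically: elongation = flatness =
#' sqrt(aspect_ratio)).
#'
#' @param aspect_ratio Target S/L in (0, 1].
#' @param elongation,flatness Target I/L and S/I in (0, 1].
#' @param size Longest box dimension L of the result (m). Default 1.
#' @param irregularity Relative amplitude of the radial perturbation (>= 0).
#' @param n_modes Number of random harmonics.
#' @param seed Integer RNG seed.
#' @param subdiv Icosphere subdivision of the template.
#' @param tol Relative tolerance on the achieved descriptors (default 5%).
#' @param max_retry Retries with derived seeds if the target is missed.
#' @return An `mcdem_trimesh`.
#' @export
generate_random_particle <- function(aspect_ratio = NULL, elongation = NULL,
                                     flatness = NULL, size = 1,
                                     irregularity = 0.15, n_modes = 4,
                                     seed, subdiv = 3, tol = 0.05,
                                     max_retry = 5) {
  if (missing(seed)) stop("an explicit seed is required")
  if (is.null(elongation) || is.null(flatness)) {
    if (is.null(aspect_ratio)) stop("give aspect_ratio or elongation+flatness")
    elongation <- sqrt(aspect_ratio)
    flatness <- sqrt(aspect_ratio)
  }
  stopifnot(
    elongation > 0, elongation <= 1, flatness > 0, flatness <= 1,
    irregularity >= 0, n_modes >= 1
  )
  target <- c(1, elongation, elongation * flatness)

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old), add = TRUE)

  base <- icosphere(subdiv)
  for (attempt in 0:max_retry) {
    set.seed(as.integer(seed) + attempt * 7919L)
    v <- base$vertices
    if (irregularity > 0) {
      field <- rep(0, nrow(v))
      for (m in seq_len(n_modes)) {
        k <- stats::rnorm(3)
        k <- k / sqrt(sum(k^2)) * (m + 1)
        phase <- stats::runif(1, 0, 2 * pi)
        amp <- stats::rnorm(1, 1, 0.25) / m
        field <- field + amp * cos(v %*% k + phase)
      }
      field <- field / max(abs(field))
      rad <- 1 + irregularity * field
      rad <- pmax(rad, 0.2)
      v <- v * as.vector(rad)
    }
    mesh <- trimesh(v, base$faces, validate = FALSE)
    ok <- FALSE
    for (it in 1:12) {
      dims <- bounding_box_dimensions(mesh)
      ratios <- dims / dims[1]
      err <- max(abs(ratios - target) / target)
      if (err < tol / 4) {
        ok <- TRUE
        break
      }
      # rescale along current principal axes toward the target ratios
      centered <- sweep(mesh$vertices, 2, colMeans(mesh$vertices))
      axes <- eigen(crossprod(centered), symmetric = TRUE)$vectors
      proj <- centered %*% axes
      ext <- apply(proj, 2, function(p) diff(range(p)))
      ord <- order(ext, decreasing = TRUE)
      scale <- numeric(3)
      scale[ord] <- target / (ext[ord] / ext[ord[1]])
      proj <- sweep(proj, 2, scale, `*`)
      mesh$vertices <- proj %*% t(axes)
    }
    if (ok) {
      dims <- bounding_box_dimensions(mesh)
      mesh$vertices <- mesh$vertices * (size / dims[1])
      mesh$provenance <- sprintf(
        "generate_random_particle(seed=%d, irregularity=%.3g)", seed,
        irregularity
      )
      if (mesh_volume(mesh) <= 0) mesh$faces <- mesh$faces[, c(1, 3, 2)]
      return(trimesh(mesh$vertices, mesh$faces, mesh$provenance))
    }
  }
  stop("could not reach the target descriptors; lower irregularity or raise tol")
}

#' Are points inside a closed mesh?
#'
#' Ray-casting (crossing-count) point-in-polyhedron test.
#'
#' @param points n x 3 matrix.
#' @param mesh An `mcdem_trimesh`.
#' @return Logical vector of length n.
#' @export
points_in_mesh <- function(points, mesh) {
  points <- matrix(as.numeric(points), ncol = 3)
  cpp_points_in_mesh(points, mesh$vertices, mesh$faces)
}

#' Distance from points to a mesh surface
#' @param points n x 3 matrix.
#' @param mesh An `mcdem_trimesh`.
#' @return Numeric vector of unsigned distances (m).
#' @export
point_mesh_distance <- function(points, mesh) {
  points <- matrix(as.numeric(points), ncol = 3)
  cpp_point_mesh_distance(points, mesh$vertices, mesh$faces)
}

#' Fill a closed mesh with sub-spheres
#'
#' Two fill modes mirroring the two multi-sphere body types:
#' * `lattice_uniform` (for deformable BMS bodies): equal, touching,
#'   non-overlapping spheres on a hexagonal close packing clipped to the mesh
#'   interior (center at least one sub-radius from the surface).
#' * `grid_adaptive` (for rigid CMS bodies): greedy placement of the largest
#'   sphere inscribed at interior grid points, overlaps allowed, until the
#'   covered interior fraction reaches `coverage` or `max_count` spheres are
#'   placed.
#'
#' @param mesh An `mcdem_trimesh`.
#' @param resolution For `lattice_uniform`: target sub-sphere count (integer
#'   >= 10) or sub-sphere radius (< 10, interpreted in mesh units). For
#'   `grid_adaptive`: grid points per longest axis (default 24 when `NULL`).
#' @param mode `"lattice_uniform"` or `"grid_adaptive"`.
#' @param seed Integer seed (jitters the grid origin; output is deterministic
#'   per seed).
#' @param coverage Interior coverage target for `grid_adaptive` (default 0.95).
#' @param max_count Sphere budget for `grid_adaptive`; when given, filling
#'   stops at exactly `max_count` spheres (the count knob of a CMS
#'   representation).
#' @param min_radius_frac Smallest allowed adaptive sphere radius as a
#'   fraction of the largest placed sphere (default 0.1).
#' @return List with `centers` (n x 3), `radii`, `count`, and for
#'   `grid_adaptive` the achieved `coverage`.
#' @export
fill_mesh_with_spheres <- function(mesh, resolution = NULL,
                                   mode = c("lattice_uniform", "grid_adaptive"),
                                   seed = 1, coverage = 0.95,
                                   max_count = NULL, min_radius_frac = 0.1) {
  mode <- match.arg(mode)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))
  vol <- mesh_volume(mesh)
  ctr <- colMeans(mesh$vertices)
  half <- max(sqrt(rowSums(sweep(mesh$vertices, 2, ctr)^2)))

  if (mode == "lattice_uniform") {
    if (is.null(resolution)) stop("lattice_uniform needs a resolution")
    fill_lattice <- function(rs) {
      pts <- sweep(hcp_lattice(2 * rs, half), 2, ctr, `+`)
      pts <- pts + matrix(stats::runif(3, -rs / 4, rs / 4),
                          nrow(pts), 3, byrow = TRUE)
      ok <- points_in_mesh(pts, mesh)
      pts <- pts[ok, , drop = FALSE]
      if (nrow(pts) == 0) return(pts)
      d <- point_mesh_distance(pts, mesh)
      pts[d >= rs * 0.999, , drop = FALSE]
    }
    if (resolution >= 10 && resolution == round(resolution)) {
      target <- resolution
      r0 <- (0.7 * vol * 3 / (4 * pi * target))^(1 / 3)
      cand <- r0 * seq(0.8, 1.3, by = 0.01)
      best_pts <- NULL; best_r <- NA; best_err <- Inf
      for (rs in cand) {
        pts <- fill_lattice(rs)
        err <- abs(nrow(pts) - target)
        if (err < best_err) {
          best_err <- err; best_pts <- pts; best_r <- rs
        }
        if (err == 0) break
      }
      if (best_err > 0.1 * target) {
        stop(sprintf("cannot reach %d lattice spheres within 10%% (best: %d)",
                     target, nrow(best_pts)))
      }
      pts <- best_pts; rs <- best_r
    } else {
      rs <- resolution
      pts <- fill_lattice(rs)
      if (nrow(pts) == 0) stop("resolution too coarse: no sphere fits inside")
    }
    return(list(centers = pts, radii = rep(rs, nrow(pts)), count = nrow(pts)))
  }

  # grid_adaptive
  ngrid <- if (is.null(resolution)) 24L else as.integer(resolution)
  dims <- apply(mesh$vertices, 2, range)
  hgrid <- max(dims[2, ] - dims[1, ]) / ngrid
  gx <- seq(dims[1, 1], dims[2, 1], by = hgrid) + stats::runif(1, 0, hgrid / 3)
  gy <- seq(dims[1, 2], dims[2, 2], by = hgrid) + stats::runif(1, 0, hgrid / 3)
  gz <- seq(dims[1, 3], dims[2, 3], by = hgrid) + stats::runif(1, 0, hgrid / 3)
  grid <- as.matrix(expand.grid(gx, gy, gz))
  colnames(grid) <- NULL
  inside <- points_in_mesh(grid, mesh)
  grid <- grid[inside, , drop = FALSE]
  if (nrow(grid) == 0) stop("grid too coarse: no interior points")
  dsurf <- point_mesh_distance(grid, mesh)
  covered <- rep(FALSE, nrow(grid))
  centers <- NULL; radii <- numeric(0)
  budget <- if (is.null(max_count)) 10000L else max_count
  rmax_placed <- 0
  while (sum(covered) / length(covered) < coverage && length(radii) < budget) {
    cand <- which(!covered)
    if (length(cand) == 0) break
    k <- cand[which.max(dsurf[cand])]
    r_new <- dsurf[k]
    if (rmax_placed > 0 && r_new < min_radius_frac * rmax_placed) break
    rmax_placed <- max(rmax_placed, r_new)
    centers <- rbind(centers, grid[k, ])
    radii <- c(radii, r_new)
    d2 <- (grid[, 1] - grid[k, 1])^2 + (grid[, 2] - grid[k, 2])^2 +
      (grid[, 3] - grid[k, 3])^2
    covered <- covered | (d2 <= r_new^2)
  }
  if (length(radii) == 0) stop("resolution too coarse to place any sphere")
  list(
    centers = centers, radii = radii, count = length(radii),
    coverage = sum(covered) / length(covered)
  )
}

#' Read an STL file
#'
#' Reads ASCII or binary STL (autodetected), merges duplicate vertices and
#' validates watertightness.
#'
#' @param path File path.
#' @return An `mcdem_trimesh`.
#' @export
read_stl <- function(path) {
  con <- file(path, "rb")
  head <- readBin(con, "raw", 84)
  close(con)
  is_binary <- FALSE
  if (length(head) == 84) {
    ntri <- readBin(head[81:84], "integer", 1, size = 4, endian = "little")
    is_binary <- file.size(path) == 84 + 50 * ntri
  }
  if (is_binary) {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", 80)
    ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
    tri <- matrix(NA_real_, ntri * 3, 3)
    for (k in seq_len(ntri)) {
      vals <- readBin(con, "numeric", 12, size = 4, endian = "little")
      readBin(con, "raw", 2)
      tri[(3 * k - 2):(3 * k), ] <- matrix(vals[4:12], 3, 3, byrow = TRUE)
    }
  } else {
    lines <- readLines(path, warn = FALSE)
    vlines <- grep("^\\s*vertex\\s", lines, value = TRUE)
    if (length(vlines) == 0 || length(vlines) %% 3 != 0) {
      stop("malformed ASCII STL: vertex count not a multiple of 3")
    }
    tri <- do.call(rbind, lapply(strsplit(trimws(vlines), "\\s+"), function(p) {
      as.numeric(p[2:4])
    }))
  }
  key <- apply(tri, 1, function(p) paste(p, collapse = "|"))
  uk <- unique(key)
  idx <- match(key, uk)
  verts <- tri[!duplicated(key), , drop = FALSE]
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  trimesh(verts, faces, provenance = paste("read_stl:", basename(path)))
}

#' Write an STL file
#'
#' @param mesh An `mcdem_trimesh`.
#' @param path Output path.
#' @param binary Write binary STL (default FALSE = ASCII).
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, binary = FALSE) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- cc - a
  nrm <- cbind(
    e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
    e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
    e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  )
  nl <- sqrt(rowSums(nrm^2))
  nl[nl == 0] <- 1
  nrm <- nrm / nl
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(80), con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    for (k in seq_len(nrow(f))) {
      writeBin(as.numeric(c(nrm[k, ], a[k, ], b[k, ], cc[k, ])), con,
               size = 4, endian = "little")
      writeBin(raw(2), con)
    }
  } else {
    fmt <- function(p) sprintf("%.9g %.9g %.9g", p[1], p[2], p[3])
    out <- c("solid mcdem")
    for (k in seq_len(nrow(f))) {
      out <- c(
        out,
        paste("  facet normal", fmt(nrm[k, ])),
        "    outer loop",
        paste("      vertex", fmt(a[k, ])),
        paste("      vertex", fmt(b[k, ])),
        paste("      vertex", fmt(cc[k, ])),
        "    endloop",
        "  endfacet"
      )
    }
    out <- c(out, "endsolid mcdem")
    writeLines(out, path)
  }
  invisible(path)
}
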