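test_that("icosphere is watertight with the expected volume", {
  ms <- icosphere(3)
  expect_equal(nrow(ms$faces), 20 * 4^3)
  # inscribed-polyhedron volume slightly below the ball's
  expect_equal(mesh_volume(ms), 4 / 3 * pi, tolerance = 1e-2)
  # deleting a face breaks watertightness with a named edge
  expect_error(trimesh(ms$vertices, ms$faces[-1, ]), "watertight")
})

test_that("principal-box dimensions: sphere, box, rotation invariance", {
  ms <- icosphere(3)
  dims <- bounding_box_dimensions(ms)
  expect_equal(unname(dims), rep(2, 3), tolerance = 5e-3)

  # axis-aligned 4 x 2 x 1 box mesh
  v <- as.matrix(expand.grid(c(0, 4), c(0, 2), c(0, 1)))
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7),
    c(1, 2, 5), c(2, 6, 5), c(3, 7, 4), c(4, 7, 8),
    c(1, 5, 3), c(3, 5, 7), c(2, 4, 6), c(4, 8, 6)
  )
  box <- trimesh(v, f)
  expect_equal(mesh_volume(box), 8)
  expect_equal(unname(bounding_box_dimensions(box)), c(4, 2, 1))

  # arbitrary rotation leaves the box dimensions within 1%
  set.seed(7)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  box_rot <- trimesh(v %*% t(q), f, validate = FALSE)
  expect_equal(unname(bounding_box_dimensions(box_rot)), c(4, 2, 1),
               tolerance = 0.01)

  # sphere-cluster input with dilation by radii
  cl <- list(centers = rbind(c(0, 0, 0), c(1, 0, 0)), radii = c(0.5, 0.5))
  expect_equal(unname(bounding_box_dimensions(cl)), c(2, 1, 1))
})

test_that("shape descriptors and their identity", {
  d <- shape_descriptors(4, 2, 1)
  expect_equal(d$aspect_ratio, 0.25)
  expect_equal(d$elongation, 0.5)
  expect_equal(d$flatness, 0.5)
  expect_equal(d$aspect_ratio, d$elongation * d$flatness)
  s <- shape_descriptors(2, 2, 2)
  expect_equal(c(s$aspect_ratio, s$elongation, s$flatness), c(1, 1, 1))
  # reference triple: elongation 0.84, flatness 0.95 -> ASR ~ 0.8
  d2 <- shape_descriptors(1, 0.84, 0.84 * 0.95)
  expect_equal(d2$aspect_ratio, 0.798)
  expect_equal(d2$aspect_ratio, 0.8, tolerance = 0.01)
  expect_error(shape_descriptors(1, 2, 0.5))
})

test_that("random particle generation hits targets and is deterministic", {
  # irregularity 0 -> exact ellipsoid ratios
  m0 <- generate_random_particle(elongation = 0.84, flatness = 0.95,
                                 irregularity = 0, seed = 1)
  dims <- bounding_box_dimensions(m0)
  expect_equal(dims[["I"]] / dims[["L"]], 0.84, tolerance = 0.01)
  expect_equal(dims[["S"]] / dims[["I"]], 0.95, tolerance = 0.01)

  # same seed -> identical mesh; different seed -> different mesh
  m1 <- generate_random_particle(aspect_ratio = 0.71, irregularity = 0.15,
                                 seed = 42)
  m1b <- generate_random_particle(aspect_ratio = 0.71, irregularity = 0.15,
                                  seed = 42)
  expect_identical(m1$vertices, m1b$vertices)
  m2 <- generate_random_particle(aspect_ratio = 0.71, irregularity = 0.15,
                                 seed = 43)
  expect_false(identical(m1$vertices, m2$vertices))

  # measured ASR within 5% of targets for the reference triple
  for (asr in c(0.84, 0.71, 0.53)) {
    mm <- generate_random_particle(aspect_ratio = asr, irregularity = 0.12,
                                   seed = round(100 * asr))
    dd <- bounding_box_dimensions(mm)
    expect_equal(dd[["S"]] / dd[["L"]], asr, tolerance = 0.05)
  }
})

test_that("lattice fill: interior, non-overlapping, deterministic", {
  ms <- icosphere(2)
  fill <- fill_mesh_with_spheres(ms, resolution = 0.22, seed = 3)
  expect_gt(fill$count, 20)
  expect_true(all(points_in_mesh(fill$centers, ms)))
  # minimum center distance >= 2 r (touching, non-overlapping lattice)
  dmin <- min(dist(fill$centers))
  expect_gte(dmin, 2 * 0.22 * (1 - 1e-9))
  fill2 <- fill_mesh_with_spheres(ms, resolution = 0.22, seed = 3)
  expect_identical(fill$centers, fill2$centers)

  expect_error(fill_mesh_with_spheres(ms, resolution = 2, seed = 1),
               "coarse")
})

test_that("lattice fill of a ball at ~545 spheres covers 50-80% of volume", {
  ms <- icosphere(2)
  fill <- fill_mesh_with_spheres(ms, resolution = 545, seed = 3)
  expect_lt(abs(fill$count - 545) / 545, 0.1)
  rs <- fill$radii[1]
  # Monte-Carlo union-volume oracle over the ball
  set.seed(1)
  pts <- matrix(runif(3 * 30000, -1, 1), ncol = 3)
  pts <- pts[rowSums(pts^2) < 1, ]
  inside_any <- rep(FALSE, nrow(pts))
  for (k in seq_len(fill$count)) {
    d2 <- (pts[, 1] - fill$centers[k, 1])^2 +
      (pts[, 2] - fill$centers[k, 2])^2 +
      (pts[, 3] - fill$centers[k, 3])^2
    inside_any <- inside_any | (d2 < rs^2)
  }
  frac <- mean(inside_any)
  expect_gt(frac, 0.5)
  expect_lt(frac, 0.8)
})

test_that("adaptive fill covers a box to the requested fraction", {
  v <- as.matrix(expand.grid(c(0, 4), c(0, 2), c(0, 1)))
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7),
    c(1, 2, 5), c(2, 6, 5), c(3, 7, 4), c(4, 7, 8),
    c(1, 5, 3), c(3, 5, 7), c(2, 4, 6), c(4, 8, 6)
  )
  box <- trimesh(v, f)
  fill <- fill_mesh_with_spheres(box, resolution = 20, mode = "grid_adaptive",
                                 seed = 2, coverage = 0.95,
                                 min_radius_frac = 0.02)
  expect_gte(fill$coverage, 0.95)
  expect_true(all(points_in_mesh(fill$centers, box)))
  # spheres stay inside: center-to-surface distance >= radius (grid tol)
  dsurf <- point_mesh_distance(fill$centers, box)
  expect_true(all(dsurf >= fill$radii - 1e-9))
})

test_that("STL round trips preserve geometry in both dialects", {
  ms <- generate_random_particle(aspect_ratio = 0.8, irregularity = 0.1,
                                 seed = 5, subdiv = 2)
  fa <- tempfile(fileext = ".stl")
  fb <- tempfile(fileext = ".stl")
  write_stl(ms, fa, binary = FALSE)
  write_stl(ms, fb, binary = TRUE)
  ma <- read_stl(fa)
  mb <- read_stl(fb)
  expect_equal(nrow(ma$faces), nrow(ms$faces))
  expect_equal(nrow(mb$faces), nrow(ms$faces))
  expect_equal(mesh_volume(ma), mesh_volume(ms), tolerance = 1e-6)
  expect_equal(mesh_volume(mb), mesh_volume(ms), tolerance = 1e-6)
  # identical descriptors from the two dialects
  expect_equal(bounding_box_dimensions(ma), bounding_box_dimensions(mb),
               tolerance = 1e-6)
  # a mesh with a deleted face fails validation on read
  bad <- ms
  bad$faces <- bad$faces[-10, ]
  fc <- tempfile(fileext = ".stl")
  write_stl(bad, fc)
  expect_error(read_stl(fc), "watertight")
  unlink(c(fa, fb, fc))
})
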