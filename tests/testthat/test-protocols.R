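dm <- default_materials()

test_that("packing fraction: lattice, union semantics, MC oracle", {
  # simple-cubic lattice of touching unit spheres fills pi/6 of its cell
  g <- as.matrix(expand.grid(1:3, 1:3, 1:3)) * 2 - 1
  region <- list(lo = c(0, 0, 0), hi = c(6, 6, 6))
  expect_equal(packing_fraction(g, 1, region, method = "analytic"), pi / 6)

  # single sphere inscribed in its circumscribing cube
  expect_equal(packing_fraction(rbind(c(0, 0, 0)), 1,
                                list(lo = c(-1, -1, -1), hi = c(1, 1, 1)),
                                method = "analytic"), pi / 6)

  # coincident spheres counted once under the MC union route
  pf2 <- packing_fraction(rbind(c(0, 0, 0), c(0, 0, 0)), 1,
                          list(lo = c(-1, -1, -1), hi = c(1, 1, 1)),
                          method = "mc", n_samples = 2e5, seed = 1)
  expect_equal(pf2, pi / 6, tolerance = 0.01)

  # random 50-sphere case: analytic equals the MC hit-count within 3 SE
  set.seed(31)
  x <- matrix(runif(150, 0.1, 0.9), 50, 3)
  r <- runif(50, 0.01, 0.04)
  region3 <- list(lo = c(0, 0, 0), hi = c(1, 1, 1))
  pa <- packing_fraction(x, r, region3, method = "analytic")
  pm <- packing_fraction(x, r, region3, method = "mc", n_samples = 4e5,
                         seed = 2)
  se <- sqrt(pa * (1 - pa) / 4e5)
  # overlaps make the union smaller than the sum; tolerate the overlap bias
  expect_lt(abs(pm - pa), max(3 * se, 0.05 * pa))

  expect_error(packing_fraction(x, r, list(lo = c(0, 0, 0), hi = c(0, 1, 1))),
               "empty region")
})

test_that("random sequential insertion never overlaps, errors when jammed", {
  r <- rep(1e-4, 60)
  x <- insert_spheres_rsa(r, lo = c(0, 0, 1e-4), hi = c(1e-3, 1e-3, 2e-3),
                          seed = 3)
  prs <- brute_pairs_r(x, r, c(0, 0, 0), c(1e-3, 1e-3, 2e-3),
                       c(TRUE, TRUE, FALSE), skin = 0)
  expect_equal(nrow(prs), 0L)
  expect_error(
    insert_spheres_rsa(rep(2e-4, 100), lo = c(0, 0, 2e-4),
                       hi = c(1e-3, 1e-3, 1e-3), seed = 1, max_tries = 200),
    "insertion failed")
})

test_that("gravity fill reaches a plausible settled packing and is seeded", {
  fill <- suppressWarnings(run_gravity_fill(n = 40, seed = 7))
  expect_gt(fill$packing_fraction, 0.4)
  expect_lt(fill$packing_fraction, 0.7)
  expect_true(all(fill$state$x[, 3] > 0))
  expect_true(all(fill$diameters >= 180e-6 - 1e-12))
  # repeatable scalars for the same seed
  fill2 <- suppressWarnings(run_gravity_fill(n = 40, seed = 7))
  expect_identical(fill$packing_fraction, fill2$packing_fraction)
  expect_identical(fill$height, fill2$height)
})

test_that("purely Hertzian bed unloads along its loading curve", {
  # elastic reversibility of the contact law without rearrangement noise:
  # a simple-cubic column of touching spheres between plates, frictionless,
  # loaded to 4% strain and unloaded; the two branches must coincide
  r <- 1e-4
  g <- as.matrix(expand.grid(0:2, 0:2, 0:3))
  x <- cbind(g[, 1] * 2 * r + r, g[, 2] * 2 * r + r, g[, 3] * 2 * r + r)
  m <- material(2.58e8, 0.3, 1541.1, restitution = 0.9)
  L <- 6 * r
  h0 <- 8 * r
  st <- dem_state(x = x, r = r, materials = list(m, m),
                  walls = list(
                    plane_wall(c(0, 0, 1), c(0, 0, 0), material = 2),
                    plane_wall(c(0, 0, -1), c(0, 0, h0), c(0, 0, -0.005),
                               material = 2)
                  ),
                  domain = sim_domain(c(0, 0, -1e-4), c(L, L, 1e-2),
                                      periodic = c(TRUE, TRUE, FALSE)),
                  model = contact_model("hertz"))
  dt <- critical_timestep(r, list(m))
  n_steps <- ceiling(0.04 * h0 / (0.005 * dt))
  rec <- max(1, n_steps %/% 100)
  out <- dem_run(st, dt, n_steps, record_every = rec)
  st2 <- out$state
  st2$walls[[2]]$velocity <- c(0, 0, 0.005)
  out2 <- dem_run(st2, dt, n_steps, record_every = rec)
  strain_of <- function(recs) 1 - (recs$wall_point[, 3, 2]) / h0
  stress_of <- function(recs) abs(recs$wall_force[, 3, 2]) / L^2
  grid <- seq(0.015, 0.035, by = 0.002)
  load <- approx(strain_of(out$records), stress_of(out$records), grid)$y
  unload <- approx(strain_of(out2$records), stress_of(out2$records), grid)$y
  expect_lt(rms_rel(unload, load), 0.02)
})

test_that("elastoplastic compaction retains residual strain at zero stress", {
  fill <- suppressWarnings(run_gravity_fill(n = 40, seed = 7))
  res <- run_uniaxial_compaction(fill, target_strain = 0.35,
                                 plate_speed = 0.01)
  su <- res[res$phase == "UNLOADING", ]
  smax <- max(res$stress)
  relaxed <- su[su$stress < 1e-4 * smax, ]
  expect_gt(nrow(relaxed), 0)
  expect_gt(relaxed$strain[1], 0.02)  # stress vanishes well before strain does
})

test_that("loading branch of a bonded/spherical bed is near-monotone", {
  fill <- suppressWarnings(run_gravity_fill(n = 40, seed = 8))
  res <- run_uniaxial_compaction(fill, target_strain = 0.4,
                                 plate_speed = 0.01, unload = FALSE)
  ld <- res[res$phase == "LOADING" & res$stress > 0.02 * max(res$stress), ]
  drops <- (head(ld$stress, -1) - tail(ld$stress, -1)) / head(ld$stress, -1)
  expect_lt(max(drops), 0.05)
})

test_that("non-spherical BMS bodies settle looser than spheres", {
  # ordering assertion only: same count and sizes, one irregular shape class
  ms <- generate_random_particle(aspect_ratio = 0.71, irregularity = 0.12,
                                 seed = 5)
  fl <- fill_mesh_with_spheres(ms, resolution = 60, seed = 2)
  dims <- bounding_box_dimensions(list(centers = fl$centers,
                                       radii = fl$radii))
  ctr <- colMeans(fl$centers)
  tpl <- list(centers = sweep(fl$centers, 2, ctr) / dims[["L"]],
              radii = fl$radii / dims[["L"]])
  fit1 <- fit_lognormal_to_quantiles(psd_spec(900, 1000, 1100))
  f_sph <- suppressWarnings(run_gravity_fill(
    n = 10, fit = fit1, cross_section = 4e-3, seed = 3, max_steps = 2e5))
  f_tpl <- suppressWarnings(run_gravity_fill(
    n = 10, fit = fit1, cross_section = 4e-3, templates = list(tpl),
    seed = 3, max_steps = 2e5))
  expect_lt(f_tpl$packing_fraction, f_sph$packing_fraction)
  # bonded bodies stay intact: every body is one connected bond component
  st <- f_tpl$state
  for (b in unique(st$body)) {
    idx <- which(st$body == b)
    sub <- st$bonds[st$bonds$i %in% idx & st$bonds$j %in% idx, ]
    comp <- bond_components(length(idx),
                            data.frame(i = match(sub$i, idx),
                                       j = match(sub$j, idx)))
    expect_equal(max(comp), 1L)
  }
})
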