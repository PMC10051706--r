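dm <- default_materials()

test_that("neighbor search equals the R brute-force scan, minimum image", {
  set.seed(21)
  for (rep in 1:4) {
    n <- 150
    lo <- c(0, 0, 0); hi <- c(1e-3, 1e-3, 2e-3)
    per <- c(TRUE, TRUE, FALSE)
    x <- cbind(runif(n, 0, 1e-3), runif(n, 0, 1e-3), runif(n, 0, 2e-3))
    r <- runif(n, 3e-5, 6e-5)
    dom <- sim_domain(lo, hi, per)
    skin <- 0.2 * min(r)
    got_cell <- neighbor_pairs(x, r, dom, skin, method = "cell")
    got_brute <- neighbor_pairs(x, r, dom, skin, method = "brute")
    ref <- brute_pairs_r(x, r, lo, hi, per, skin)
    key <- function(m) sort(paste(m[, 1], m[, 2]))
    expect_identical(key(got_cell), key(ref))
    expect_identical(key(got_brute), key(ref))
  }
  # two spheres touching across the periodic x face
  x2 <- rbind(c(0.02e-3, 0.5e-3, 0.5e-3), c(0.98e-3, 0.5e-3, 0.5e-3))
  prs <- neighbor_pairs(x2, c(3e-5, 3e-5), sim_domain(c(0, 0, 0),
                        c(1e-3, 1e-3, 1e-3), c(TRUE, FALSE, FALSE)))
  expect_equal(nrow(prs), 1L)
  # empty system
  expect_equal(nrow(neighbor_pairs(matrix(numeric(), ncol = 3), numeric())),
               0L)
  # oversized sphere in a periodic box is refused
  expect_error(neighbor_pairs(x2, c(4e-4, 4e-4), sim_domain(c(0, 0, 0),
               c(1e-3, 1e-3, 1e-3), c(TRUE, FALSE, FALSE))),
               "periodic")
})

test_that("Rayleigh timestep formula and scalings", {
  m <- material(18.5e6, 0.46, 2000)
  g <- 18.5e6 / (2 * (1 + 0.46))
  t_r <- pi * 1e-3 * sqrt(2000 / g) / (0.1631 * 0.46 + 0.8766)
  expect_equal(critical_timestep(1e-3, m, safety_factor = 1), t_r)
  # linear in r; ~1/sqrt(G) in stiffness
  expect_equal(critical_timestep(5e-4, m), critical_timestep(1e-3, m) / 2)
  m100 <- material(18.5e8, 0.46, 2000)
  expect_equal(critical_timestep(1e-3, m) / critical_timestep(1e-3, m100),
               10)
  expect_error(critical_timestep(numeric(), m), "sphere")
})

test_that("free-fall trajectory matches the closed form; zero forces exact", {
  m <- dm$mcc
  st <- dem_state(x = rbind(c(0, 0, 0)), r = 1e-4, materials = list(m),
                  gravity = c(0, 0, -9.81),
                  domain = sim_domain(c(-1, -1, -1), c(1, 1, 1)))
  dt <- 1e-5
  out <- dem_run(st, dt, 1000)
  t_tot <- 1000 * dt
  expect_equal(out$state$x[1, 3], -0.5 * 9.81 * t_tot^2, tolerance = 1e-10)

  st2 <- dem_state(x = rbind(c(0, 0, 0)), r = 1e-4, materials = list(m),
                   v = rbind(c(0.25, 0, 0)),
                   domain = sim_domain(c(-1, -1, -1), c(1, 1, 1)))
  out2 <- dem_run(st2, dt, 1000)
  expect_equal(out2$state$x[1, 1], 0.25 * t_tot, tolerance = 1e-12)
})

test_that("undamped collision is time-reversal symmetric", {
  m <- material(18.5e6, 0.46, 2000, restitution = 1)
  r <- 0.01
  st <- dem_state(x = rbind(c(-0.0101, 0, 0), c(0.0101, 0, 0)), r = r,
                  materials = list(m),
                  v = rbind(c(0.3, 0, 0), c(-0.3, 0, 0)),
                  domain = sim_domain(c(-1, -1, -1), c(1, 1, 1)))
  dt <- critical_timestep(rep(r, 2), list(m), safety_factor = 0.02)
  n1 <- 5000
  out <- dem_run(st, dt, n1)
  mid <- out$state
  mid$v <- -mid$v
  back <- dem_run(mid, dt, n1)
  expect_equal(back$state$x, st$x, tolerance = 1e-6)
  expect_equal(-back$state$v, st$v, tolerance = 1e-6)
})

test_that("cell-list and brute-force trajectories are bit-identical", {
  set.seed(5)
  n <- 120
  x <- cbind(runif(n, 0, 1e-3), runif(n, 0, 1e-3), runif(n, 1e-4, 1.5e-3))
  mk <- function() dem_state(
    x = x, r = 4e-5, materials = list(dm$mcc, dm$mcc_wall),
    v = matrix(rnorm(3 * n, 0, 0.01), n, 3),
    walls = list(plane_wall(c(0, 0, 1), c(0, 0, 0), material = 2)),
    domain = sim_domain(c(0, 0, -1e-4), c(1e-3, 1e-3, 2e-3),
                        periodic = c(TRUE, TRUE, FALSE)),
    gravity = c(0, 0, -9.81)
  )
  set.seed(5); st_a <- mk()
  set.seed(5); st_b <- mk()
  dt <- critical_timestep(4e-5, dm$mcc, safety_factor = 0.1)
  out_a <- dem_run(st_a, dt, 1000, neighbor = "cell")
  out_b <- dem_run(st_b, dt, 1000, neighbor = "brute")
  expect_identical(out_a$state$x, out_b$state$x)
  expect_identical(out_a$state$v, out_b$state$v)
  expect_identical(out_a$state$w, out_b$state$w)
})

test_that("determinism: identical state yields a bit-identical trajectory", {
  set.seed(11)
  n <- 40
  x <- cbind(runif(n, 0, 5e-4), runif(n, 0, 5e-4), runif(n, 1e-4, 1e-3))
  mk <- function() dem_state(
    x = x, r = 3e-5, materials = list(dm$mcc, dm$mcc_wall),
    walls = list(plane_wall(c(0, 0, 1), c(0, 0, 0), material = 2)),
    domain = sim_domain(c(0, 0, -1e-4), c(5e-4, 5e-4, 1.5e-3),
                        periodic = c(TRUE, TRUE, FALSE)),
    gravity = c(0, 0, -9.81)
  )
  dt <- critical_timestep(3e-5, dm$mcc, safety_factor = 0.1)
  o1 <- dem_run(mk(), dt, 2000)
  o2 <- dem_run(mk(), dt, 2000)
  expect_identical(o1$state$x, o2$state$x)
  expect_identical(o1$state$v, o2$state$v)
})

test_that("closed-system momentum drift stays below 1e-10 relative", {
  set.seed(13)
  n <- 60
  m <- material(2.58e8, 0.3, 1541, restitution = 0.7, sliding_friction = 0.4,
                rolling_friction = 0.1)
  x <- cbind(runif(n, 0, 1e-3), runif(n, 0, 1e-3), runif(n, 0, 1e-3))
  st <- dem_state(x = x, r = 4e-5, materials = list(m),
                  v = matrix(rnorm(3 * n, 0, 0.05), n, 3),
                  domain = sim_domain(c(0, 0, 0), c(1e-3, 1e-3, 1e-3),
                                      periodic = c(TRUE, TRUE, TRUE)))
  p0 <- colSums(st$m * st$v)
  pscale <- sum(st$m) * 0.05
  dt <- critical_timestep(4e-5, m, safety_factor = 0.1)
  out <- dem_run(st, dt, 10000)
  p1 <- colSums(out$state$m * out$state$v)
  expect_lt(max(abs(p1 - p0)) / pscale, 1e-10)
})

test_that("wall contacts: touch point, static plate balance, stress", {
  m <- dm$rubber
  # exactly touching -> zero force
  st <- dem_state(x = rbind(c(0, 0, 0.01)), r = 0.01,
                  materials = list(m, dm$rubber_wall),
                  walls = list(plane_wall(c(0, 0, 1), c(0, 0, 0),
                                          material = 2)),
                  domain = sim_domain(c(-1, -1, -1), c(1, 1, 1)))
  wf <- wall_contact_forces(st)
  expect_equal(wf$wall_forces[1, ], c(0, 0, 0))

  # sphere squeezed between two plates: reactions balance, and the
  # sphere-plane force uses R* = r
  delta <- 2e-4
  st2 <- dem_state(x = rbind(c(0, 0, 0.01 - delta)), r = 0.01,
                   materials = list(m, dm$rubber_wall),
                   walls = list(
                     plane_wall(c(0, 0, 1), c(0, 0, 0), material = 2),
                     plane_wall(c(0, 0, -1), c(0, 0, 0.02 - 2 * delta),
                                material = 2)
                   ),
                   domain = sim_domain(c(-1, -1, -1), c(1, 1, 1)))
  wf2 <- wall_contact_forces(st2)
  fb <- wf2$wall_forces[1, 3]
  ft <- wf2$wall_forces[2, 3]
  expect_equal(abs(fb + ft) / abs(fb), 0, tolerance = 1e-6)
  f_ref <- hertz_closed_form(m$young_modulus, m$poisson_ratio,
                             1e9, 0.46, 0.01, Inf, delta)
  expect_equal(abs(fb), f_ref, tolerance = 1e-9)

  # axial stress arithmetic: 30 N on 1 mm^2 is 30 MPa
  expect_equal(measure_axial_stress(c(0, 0, 30), 1e-6), 30e6)
  expect_equal(measure_axial_stress(30, 1e-6), 30e6)
  expect_error(measure_axial_stress(30, 0), "positive")
})
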