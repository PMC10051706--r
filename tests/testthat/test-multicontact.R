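test_that("contact area is the Hertz circle", {
  expect_identical(contact_area(0, 0.005), 0)
  expect_equal(contact_area(1e-4, 0.005), pi * 5e-7)
  # linear in the overlap
  expect_equal(contact_area(2e-4, 0.005) / contact_area(1e-4, 0.005), 2)
})

test_that("particle stress accumulation and pressure follow the virial", {
  # no contacts -> zero stress
  s <- matrix(0, 3, 3)
  expect_equal(particle_pressure(s), 0)
  expect_equal(particle_pressure(diag(3e6, 3)), 3e6)

  # single contact: compression-positive trace = -(r . F) / V
  r <- 0.01
  v <- 4 / 3 * pi * r^3
  ctr <- c(0, 0, 0)
  cp <- c(0, 0, r)
  f <- c(0, 0, -2)   # pushing down on the top of the sphere
  s1 <- accumulate_particle_stress(s, ctr, r, cp, f)
  expect_equal(sum(diag(s1)), -sum((cp - ctr) * f) / v)
  expect_equal(s1, t(s1))

  # two opposing diametral forces +-F z: P = 2 |F| r / (3V), compression +
  s2 <- accumulate_particle_stress(s1, ctr, r, c(0, 0, -r), c(0, 0, 2))
  expect_equal(particle_pressure(s2), 2 * 2 * r / (3 * v))
  expect_gt(particle_pressure(s2), 0)

  # hydrostatic compression by six symmetric contacts of magnitude F:
  # P equals the brute-force virial sum
  s6 <- matrix(0, 3, 3)
  fmag <- 3.7
  virial <- matrix(0, 3, 3)
  for (dirn in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                    c(0, 0, 1), c(0, 0, -1))) {
    cp <- r * dirn
    f <- -fmag * dirn
    s6 <- accumulate_particle_stress(s6, ctr, r, cp, f)
    virial <- virial - outer(cp, f)   # independent raw sum, sign-flipped
  }
  expect_equal(particle_pressure(s6),
               sum(diag(virial)) / (3 * v))
  expect_equal(particle_pressure(s6), 6 * fmag * r / (3 * v) / 1,
               tolerance = 1e-12)
})

test_that("elastoplastic branches reproduce an independent scalar oracle", {
  k1 <- 1e6
  par <- elastoplastic_params(k1, k2_ratio = 5, kc = 0.5 * k1)
  # load to 1e-4, unload to 0, reload to 1.5e-4
  dseq <- c(seq(1e-6, 1e-4, length.out = 60),
            seq(1e-4, 1e-6, length.out = 60),
            seq(1e-6, 1.5e-4, length.out = 80))
  oracle <- ep_scalar_oracle(dseq, k1, 5 * k1, 0.5 * k1)
  hist <- plastic_history()
  got <- numeric(length(dseq))
  for (s in seq_along(dseq)) {
    out <- elastoplastic_normal_force(dseq[s], hist, par)
    hist <- out$hist
    got[s] <- out$force
  }
  expect_equal(got, oracle, tolerance = 1e-12)
  # hysteresis: unloading path below loading path, residual overlap > 0
  expect_gt(hist$plastic_overlap, 0)
  load_f <- got[60]
  unload_f <- got[61]
  expect_lt(unload_f, load_f)
})

test_that("first loading is Hertz with stiffness k1; k2 = k1 degenerates", {
  k1 <- 2.2e6
  par <- elastoplastic_params(k1, k2_ratio = 5)
  out <- elastoplastic_normal_force(3e-5, plastic_history(), par)
  expect_equal(out$force, k1 * (3e-5)^1.5)
  expect_identical(out$branch, 1L)

  # purely elastic limit: a full cycle retraces the k1 curve exactly
  pe <- elastoplastic_params(k1, k2_ratio = 1)
  h <- plastic_history()
  for (d in c(1e-5, 5e-5, 2e-5, 4e-5, 1e-6)) {
    o <- elastoplastic_normal_force(d, h, pe)
    h <- o$hist
    expect_identical(o$force, k1 * d^1.5)
  }
  expect_equal(h$plastic_overlap, 0)
})

test_that("branch switches are continuous in the overlap", {
  k1 <- 1e6
  par <- elastoplastic_params(k1, k2_ratio = 4, kc = 0.8 * k1, f0 = -1e-4)
  # load beyond the elastic point, then sweep down finely across both
  # branch boundaries; force increments must scale with the sweep step
  h <- plastic_history()
  h <- elastoplastic_normal_force(2e-4, h, par)$hist
  dgrid <- seq(2e-4, 1e-6, length.out = 4000)
  f <- numeric(length(dgrid))
  for (s in seq_along(dgrid)) {
    o <- elastoplastic_normal_force(dgrid[s], h, par)
    h <- o$hist
    f[s] <- o$force
  }
  jumps <- abs(diff(f))
  scale <- max(abs(f))
  # a discontinuity would show as a jump far above the smooth increment
  expect_lt(max(jumps), 50 * stats::median(jumps) + 1e-9 * scale)
})

test_that("non-local term arithmetic and coordination stiffening", {
  par <- elastoplastic_params(1e6, beta = 1.3, poisson = 0.3)
  out <- elastoplastic_normal_force(1e-4, plastic_history(), par,
                                    area = 1e-9, pressure = 1e6)
  base <- elastoplastic_normal_force(1e-4, plastic_history(), par)$force
  expect_equal(out$force - base, 1.3 * 0.3 * 1e-9 * 1e6)  # 3.9e-4 N

  # n symmetric neighbors: with compression-positive pressure the total
  # force on the confined center exceeds n times the isolated-pair force
  r <- 1e-4
  v <- 4 / 3 * pi * r^3
  delta <- 1e-5
  f_iso <- elastoplastic_normal_force(delta, plastic_history(), par)$force
  for (n in c(4, 6)) {
    # center pressure from n contacts each carrying ~f on the center
    p_center <- n * f_iso * (r - delta / 2) / (3 * v)
    f_conf <- elastoplastic_normal_force(
      delta, plastic_history(), par,
      area = contact_area(delta, r / 2), pressure = p_center / 2
    )$force
    expect_gt(n * f_conf, n * f_iso)
  }
})

test_that("engine elastoplastic bed shows hysteresis and residual strain", {
  # a tiny bed: load-unload with the plastic law leaves residual strain;
  # the purely Hertzian bed retraces elastically
  m <- material(2.58e8, 0.3, 1541.1, restitution = 0.352,
                sliding_friction = 0.3)
  r <- 1e-4
  xs <- as.matrix(expand.grid(c(-1, 1) * r, c(-1, 1) * r, c(1, 3) * r * 0.999))
  st0 <- dem_state(
    x = xs, r = r, materials = list(m, m),
    material_id = rep(1L, 8),
    walls = list(plane_wall(c(0, 0, 1), c(0, 0, 0), material = 2)),
    domain = sim_domain(c(-5 * r, -5 * r, -1), c(5 * r, 5 * r, 1)),
    model = contact_model("elastoplastic", k2_ratio = 5)
  )
  h0 <- max(xs[, 3] + r)
  v <- 0.02
  st0$walls[[2]] <- unclass(plane_wall(c(0, 0, -1), c(0, 0, h0),
                                       c(0, 0, -v), material = 2))
  dt <- critical_timestep(r, list(m))
  n_steps <- ceiling(0.25 * h0 / (v * dt))
  out <- dem_run(st0, dt, n_steps, record_every = max(1, n_steps %/% 50))
  st1 <- out$state
  f_loaded <- abs(out$records$wall_force[dim(out$records$wall_force)[1], 3, 2])
  expect_gt(f_loaded, 0)
  st1$walls[[2]]$velocity <- c(0, 0, v)
  out2 <- dem_run(st1, dt, n_steps, record_every = max(1, n_steps %/% 50))
  # force returns to zero before the plate returns to h0: residual strain
  fz <- abs(out2$records$wall_force[, 3, 2])
  z <- out2$records$wall_point[, 3, 2]
  first_zero <- which(fz < 1e-9 * f_loaded)[1]
  expect_false(is.na(first_zero))
  expect_lt(z[first_zero], h0 * 0.999)
})
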