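dm <- default_materials()

test_that("Hertz normal force follows kn * delta^{3/2}", {
  m <- dm$rubber
  p <- effective_pair_properties(m, m, 0.01, 0.01)
  # zero at zero overlap / separation
  g0 <- contact_geometry(c(0, 0, 0.02), c(0, 0, 0), 0.01, 0.01)
  expect_identical(hertz_normal_force(g0, p), c(0, 0, 0))

  g1 <- contact_geometry(c(0, 0, 0.019), c(0, 0, 0), 0.01, 0.01)
  f1 <- hertz_normal_force(g1, p)
  expect_equal(f1[3], p$normal_stiffness * 1e-3^1.5)
  expect_equal(f1[3], 34.97, tolerance = 1e-3)   # ~35 N at 1 mm overlap
  expect_equal(f1[1:2], c(0, 0))

  # power-law exponent: doubling the overlap multiplies by 2^1.5
  g2 <- contact_geometry(c(0, 0, 0.018), c(0, 0, 0), 0.01, 0.01)
  f2 <- hertz_normal_force(g2, p)
  expect_equal(f2[3] / f1[3], 2^1.5)

  # damping opposes approach and never makes the force tensile
  gap <- contact_geometry(c(0, 0, 0.0199), c(0, 0, 0), 0.01, 0.01,
                          v_i = c(0, 0, 1))  # separating fast
  expect_identical(hertz_normal_force(gap, p, restitution = 0.3), c(0, 0, 0))
})

test_that("tangential force accumulates, saturates at the Coulomb cap", {
  m <- dm$rubber
  p <- effective_pair_properties(m, m, 0.01, 0.01)
  geom <- contact_geometry(c(0, 0, 0.0195), c(0, 0, 0), 0.01, 0.01,
                           v_i = c(1e-3, 0, 0))
  hist <- tangential_history()
  # zero spring, zero tangential velocity -> zero force
  g_still <- contact_geometry(c(0, 0, 0.0195), c(0, 0, 0), 0.01, 0.01)
  expect_identical(
    tangential_force(g_still, hist, p, 10, mu = 0.5)$force, c(0, 0, 0))

  # monotonic loading grows then saturates exactly at mu * Fn = 5 N
  dt <- 1e-3
  fmags <- numeric(400)
  for (s in 1:400) {
    out <- tangential_force(geom, hist, p, 10, mu = 0.5, dt = dt)
    hist <- out$hist
    fmags[s] <- sqrt(sum(out$force^2))
    expect_lte(fmags[s], 5 + 1e-9)
  }
  expect_gt(fmags[10], 0)
  expect_lt(fmags[10], 5)
  expect_equal(fmags[400], 5, tolerance = 1e-9)
  # capped force opposes the motion
  expect_lt(tangential_force(geom, hist, p, 10, mu = 0.5)$force[1], 0)

  # zero normal force -> zero tangential force, spring reset
  out0 <- tangential_force(geom, hist, p, 0, mu = 0.5)
  expect_identical(out0$force, c(0, 0, 0))
  expect_identical(out0$hist$spring, c(0, 0, 0))
})

test_that("as-printed tangential law uses the 3/2 power", {
  m <- dm$rubber
  p <- effective_pair_properties(m, m, 0.01, 0.01)
  geom <- contact_geometry(c(0, 0, 0.0195), c(0, 0, 0), 0.01, 0.01)
  h <- tangential_history()
  h$spring <- c(1e-5, 0, 0)
  f <- tangential_force(geom, h, p, 1e9, mu = 10, law = "as_printed")$force
  expect_equal(-f[1], p$tangential_stiffness_coeff * (1e-5)^1.5)
})

test_that("CDT rolling torque: magnitude, direction, zero cases", {
  m <- dm$rubber
  p <- effective_pair_properties(m, m, 0.01, 0.01)
  # |tau| = mu_r * R* * Fn; antiparallel to omega_rel
  tau <- rolling_torque(c(2, 0, 0), c(0, 0, 0), 0.3, p, 1)
  expect_equal(tau, c(-0.3 * 0.005 * 1, 0, 0))
  w1 <- c(0.3, -1.2, 0.5); w2 <- c(-0.1, 0.4, 0.2)
  tau2 <- rolling_torque(w1, w2, 0.3, p, 2)
  expect_equal(sum(tau2 * (w1 - w2)) / sqrt(sum(tau2^2)) /
                 sqrt(sum((w1 - w2)^2)), -1)
  # stationary relative spin or zero normal force -> zero torque
  expect_identical(rolling_torque(c(1, 1, 1), c(1, 1, 1), 0.3, p, 5),
                   c(0, 0, 0))
  expect_identical(rolling_torque(c(1, 0, 0), c(0, 0, 0), 0.3, p, 0),
                   c(0, 0, 0))
})

test_that("quasi-static engine force-displacement matches kn d^{3/2} to 0.5%", {
  # drive two spheres together slowly and compare the wall-free pair force
  # constant approach enforced by near-infinite inertia (driven displacement)
  m <- material(18.5e6, 0.46, 2000, restitution = 1)
  r <- 0.01
  p <- effective_pair_properties(m, m, r, r)
  v0 <- 1e-3
  st <- dem_state(
    x = rbind(c(-r, 0, 0), c(r, 0, 0)), r = r, materials = list(m),
    v = rbind(c(v0, 0, 0), c(-v0, 0, 0)), mass = 1e5,
    domain = sim_domain(c(-1, -1, -1), c(1, 1, 1))
  )
  dt <- critical_timestep(rep(r, 2), list(m))
  # probe the force at two depths up to delta/R* = 0.05
  for (target in c(0.025, 0.05) * p$eff_radius) {
    delta_now <- 2 * r - (st$x[2, 1] - st$x[1, 1])
    n_steps <- ceiling((target - delta_now) / (2 * v0 * dt))
    out <- dem_run(st, dt, n_steps)
    st <- out$state
    delta <- 2 * r - (st$x[2, 1] - st$x[1, 1])
    expect_gt(delta, 0.9 * target)
    f_engine <- abs(st$forces[1, 1])
    expect_equal(f_engine, p$normal_stiffness * delta^1.5, tolerance = 5e-3)
  }
})

test_that("undamped two-sphere oscillation conserves energy within 0.1%", {
  # periodic box: the pair re-collides ~10 times; total energy (KE + Hertz PE)
  # tracked at the recorded states
  m <- material(18.5e6, 0.46, 2000, restitution = 1)
  r <- 0.01
  p <- effective_pair_properties(m, m, r, r)
  st <- dem_state(
    x = rbind(c(0.005, 0, 0), c(0.035, 0, 0)), r = r, materials = list(m),
    v = rbind(c(0.3, 0, 0), c(-0.3, 0, 0)),
    domain = sim_domain(c(0, -0.02, -0.02), c(0.06, 0.02, 0.02),
                        periodic = c(TRUE, TRUE, TRUE))
  )
  dt <- critical_timestep(rep(r, 2), list(m), safety_factor = 0.1)
  e0 <- 0.5 * st$m[1] * 2 * 0.3^2
  es <- numeric(30)
  for (k in 1:30) {
    out <- dem_run(st, dt, 2000)
    st <- out$state
    dx <- abs(st$x[2, 1] - st$x[1, 1])
    dx <- min(dx, 0.06 - dx)
    delta <- max(0, 2 * r - dx)
    pe <- 2 / 5 * p$normal_stiffness * delta^2.5
    es[k] <- 0.5 * st$m[1] * sum(st$v^2) + pe
  }
  expect_lt(max(abs(es - e0)) / e0, 1e-3)
})

test_that("Newton's third law holds for oblique frictional pair contacts", {
  m <- material(2.58e8, 0.3, 1541, restitution = 0.5, sliding_friction = 0.5,
                rolling_friction = 0.2)
  set.seed(42)
  for (rep in 1:5) {
    x1 <- runif(3, -1e-4, 1e-4)
    dirn <- rnorm(3); dirn <- dirn / sqrt(sum(dirn^2))
    x2 <- x1 + dirn * 1.9e-4
    st <- dem_state(
      x = rbind(x1, x2), r = 1e-4, materials = list(m),
      v = matrix(rnorm(6, 0, 0.1), 2, 3), w = matrix(rnorm(6, 0, 50), 2, 3),
      domain = sim_domain(c(-1, -1, -1), c(1, 1, 1))
    )
    out <- dem_run(st, 1e-9, 0)   # static force evaluation
    expect_true(all(abs(out$state$forces[1, ] + out$state$forces[2, ]) <
                      1e-12 * max(abs(out$state$forces))))
  }
})
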