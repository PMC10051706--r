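# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths wherever the test compares against them.

# closed-form Hertz pair force magnitude
hertz_closed_form <- function(E1, nu1, E2, nu2, r1, r2, delta) {
  estar <- 1 / ((1 - nu1^2) / E1 + (1 - nu2^2) / E2)
  rstar <- if (is.infinite(r2)) r1 else r1 * r2 / (r1 + r2)
  (4 / 3) * estar * sqrt(rstar) * delta^1.5
}

# pure-R velocity-Verlet integration of a head-on two-sphere Hertz collision
# with the package's damping coefficients (used as the COR oracle)
collide_two_spheres_r <- function(mat, r, v0, dt, n_steps,
                                  restitution = mat$restitution) {
  p <- effective_pair_properties(mat, mat, r, r)
  m <- mat$density * 4 / 3 * pi * r^3
  x1 <- -r - 1e-6; x2 <- r + 1e-6
  v1 <- v0; v2 <- -v0
  fpair <- function(x1, x2, v1, v2) {
    delta <- 2 * r - (x2 - x1)
    if (delta <= 0) return(0)
    gam <- damping_coefficients(p, restitution, delta)[["gamma_n"]]
    f <- p$normal_stiffness * delta^1.5 + gam * (v1 - v2)
    max(f, 0)
  }
  a1 <- -fpair(x1, x2, v1, v2) / m
  for (s in seq_len(n_steps)) {
    v1 <- v1 + 0.5 * dt * a1; v2 <- v2 - 0.5 * dt * a1
    x1 <- x1 + dt * v1; x2 <- x2 + dt * v2
    f <- fpair(x1, x2, v1, v2)
    a1 <- -f / m
    v1 <- v1 + 0.5 * dt * a1; v2 <- v2 - 0.5 * dt * a1
    if (x2 - x1 > 2 * r + 1e-5 && v2 > v1) break
  }
  c(v1 = v1, v2 = v2)
}

# brute-force neighbor scan with minimum image (R, independent of the engine)
brute_pairs_r <- function(x, r, lo, hi, periodic, skin) {
  n <- nrow(x)
  out <- NULL
  span <- hi - lo
  for (i in seq_len(n - 1)) {
    d <- sweep(x[(i + 1):n, , drop = FALSE], 2, x[i, ])
    for (ax in which(periodic)) {
      d[, ax] <- d[, ax] - span[ax] * round(d[, ax] / span[ax])
    }
    dist <- sqrt(rowSums(d^2))
    hit <- which(dist < r[i] + r[(i + 1):n] + skin)
    if (length(hit)) out <- rbind(out, cbind(i, i + hit))
  }
  if (is.null(out)) matrix(integer(), ncol = 2) else out
}

# scalar three-branch hysteretic law, written independently for comparison
ep_scalar_oracle <- function(delta_seq, k1, k2, kc, f0 = 0) {
  d0 <- 0
  out <- numeric(length(delta_seq))
  for (s in seq_along(delta_seq)) {
    d32 <- delta_seq[s]^1.5
    d032 <- d0^1.5
    if (k2 * (d32 - d032) >= k1 * d32) {
      f <- k1 * d32
      d0 <- (d32 * (1 - k1 / k2))^(2 / 3)
    } else if (k2 * (d32 - d032) <= -kc * d32) {
      f <- -kc * d32
      d0 <- (d32 * (1 + kc / k2))^(2 / 3)
    } else {
      f <- k2 * (d32 - d032)
    }
    out[s] <- f0 + f
  }
  out
}

rms_rel <- function(a, b) sqrt(mean((a - b)^2)) / sqrt(mean(b^2))

interp_curve <- function(res, xout, phase = "LOADING",
                         xcol = "deformation", ycol = "force") {
  ld <- res[res$phase == phase, ]
  stats::approx(ld[[xcol]], ld[[ycol]], xout = xout, rule = 2)$y
}

mcc_pair_tables <- function() {
  list(
    mu = matrix(c(0.561, 0.707, 0.707, 0.707), 2, 2),
    mur = matrix(c(0.3, 0.01, 0.01, 0.01), 2, 2),
    cor = matrix(0.352, 2, 2)
  )
}

cross3v <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
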