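#' Parameters of the adhesive elastic-plastic contact law
#'
#' The normal force law has three branches selected by the loading history:
#' a plastic loading branch with stiffness `k1`, a steeper unload/reload
#' branch `k2` anchored at the plastic overlap `delta0`, and an adhesive
#' branch `-kc`. A constant pull-off force `f0` and a non-local increment
#' `beta * nu * A_ij * P_ij` (contact area times the mean particle pressure of
#' the two endpoints) are added to every branch, so that a particle confined
#' by many simultaneous contacts feels a stiffer response than an isolated
#' pair.
#'
#' @param k1 Loading branch stiffness (N m^-3/2). Usually the Hertz stiffness
#'   `(4/3) E* sqrt(R*)` of the pair, optionally rescaled for calibration.
#' @param k2_ratio Ratio k2/k1 (> 1 for plastic behaviour; `k2 = k1` recovers
#'   a purely elastic Hertz contact). Default 5.
#' @param kc Adhesion branch stiffness (N m^-3/2), >= 0.
#' @param f0 Constant pull-off force (N).
#' @param beta Dimensionless non-local prefactor, >= 0.
#' @param poisson Poisson's ratio entering the non-local term.
#' @return List of class `mcdem_ep_params`.
#' @export
elastoplastic_params <- function(k1, k2_ratio = 5, kc = 0, f0 = 0,
                                 beta = 0, poisson = 0.3) {
  stopifnot(k1 > 0, k2_ratio >= 1, kc >= 0, beta >= 0)
  structure(
    list(
      k1 = as.numeric(k1), k2 = as.numeric(k1 * k2_ratio),
      kc = as.numeric(kc), f0 = as.numeric(f0),
      beta = as.numeric(beta), poisson = as.numeric(poisson)
    ),
    class = "mcdem_ep_params"
  )
}

#' Hertzian contact area
#'
#' Area of the Hertz contact circle, `A = pi * R* * delta_n` (the contact
#' radius obeys a^2 = R* delta_n). Used as the A_ij factor of the non-local
#' force term.
#'
#' @param overlap_n Normal overlap (m).
#' @param eff_radius Effective radius R* (m).
#' @return Contact area (m^2); zero at or below zero overlap.
#' @export
contact_area <- function(overlap_n, eff_radius) {
  if (overlap_n <= 0) return(0)
  pi * eff_radius * overlap_n
}

#' Accumulate the per-particle (Love-Weber) stress tensor
#'
#' Adds one contact's contribution to a sphere's stress tensor using the
#' compression-positive convention
#' \deqn{\sigma \mathrel{+}= -\frac{1}{V}\, \mathrm{sym}(r \otimes F)}
#' where `r` is the branch vector from the sphere center to the contact point,
#' `F` the force on the sphere and `V` its volume. A repulsive (compressive)
#' contact therefore adds a positive diagonal. Tensors are reset at the start
#' of each step and re-accumulated over all contacts.
#'
#' @param stress Current 3x3 stress tensor (Pa).
#' @param center Sphere center (m).
#' @param radius Sphere radius (m), used for the volume.
#' @param contact_point Contact location (m).
#' @param force Force on the sphere at that contact (N).
#' @return Updated symmetric 3x3 stress tensor.
#' @export
accumulate_particle_stress <- function(stress, center, radius,
                                       contact_point, force) {
  v <- 4 / 3 * pi * radius^3
  r <- contact_point - center
  op <- outer(r, force)
  stress - (op + t(op)) / (2 * v)
}

#' Mean pressure of a particle
#'
#' One third of the trace of the particle's stress tensor. With the
#' compression-positive accumulation of [accumulate_particle_stress()], a
#' confined particle has positive pressure. The pair value entering the
#' non-local force term is the arithmetic mean of the two endpoint pressures.
#'
#' @param stress 3x3 stress tensor (Pa).
#' @return Scalar pressure (Pa).
#' @export
particle_pressure <- function(stress) {
  (stress[1, 1] + stress[2, 2] + stress[3, 3]) / 3
}

#' Adhesive elastic-plastic normal force (scalar form)
#'
#' Evaluates the three-branch hysteretic normal force for one contact:
#' \deqn{F_n = F_0 + \beta\nu A_{ij} P_{ij} + \begin{cases}
#'   k_1 \delta_n^{3/2} & k_2(\delta_n^{3/2}-\delta_0^{3/2}) \ge k_1\delta_n^{3/2}\\
#'   k_2 (\delta_n^{3/2}-\delta_0^{3/2}) & \text{intermediate}\\
#'   -k_c \delta_n^{3/2} & k_2(\delta_n^{3/2}-\delta_0^{3/2}) \le -k_c\delta_n^{3/2}
#' \end{cases}}
#' On the plastic loading branch the plastic overlap advances so that the
#' unload branch passes through the current point:
#' \eqn{\delta_0^{3/2} = \delta_n^{3/2} (1 - k_1/k_2)}. The force is
#' continuous across branch switches by construction.
#'
#' @param overlap_n Normal overlap delta_n (m), >= 0.
#' @param hist Plastic history: list with `plastic_overlap` (delta0, m) and
#'   `max_overlap`. Use [plastic_history()] for a fresh contact.
#' @param params An `mcdem_ep_params`.
#' @param area Contact area A_ij (m^2), e.g. from [contact_area()].
#' @param pressure Pair mean pressure P_ij (Pa), compression positive
#'   (lagged one step in the dynamic engine).
#' @return List with `force` (scalar branch force, N, along the contact
#'   normal on sphere i), `hist` (updated history) and `branch`
#'   (1 = plastic loading, 2 = unload/reload, 3 = adhesive).
#' @export
elastoplastic_normal_force <- function(overlap_n, hist, params,
                                       area = 0, pressure = 0) {
  if (params$k2 < params$k1) {
    stop("k2 < k1: unload branch softer than loading branch is not supported")
  }
  if (overlap_n <= 0) {
    hist$plastic_overlap <- 0
    hist$max_overlap <- 0
    return(list(force = 0, hist = hist, branch = 0L))
  }
  d32 <- overlap_n^1.5
  d032 <- hist$plastic_overlap^1.5
  f_unl <- params$k2 * (d32 - d032)
  f_load <- params$k1 * d32
  f_adh <- -params$kc * d32
  nonlocal <- params$beta * params$poisson * area * pressure
  if (f_unl >= f_load) {
    branch <- 1L
    f <- f_load
    # advance delta0 so the k2 branch intersects the k1 branch here
    hist$plastic_overlap <- (d32 * (1 - params$k1 / params$k2))^(2 / 3)
  } else if (f_unl <= f_adh) {
    branch <- 3L
    f <- f_adh
    # unloading proceeded past the adhesive branch: pull delta0 back so the
    # reload path stays continuous (standard hysteretic-adhesion bookkeeping)
    hist$plastic_overlap <- (d32 * (1 + params$kc / params$k2))^(2 / 3)
  } else {
    branch <- 2L
    f <- f_unl
  }
  if (overlap_n > hist$max_overlap) hist$max_overlap <- overlap_n
  list(force = params$f0 + f + nonlocal, hist = hist, branch = branch)
}

#' Empty plastic contact history
#' @return List with zero `plastic_overlap` and `max_overlap`.
#' @export
plastic_history <- function() list(plastic_overlap = 0, max_overlap = 0)
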