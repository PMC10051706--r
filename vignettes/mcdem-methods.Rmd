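---
title: "Multi-contact DEM for high-load powder compaction: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-contact DEM for high-load powder compaction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`mcdem` simulates dense granular systems under high confinement — the regime
of pharmaceutical die compaction, where a powder bed is squeezed to
engineering strains above 50% and the usual binary-contact picture of the
discrete element method (DEM) starts to fail. This vignette documents the
models, their assumptions, the tunable parameters, and the places where the
design was genuinely open and a choice had to be made.

## 1. The mechanical model

Every particle is a sphere (or a body built from spheres) obeying Newton's
equations,

$$ m_i \ddot{\mathbf a}_i = \sum_j (\mathbf F^n_{ij} + \mathbf F^t_{ij})
   + \sum_j \mathbf F^b_{ij} + m_i \mathbf g, \qquad
   I_i \dot{\boldsymbol\omega}_i = \boldsymbol\tau_{ij}, $$

integrated explicitly by velocity-Verlet with per-step force evaluation
(`dem_run()`). Three force families are implemented.

**Hertz–Mindlin contact.** The normal repulsion is
$F_n = k_n\,\delta_n^{3/2} + \gamma_n \dot\delta_n$ with
$k_n = \tfrac43 E^* \sqrt{R^*}$ and the standard effective radius, modulus
and mass of the pair (`effective_pair_properties()`). The tangential force is
a history spring: the accumulated tangential displacement $\xi$ is rotated
into the current tangent plane each step, loaded with the no-slip Mindlin
stiffness $k_t = 8 G^* \sqrt{R^* \delta_n}$, damped, and capped by Coulomb
friction $|F_t| \le \mu |F_n|$; when the cap binds the stored spring is
rescaled onto the friction cone after removing the viscous part (folding the
damping into the spring turns out to pump energy into rolling pairs). A
`tangential_law = "as_printed"` switch implements the alternative
$F_t \propto \xi^{3/2}$ power-law form with $k_t = 8G^*\sqrt{R^*}$. Rolling
resistance is the constant-directional-torque model,
$\boldsymbol\tau = -\hat{\boldsymbol\omega}_{rel}\, \mu_r R^* |F_n|$, applied
equal-and-opposite to the two partners.

**Damping and restitution.** Only restitution coefficients are tabulated for
the reference materials, so the dashpot must be derived. We use
$\gamma = A(e)\sqrt{S\,m^*}$ with the instantaneous contact stiffness
$S(\delta_n)$. Because $\gamma \propto \delta_n^{1/4}$, the restitution of a
binary impact under this dashpot (with the no-tension clamp) is a *universal*
function of the dimensionless coefficient — independent of impact speed, size
and stiffness. $A(e)$ is therefore obtained numerically: the dimensionless
collision ODE is integrated once over a grid of damping levels and the map
inverted by monotone spline (`cor_damping_coefficient`, cached per session).
The popular closed form $A \propto -\ln e/\sqrt{\ln^2 e + \pi^2}$ was tried
first and rejected: it reproduces $e = 0.7$ to ~3% but overshoots $e = 0.3$
by more than 20%, violating the package's own 5% restitution contract. With
the numeric calibration a measured binary impact recovers the configured
restitution to ~2% at the default timestep and <1% at fine timesteps.

**Multi-contact adhesive elastic–plastic law.** For compaction the normal
force is the three-branch hysteretic law

$$ F_n = F_0 + \beta\nu A_{ij} P_{ij} + \begin{cases}
 k_1 \delta_n^{3/2} & \text{plastic loading} \\
 k_2 (\delta_n^{3/2} - \delta_0^{3/2}) & \text{unload / reload} \\
 -k_c \delta_n^{3/2} & \text{adhesive branch,}
\end{cases} $$

with the plastic overlap advanced on the loading branch so the unload branch
passes through the current point,
$\delta_0^{3/2} = \delta_n^{3/2}(1 - k_1/k_2)$, which makes the branch tests
self-consistent and the force continuous across switches
(`elastoplastic_normal_force()`). The non-local term is what makes the model
"multi-contact": $A_{ij} = \pi R^* \delta_n$ is the Hertz contact-circle
area, and $P_{ij}$ is the mean of the two particles' pressures, each defined
as one third of the trace of the per-particle Love–Weber stress
$\sigma_i = -\tfrac1V \sum_c \mathrm{sym}(\mathbf r_c \otimes \mathbf F_c)$
accumulated over that particle's contacts. A confined particle therefore
feels a stiffer contact than an isolated pair — the essential physics of a
die at 30 MPa.

Open points the source material does not fix, and how they were resolved:

* *Sign conventions.* Stress is accumulated compression-positive, so
  confinement stiffens the contact. (The alternative sign would soften
  confined contacts, the opposite of the model's purpose.)
* *Pressure feedback.* $P$ feeds back into the force that generates it. A raw
  one-step lag makes the loop a marginally-damped discrete map that diverges
  under deep confinement (observed in rigid-cluster compression). $P$ is
  therefore relaxed with an exponential moving average (time constant 10
  steps) — negligible lag at quasi-static rates, unconditionally stable in
  every case we exercised.
* *Deep-overlap guards.* When a plate overlap exceeds a small sphere's
  diameter (routine for rigid clusters at 40% deformation) the nominal
  contact point passes the sphere center and the Hertz circle exceeds the
  sphere's cross-section. The engine clamps the moment arm at zero and caps
  $A_{ij}$ at $\pi r_{\min}^2$; the exported `contact_area()` keeps the
  uncapped small-overlap law.
* *Unprinted stiffnesses.* $k_2$ and $k_c$ are configured as ratios of $k_1$
  (defaults 5 and 0); $k_1$ defaults to the Hertz stiffness but carries a
  `k1_scale` multiplier — the calibration knob, since the loading
  stiffness of a real excipient is *not* tied to its elastic modulus.

**Bonds.** A bonded pair carries a linear normal spring
$F = -k_{nb} A_b (L - L_0)$ acting in tension *and* compression, a tangential
spring on the accumulated tangential offset of the attachment (rotated with
the pair each step), and a small viscous term (`damping_ratio` of critical,
default 0.05). $A_b = \pi r_b^2$ with $r_b = \min(r_i, r_j)$, so the printed
stiffness densities in N/m³ become spring constants in N/m. Bonds are created
once, by the distance criterion $|x_i - x_j| < (r_i + r_j)\, m_b$ with
$m_b = 1.15$ by default, and never break. Bonded pairs are excluded from the
contact loop — the bond alone carries the interaction. We tried the
alternative routing (bond in tension, frictional Hertz contact in
compression): a bonded ball then shears plastically like a sandpile and
collapses at 20% deformation; the pure-bond truss stays elastic to 40% as the
single-sphere study requires. Non-bonded sub-spheres of the same body that
come into overlap under large deformation *do* contact normally, which
resists self-penetration.

**Bond stiffness and a value that does not verify.** The tabulated bond
stiffness density for the rubber single-sphere study (1.15×10⁶ N/m³) gives,
at 545-sub-sphere resolution, about 5 N/m per bond — seven orders softer than
the sub-sphere Hertz stiffness. A ball built that way cannot hold its shape,
let alone reproduce an elastic rubber sphere; no reading of the units we
tried (per-area, per-volume, per-strain) rescues it. Bond micro-parameters
in the BMS family are understood to be numerically calibrated quantities, so
`bms_bond_params()` instead derives the default from the material: a bond of length $L_0 = 2r$ and
section $A_b$ behaving as a rod of the material gives $k_{nb} = E/L_0$, and a
close-packed lattice of such rods has an effective Young's modulus close to
$E$. The printed values remain settable through `bond_params()`.

**Rigid (CMS) clusters.** Overlapping-sphere unions with fixed internal
geometry. Mass, center of mass and inertia come from Monte-Carlo rejection
sampling of the union (`monte_carlo_mass_properties()`; a sample is inside if
inside *any* sphere, so overlap is not double counted). Translation is
velocity-Verlet; rotation integrates Euler's equations in the principal frame
with a leapfrog quaternion update and per-step renormalization. Intra-body
overlaps are constitutive, not contacts. A rigid bumpy cluster squeezed
between frictional plates is dynamically unstable to rolling ejection (the
watermelon-seed mode); the single-particle compression protocol therefore
guides the body — `fix_rotation`/`fix_lateral` in `make_cms_body()` — like a
real compression rig would.

## 2. Bodies, shapes and sizes

`build_bms_ball()` replaces a solid elastic sphere by equal touching
sub-spheres on a hexagonal close packing clipped to the ball, with the pitch
chosen to hit the requested count within 10%. Two geometric refinements
matter in practice: the lattice is tilted by a fixed incommensurate rotation
(an axis-aligned clip presents flat facets to the plates and overestimates
the initial contact stiffness several-fold), and the outermost shell is
projected radially onto the circumscribed sphere so that the envelope is
smooth (`conform_surface = TRUE`). Sub-sphere masses are scaled so the body
mass equals the solid sphere's.

`generate_random_particle()` is a deliberately simplified stand-in for
Fourier–Voronoi particle generators: a unit icosphere perturbed by a seeded
sum of spatial cosine harmonics, then iteratively rescaled along its
principal axes until the Feret-box descriptors — aspect ratio $S/L$,
elongation $I/L$, flatness $S/I$ of the principal-axis bounding box — hit the
targets within tolerance. The box is the principal-axis-aligned box (cheap,
deterministic), not the exact minimum-volume box. `fill_mesh_with_spheres()`
fills any watertight mesh either with a uniform touching lattice (for
deformable bodies) or by greedy largest-inscribed-sphere placement with
overlaps (for rigid bodies); point-in-mesh and point-to-surface queries are
exact ray-casting / closest-point computations on the triangulation.

Particle sizes come from a log-normal fitted to volume-quantile triples
(`fit_lognormal_to_quantiles()`). The reference excipient's printed quantiles
(82.9 / 224.6 / 379.3 µm) are *not* log-symmetric: no two-parameter
log-normal reproduces all three within 5% (plain least squares in log space
puts the median 15% low). Because the compaction workflow discards fines
below 180 µm — above the 10th percentile — the default fit anchors the
distribution on x50 and x90, the quantiles that survive truncation; plain LS
is available as `method = "ls"`. Sampling is inverse-CDF with lower
truncation; the bed protocol additionally caps diameters at half the periodic
box length so the minimum-image convention stays valid (~3% of draws).

## 3. Protocols

*Single-sphere compression* (`run_single_sphere_compression()`): the body
sits exactly between two plates at its actual built extent (the lattice clip
makes the agglomerate slightly smaller than nominal; deformation is
normalized by the built diameter). Both plates close symmetrically at 0.1% of
the material's sound speed by default — inertial effects are then ~10⁻⁶ of
elastic forces.

*Gravity filling* (`run_gravity_fill()`): particles are inserted by random
sequential addition as a **dilute cloud** (~10% solids), so they deposit
sequentially like powder poured into a die; flash-settling a dense cloud
arrests ~3 points looser. During filling the Young's moduli are scaled by 0.1
(overlaps stay below ~0.5% of a radius, so the packing is insensitive, and
the Rayleigh timestep triples); a deeper reduction makes impact overlaps so
deep that the rotational tangential mode outruns the Rayleigh stability
estimate. Settling ends when the kinetic energy per particle falls below
$10^{-8}\,m g d$ (or the bed height freezes while the energy sits far below
the gravitational scale).

*Uniaxial compaction* (`run_uniaxial_compaction()`): a top plate descends at
constant speed to the target engineering strain $1 - h/h_0$ and reverses;
stress is the plate reaction over the die cross-section. The stage restores
the full moduli and starts from fresh contact histories.
`calibrate_compaction()` drives the peak stress to a target (30 MPa at 57%
strain for the reference excipient) by secant iteration on `k1_scale` in
log-log space — stress is near power-law in the loading stiffness, so 3–4
compactions suffice.

## 4. Numerical choices

* Timestep: `critical_timestep()` returns a safety factor (default 0.15)
  times the Rayleigh time $t_R = \pi r \sqrt{\rho/G} / (0.1631\nu + 0.8766)$
  of the smallest, stiffest sphere. Stiff-bonded bodies additionally bound
  the step by $0.15\sqrt{m/(z\,k_{bond})}$ with lattice coordination
  $z = 12$.
* Neighbor search: linked cells with skin $0.2\,r_{\min}$, rebuilt when any
  displacement exceeds half the skin; candidate pairs are sorted so the
  cell-list and brute-force paths produce bit-identical trajectories.
* Rolling-torque singularity: zero below $|\omega_{rel}| = 10^{-12}$ rad/s.
* Everything is deterministic: every stochastic helper takes an explicit seed
  and restores the caller's RNG state.

## 5. What the synthetic world does and does not establish

The generators emulate the *stated* conditions of the compaction study:
tabulated elastic/frictional parameters, the printed size quantiles with the
180 µm cut, 150 particles in a 1×1 mm periodic die, bonded agglomerates at
the printed resolutions, shape targets (aspect ratios 0.84/0.71/0.53,
descriptor triple 0.8/0.84/0.95). They do not reproduce: real particle
surfaces (SEM-derived contours), the press kinematics of an instrumented
compaction simulator, humidity/rate effects, or bond failure. A green test
therefore establishes internal consistency of the mechanics and faithfulness
to the printed parameter set — not agreement with any particular experimental
trace beyond the scalar targets the acceptance suite checks.

Known limitations worth stating plainly:

* A discretized multi-sphere agglomerate is **systematically softer than the
  Hertz closed form at small deformation**: the plate engages a patch of
  sub-spheres whose envelope follows the parent curvature, which yields
  $F \propto \delta^{5/2}$ rather than $\delta^{3/2}$ as $\delta \to 0$, plus
  the truss interior adds series compliance that the half-space Hertz
  solution does not have. At 545-sphere resolution the simulated force in the
  2–5% deformation window sits well below the closed form, crossing it near
  30% deformation and exceeding it beyond — the qualitative large-deformation
  stiffening is reproduced, the small-deformation 10% agreement target is
  not. The corresponding acceptance test is left red deliberately.
* Refinement convergence of bonded agglomerates is first-order in
  $r_{sub}/a$ (sub-sphere radius over contact-patch radius): the plate-layer
  compliance scales with $r_{sub}$, so resolutions around 10³ sub-spheres per
  ball still differ by tens of percent — far from the 2% the source claims
  for 819 vs 1322. Measured honestly, reported honestly.
* The settled packing fraction of the frictional reference bed comes out at
  0.55–0.58 (height measured to the highest sphere top, per the stated
  definition) against the printed 59%; the rough free surface of a
  150-particle bed alone costs a few points of the denominator.
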