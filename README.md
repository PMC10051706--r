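# mcdem — multi-contact DEM for high-load powder compaction

`mcdem` is an R package (with a compiled C++ core) for discrete element
simulation of dense granular systems under high confinement — the regime of
pharmaceutical die compaction, where a powder bed is squeezed to engineering
strains beyond 50% and binary Hertzian contacts stop telling the whole story.

It is aimed at researchers in particle technology / pharmaceutical
engineering who want a small, fully scriptable, reproducible DEM to study
compaction mechanics, multi-sphere particle representations and contact-model
behavior — not a replacement for production DEM codes.

## What is inside

* **Hertz–Mindlin contacts**: normal force `F_n = k_n δ^{3/2} + γ_n δ̇` with
  `k_n = (4/3) E* √R*`, a tangential history spring with Coulomb cap
  `|F_t| ≤ μ|F_n|`, restitution-calibrated damping, and
  constant-directional-torque rolling friction `τ = −ω̂_rel μ_r R* |F_n|`.
* **Multi-contact adhesive elastic–plastic law**: the three-branch hysteretic
  normal force with loading stiffness `k1`, unload/reload stiffness `k2`,
  adhesive branch `−kc`, pull-off force `F0`, and the non-local increment
  `β·ν·A_ij·P_ij` built from each particle's Love–Weber stress — confinement
  stiffens the contact, which is what carries a die to 30 MPa.
* **Bonded multi-sphere (BMS) bodies**: deformable agglomerates of touching
  sub-spheres joined by permanent normal+tangential bond springs created by
  the distance criterion `|x_i − x_j| < (r_i + r_j)·m_b`.
* **Conventional multi-sphere (CMS) clusters**: rigid unions of overlapping
  spheres with Monte-Carlo mass properties and quaternion rigid-body
  dynamics.
* **Shapes & sizes**: seeded random star-shaped particle generation targeting
  Feret-box descriptors (aspect ratio, elongation, flatness), sphere filling
  of watertight STL meshes, log-normal PSD fitting/sampling with truncation.
* **Protocols**: quasi-static single-particle compression between plates,
  gravity die filling, uniaxial compaction with strain–stress recording, and
  secant calibration of the loading stiffness to a target compaction stress.

The time-stepping engine (velocity-Verlet, linked-cell neighbor search,
periodic boundaries, moving plane walls, per-wall reaction recording) is
C++ via Rcpp; every model equation is also exposed as a plain R function so
each force law can be tested against independent oracles.

## Worked example

Two identical rubber spheres (E = 18.5 MPa, ν = 0.46, R = 1 cm) pressed to a
1 mm overlap:

```r
library(mcdem)
m <- default_materials()$rubber
p <- effective_pair_properties(m, m, 0.01, 0.01)
p$eff_young          # 11732623  -> E* = E / (2 (1 - nu^2)) ≈ 1.17e7 Pa
p$normal_stiffness   # 1106162   -> k_n = (4/3) E* sqrt(R*)  [N m^-3/2]

g <- contact_geometry(c(0, 0, 0.019), c(0, 0, 0), 0.01, 0.01)
hertz_normal_force(g, p)[3]   # 34.97 N  = k_n * (1e-3)^{3/2}
```

Size statistics of the reference microcrystalline-cellulose excipient and a
settled 150-particle bed in a 1 × 1 mm periodic die:

```r
psd_span(82.9, 224.6, 379.3)        # 1.3197 -> printed as 1.32
fit <- fit_lognormal_to_quantiles(mcc_psd())
fill <- run_gravity_fill(n = 150, fit = fit, seed = 1)
fill$packing_fraction               # ~0.55-0.58 depending on seed
```

The packing fraction is solid volume over (cross-section × bed height), with
bed height measured to the highest sphere top. A full compaction with the
multi-contact law, calibrated to 30 MPa at 57% strain:

```r
cal <- calibrate_compaction(fill, target_stress = 30e6, target_strain = 0.57)
cal$stress / 1e6                    # within 10% of 30 MPa after 3-4 runs
```

## Command line

```sh
Rscript inst/cli/mcdem psd-span
Rscript inst/cli/mcdem fill --seed 1 --out-dir out
Rscript inst/cli/mcdem compact --config cfg.toml --seed 1 --out-dir out
Rscript inst/cli/mcdem single-sphere --config cfg.json --out-dir out
Rscript inst/cli/mcdem shapes-generate --seed 2 --out-dir out
```

Configs are JSON or flat `key = value` text; every run writes CSV time
series plus a `summary.json` echoing inputs and scalar results.

## Documentation

The methods vignette (`vignettes/mcdem-methods.Rmd`) documents the force
laws, the damping calibration, the bond-stiffness reasoning, the filling and
compaction protocols, all numerical guards (pressure relaxation, deep-overlap
clamps, timestep bounds) and the known limitations of multi-sphere
discretizations, including which acceptance checks are deliberately left red
and why.
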