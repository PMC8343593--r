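---
title: "Growth-driven cortical folding and 3-hinge detection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth-driven cortical folding and 3-hinge detection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gyrogenesis)
```

# The scientific problem

A 3-hinge gyrus is the conjunction where gyral crest lines from three
different orientations meet.  These junctions are the most common
identifiable gyral structure in primate cortices (4-way crossings are
rare), they carry the thickest cortex and the densest long-range axonal
connections, and their counts and locations vary between individuals while
a subset is preserved across subjects and species.  `gyrogenesis`
implements an in-silico laboratory for studying how such junctions form:

1. a **finite-growth biomechanical model** of a flat bilayer brain patch —
   a thin growing cortical plate bonded to a thick non-growing core —
   solved quasi-statically with nonlinear finite elements;
2. a **surface-based detection pipeline** that extracts the gyral-crest
   network of any triangulated surface and identifies its degree-3 joints;
3. **experiment drivers** reproducing the in-silico designs: perturbation
   ensembles, fiber-bundle templates with gradient axial growth, and
   thickness/area sweeps with a count-prediction fit;
4. **analytic fixtures** (flat sheets, ridges, Y/X junctions) with exact
   ground truth, so the detection pipeline is testable without running any
   simulation.

# The mechanical model

## Kinematics and constitutive law

Growth is modelled by the multiplicative decomposition of the deformation
gradient, \(F = A\,G\): the growth tensor \(G\) adds material without
stress, and the elastic tensor \(A\) carries all stress-producing
deformation.  Cortical growth is isotropic, \(G = g I\) with
\(\det G = g^3\); axonal fiber bundles grow along the surface normal
\(z\), \(G = (g-1)\,z \otimes z + I\) with \(\det G = g\); the core does
not grow.  The growth ratio advances linearly in time, \(\dot g = const\).

All tissues share a compressible neo-Hookean energy parameterized in the
elastic tensor and its Jacobian \(J = \det A\):
\[
W(A) = \tfrac12 \lambda \ln^2 J
     + \tfrac12 \mu \left( A\!:\!A - 3 - 2 \ln J \right) .
\]
The first Piola–Kirchhoff stress is implemented as the exact gradient of
\(W(F G^{-1})\) with respect to \(F\),
\[
P = \left[\mu A + (\lambda \ln J - \mu) A^{-T}\right] G^{-T},
\]
so that a grown but unconfined configuration (\(F = G\)) is exactly
stress-free and the finite-element residual is the exact gradient of the
assembled energy.  Two published conventions exist for a volume prefactor
in the stress; we use the per-reference-volume form because it makes
stress and energy an exact conjugate pair — the property the test suite
verifies by finite differences — and because only this form gives zero
stress at \(F = G\) for every growth state.

**Parameters.** The shear modulus is \(\mu = 0.5\) kPa for cortex, core
and fibers alike (reported brain-tissue stiffness; there is no substantial
gray/white contrast).  The first Lamé constant is not fixed by tissue
data; the default is \(\nu = 0.45\) (\(\lambda = 4.5\) kPa), a common
soft-tissue choice, and both constants are configurable through
`material_params()`.  Note that \(\lambda/\mu = 9\) is only mildly
incompressible: under laterally confined growth a substantial part of the
added volume is accommodated by elastic thickening of the plate rather
than by folding (see *Known limitations*).

## Geometry, boundary conditions, perturbation

The base slab is \(60 \times 60\) mm in plane with a 50 mm core and a
1.5 mm cortex (`slab_spec()`), meshed with trilinear hexahedra on a
structured grid: uniform in-plane spacing (default one cortical thickness),
at least two element layers through the cortex, and geometrically graded
core layers (fine at the interface where fold strain concentrates, coarse
at depth).  Symmetric boundary conditions hold on the four sides (zero
normal displacement), the bottom is fixed, the top is free.  Setting the
in-plane width to one element realizes a plane-strain slice.

Folding is seeded by the checkerboard perturbation
\(\epsilon_z = A_0[\sin(\omega x) + \sin(\omega y)]\) applied to the top
surface and blended linearly to zero at the cortex–core interface.
\(A_0\) defaults to 1% of the cortical thickness.  Ensemble members draw
\(\omega\) reproducibly from wavelengths of 5–20 mm (bracketing observed
fold wavelengths; the source describes only that each member's
\(\omega\) differs), so members differ *only* in their perturbation.

## Solver

Equilibrium (\(\mathrm{Div}\,P = 0\), no body forces) is re-solved after
each growth increment by Newton's method with a consistent tangent
(assembled in C++, solved with sparse Cholesky; shifted factorizations
when the tangent is indefinite).  Because the load-free quasi-static
problem is the minimization of total potential energy, the line search
accepts steps by an Armijo decrease of the energy as well as by residual
reduction — this follows stable branches through the wrinkling
bifurcation, where the residual alone is a poor merit function.  If
Newton stalls, the growth increment is substepped adaptively, and as a
last resort a kinetic-damped dynamic relaxation (explicit pseudo-dynamics
with Gershgorin-safe mass scaling and a per-iteration displacement cap)
carries the state across the bifurcation before Newton polishes it; this
mirrors the quasi-static dynamic stepping used by the original
simulations, including its property that round-off asymmetry — not an
explicit perturbation — selects the post-buckling branch.  Convergence is
declared at a relative residual of \(10^{-6}\).

Self-penetration of the top surface is limited by a node-pair penalty
(activation gap half the in-plane element size, stiffness
\(100\,\mu/\mathrm{mm}\) times the nodal area, reference-distance
exclusion of material neighbours).  Deep post-contact regimes are
best-effort.

The default schedule grows the cortex to \(g = 1.8\) in 100 increments.
The reduced desk-scale profile (`reduced_config()`: 21 mm slab, 12 mm
core, 10 increments to \(g = 2.0\)) is the largest configuration that a
single-CPU test run can afford; \(g \approx 2.1\) is also the practical
limit of this mesh resolution — beyond it, sulci sharpen into mesh-scale
creases with no nearby discrete equilibrium, and a shallow slab also
admits spurious global buckling modes.

# The detection pipeline

Given any triangulated surface (simulated, fixture, or read from
PLY/OFF/VTK):

1. **Gyral altitude** — the midsurface is a strongly Laplacian-smoothed
   copy of the surface (boundary vertices pinned so an open sheet does
   not shrink), translated so the mean signed normal displacement is
   zero; altitude is the signed normal-direction distance to it, positive
   on gyri.  The smoothing length defaults to \(\sqrt{\mathrm{area}}/8\)
   — an intrinsic scale, so the field is exactly invariant under rigid
   motions, uniform scaling and mesh subdivision — and the Laplacian
   iteration count follows from the diffusion scaling
   \(n \approx (2 L_s/h)^2/\lambda\).
2. **Crest segmentation** — a descending-altitude watershed grows crest
   basins from local maxima down to the altitude level (default 0, i.e.
   the midsurface; the source states only "an altitude level").
3. **Skeletonization** — a geodesic distance transform from the crest
   boundary highlights central regions; *tree marching* connects crest
   vertices in decreasing centrality, bridging sub-trees where they meet
   (that is where skeleton joints are born); redundant branches are
   pruned.  A branch is judged by its extension beyond its junction's
   medial blob, \(\mathrm{len} - d(\mathrm{junction})\): corner forks of
   band caps and lateral band-width twigs never extend past the blob
   radius, while genuine gyral spokes do.  Branches below
   \(\max(0.25 \times \text{longest leaf branch},\ 2\bar h,\ d)\) are
   removed.  All orderings quantize distances at \(10^{-6}\) mm and break
   ties by vertex id, so results are reproducible to the vertex under
   rigid motions.
4. **Joint extraction** — skeleton vertices of degree > 2 are gyral
   joints; joints closer along the skeleton than one pruning length merge
   (suppressing discretization doubles); joints with exactly three
   outgoing branches are 3-hinge records (center, three traced spoke
   paths, spoke directions); degree-4+ joints are reported separately and
   never counted as 3-hinges.

# Fixtures: what a green test establishes

`make_surface()` builds height fields from Gaussian-profile ridges along
polylines (width parameter = 1 SD; smooth cross-sections are
watershed-friendly), triangulated with a fixed diagonal.  Ground truth is
exact by construction: a flat sheet has no hinge, a straight ridge none,
a 120° Y exactly one, an X crossing one 4-joint and no 3-hinge, `multi_y`
exactly `k`.  The suite verifies counts, junction localization (within
two edge lengths), and invariance under rigid motion, scaling and
subdivision.  Fixtures emulate crest/junction *geometry*, not the
statistics of real cortical surfaces (no curvature spectra or sulcal
depth distributions): green fixture tests establish the correctness of
the detection pipeline, not the realism of the simulated folds.

# Experiments and the desk-scale compromise

`run_ensemble()` repeats simulate+detect across perturbation seeds and
aggregates count statistics; members that error or fail to pass 3/4 of
the schedule are excluded with a warning, while members that stop
slightly early are analyzed at their last converged state.
`run_fiber_experiment()` compares fiber-template runs against no-fiber
controls: whether a 3-hinge is captured within 5 mm of the template
junction (the source reports visual correspondence only; 5 mm is our
operationalization).  `run_thickness_area_sweep()` counts hinges in a
central patch (clipped to the domain, lessening edge effects) and fits
\(\mathrm{count} = \mathrm{area}\,(a/t + b)\) — linear in area,
inverse-affine in thickness, reflecting the analytic result that fold
number scales with size over thickness; `predict_count()` evaluates the
fit from initial geometry alone and flags extrapolation.

**Known limitations, stated plainly.**  The full-scale simulations behind
the published ensemble (29–38 hinges on a 60 mm patch, mean ≈ 34; final
thickness ≈ 3.5 mm from 1.5 mm) ran a commercial explicit solver to a
highly convoluted, self-contacting regime on meshes far beyond a
single-CPU test budget.  The desk-scale profile reaches early
post-buckling (fold amplitudes below ~1 mm at \(g \approx 2\)):

* the surface pattern is a near-periodic bump/stripe lattice set by the
  seeded checkerboard; branching Y-junctions arise from pattern
  *defects*, which a 16-wavelength-sized domain barely produces, so
  desk-scale hinge counts are far below the area-scaled published band;
* with \(\nu = 0.45\), laterally confined growth thickens the plate
  strongly before folding relieves it, so the measured final/initial
  thickness ratio at \(g \approx 2\) is ≈ 5, well above the published
  ≈ 2.3 that presumes fully developed folds (raising \(\nu\) does not
  rescue this: volumetric locking of trilinear hexahedra stiffens the
  response at \(\nu \to 0.5\));
* the equal-modulus plane-strain bilayer with a non-growing core has its
  linearized surface instability at the classical threshold near
  \(g \approx 1.8\) (measured 10× amplification at \(g \approx 1.7\),
  insensitive to wavelength 3–12 mm and to mesh refinement).  The often
  quoted critical ratio 4/3 originates from settings where *both* layers
  grow — biologically, cortical-plate volume grows ~4-fold while the
  subplate grows ~3-fold over the folding window — which is not the same
  experiment as a growing film on an inert substrate.

The acceptance blocks in `tests/testthat/test-acceptance.R` state the
published bands verbatim and print the measured values; the blocks that
the desk-scale world cannot meet fail honestly rather than being tuned.

# Numerical choices

* Tolerances: Newton relative residual \(10^{-6}\); stress-gradient check
  \(10^{-6}\) relative; distance quantum \(10^{-6}\) mm.
* Tie-breaks: vertex id everywhere after quantized keys.
* Degenerate inputs: empty crest masks yield empty nets; single-vertex
  crest components yield no skeleton; zero-rate schedules return the
  state unchanged; inverted elements reject the step and trigger
  substepping.
* Determinism: identical configuration + seed reproduce trajectories
  bit-identically on a given platform; every experiment result carries
  its seeds and a config fingerprint.

# Configuration and interfaces

All tunables live in five small constructor objects — `material_params()`
(kPa), `slab_spec()` (mm), `perturbation_spec()`, `growth_schedule()`,
`detect_config()` — bundled by `sim_config()`.  Surfaces are read and
written as ASCII PLY/OFF/legacy-VTK; volume snapshots as legacy-VTK
unstructured grids with region and growth-rate cell fields; reports as
JSON/CSV.  A thin command-line wrapper (`inst/cli/gyrogenesis`) exposes
`simulate`, `detect`, `fixtures`, `ensemble` and `sweep` over a JSON
config file.
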