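---
title: "Growth, folding and sulcal-pit matching: models and methods"
author: "neurofold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth, folding and sulcal-pit matching: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`neurofold` studies how sulcal pits — the deepest points of sulcal basins,
the first-formed and most genetically stable cortical landmarks — emerge
and persist while the fetal brain folds. It combines

* a differential-tangential-growth (DTG) finite element model that grows a
  smooth bilayer brain until it buckles into folds,
* sulcal depth estimation and pit extraction (depth potential function +
  watershed-by-flooding),
* a two-stage point-cloud matching pipeline for pits of two brains, scored
  by the similarity degree of sulcal pits (SDSP), and
* cohort-level analyses (all-pairs SDSP matrices, diagonal-dominance
  matching, stage trajectories, paired tests and regressions).

Real fetal MRI surfaces are not distributed with the package; a synthetic
geometry module generates brain-like surfaces and two-timepoint pit-cloud
cohorts with known ground truth, which every test and the acceptance
script run on.

# The mechanical model

## Kinematics and constitutive choice

Deformation is decomposed multiplicatively into growth and elastic parts,
`F = Fe Fg`. Growth is anisotropic in the cortical plate and isotropic in
the white matter:

* cortex: `Fg = theta_c I + (1 - theta_c) n0 (x) n0`, where `n0` is the
  *referential* unit normal of the pial surface, assigned once when the
  bilayer mesh is built and never updated. The in-plane eigenvalue is
  `theta_c` (multiplicity 2), the normal eigenvalue 1, so
  `det Fg = theta_c^2`: `theta_c` is the linear in-plane stretch and
  cortical *area* grows as `theta_c^2`. (An alternative printed reading
  defines `theta` as `det Fg`; the operational tensor form above is what
  the elastic decomposition uses, so it is authoritative here and the
  determinant identity follows from it.)
* white matter: `Fg = theta_w^(1/3) I` with `det Fg = theta_w`, the volume
  multiplier.

Both multipliers follow linear kinetics, `theta_c' = Gctx`,
`theta_w' = Gsub`. The representative rate ratio `Gctx/Gsub = 4` sits near
the centre of the range measured from paired fetal scans under a linear
growth assumption (ratio of relative area change to relative volume
change, `estimateGrowthRatio()`).

Both tissues are the same compressible neo-Hookean material,

```
W = mu/2 (Je^{-2/3} tr(Fe^T Fe) - 3) + k/2 (Je - 1)^2 ,
```

with equal shear moduli (`mu`) for cortex and white matter. The bulk
modulus is not fixed by the source material model; the default `k = 5 mu`
gives mild compressibility, the standard regime in folding simulations,
and is configurable. The Cauchy stress is the Piola push-forward

```
T = Je^{-1} (dW/dFe) Fe^T = mu Je^{-5/3} dev(Fe Fe^T) + k (Je - 1) I .
```

The printed transpose placement in the source stress relation is
ambiguous; this standard form is verified in the test suite against
central differences of `W` on random elastic states (1e-6 relative) and
satisfies objectivity and zero stress on rotations.

A uniform follower pressure of `0.7 mu` acts on the current pial surface,
emulating the constraint of the meninges and developing skull that
flattens fold crests.

## Solver

`simulateGrowth()` integrates damped explicit pseudo-dynamics (dynamic
relaxation) on linear tetrahedra. Numerical controls, all in
`simConfig()`:

* **Mass scaling.** The fictitious density is set from the chosen step
  count and the smallest element altitude so the explicit step is stable
  (`cfl` safety 0.35). Inertia is fictitious; quasi-statics is enforced by
  slow growth plus damping.
* **Damping and settling.** Velocities are scaled by `damp` (0.97) each
  step; at every emitted snapshot growth is frozen and the state is
  settled until the kinetic energy falls below `settleTol` (5e-4) of the
  strain energy, so reported states are near-equilibria. The
  homogeneous-growth test tightens this and observes residual stress
  below 1e-3 mu.
* **Self-contact.** Node-to-triangle penalty contact on the pial surface
  only, with a spatial hash rebuilt every 20 steps and a 3-ring
  topological exclusion so neighbouring triangles never repel. The push
  direction falls back to the face normal for just-penetrated vertices.
  Penalty stiffness 5 mu/mm, activation gap 0.4 of the median pial edge.
* **Stop criterion.** Snapshots are emitted evenly spaced in `theta_w`
  between 1 and the target (spacing is a package choice; only the number
  of stages, seven, is prescribed). When a deformed white-matter volume
  ratio target is set, growth continues in correction rounds until the
  measured ratio is within `stopTol` (0.02) of it.
* **Element inversion** aborts the run with an error rather than
  continuing silently.

Folding behaviour: with `Gctx/Gsub = 4` a spherical bilayer (1.4 mm
cortex) stays smooth at small growth and buckles once the tangential
mismatch strain `(theta_c - theta_w^{1/3})/theta_c` passes the
surface-instability range; the acceptance suite checks smoothness below
0.46 mismatch, folding beyond it, and no instability at matched growth
rates. Measured onset on the desk-scale spheres is somewhat *below* 0.46
(finite shell curvature and compressibility advance the instability
relative to the incompressible half-space estimate), which the folded /
smooth checks bracket.

# Surface processing

* **Taubin smoothing**: uniform-weight two-step fairing, defaults
  `lambda = 0.5`, `mu = -0.53` (iteration count 100 in the standard
  workflow). At these defaults 100 iterations reduce radial noise on
  sphere fixtures by about 4x while changing enclosed volume by under 3%;
  a tighter pass-band (e.g. `mu = -0.505`) exceeds 5x reduction. Both are
  asserted in the tests.
* **Isotropic remeshing** resamples the surface with a geodesic sphere of
  matching resolution and radial ray-casting from the centroid. This is
  exact for surfaces star-shaped about their centroid — which covers all
  smooth fetal-brain-like geometry the package produces — and is *not* a
  general remesher: strongly folded or non-star-shaped surfaces are out
  of its domain. Median edge lands within a few percent of the target and
  the operation is idempotent.
* **Inward offset** moves vertices along inward area-weighted vertex
  normals (uniform 1.4 mm for the white surface, the assumed early
  cortical thickness), with a local relaxation pass if triangles
  degenerate.
* **Bilayer meshing** extrudes the pial triangulation radially: cortical
  shells (count `ceil(thickness/edge)`, at least 2 — four layers at the
  reference 0.4 mm element size), geometrically graded interior shells,
  and a central fan. Prisms split into three tetrahedra using the
  lowest-column-index diagonal rule, which makes adjacent prisms share
  quad diagonals, so the mesh is conforming by construction — in
  particular across the gray–white interface, where cortex and white
  elements share faces and nodes. Every cortex element stores the
  referential pial normal of its column.

# Sulcal pits

## Depth potential function

Depth is the solution of a regularized surface Poisson problem driven by
mean curvature:

```
(alpha * M/A + L) d = (M/A) b ,   b = 2 (Hbar - H) sqrt(A) g ,
```

with `L` the cotangent Laplace–Beltrami stiffness, `M` the lumped vertex
mass, `A` the total area, `H` mean curvature (`Hbar` its area-weighted
mean) and `alpha = 0.03` the single trade-off parameter between mean
curvature and average convexity. Because `M/A`, `L` and `b` are all
invariant under uniform rescaling of the surface, the depth map is
*exactly* independent of brain size (the tests assert identity under a
2x rescale). The fixed calibration gain `g = 50` puts DPF values on the
scale of geometric sulcal depth in millimetres for fetal-scale geometry
(a 1.5 mm dent on a 10 mm sphere maps to DPF ~ 1.6), which keeps the
published ridge-height threshold meaningful. Sign convention: concave
(sulcal) regions positive, so pits are depth maxima; this polarity is a
documented package convention.

## Watershed-by-flooding

Vertices are processed by decreasing depth (ties broken by vertex index,
making the result deterministic); a vertex joins its deepest labelled
neighbour's basin, founds a basin when it has none, and is a ridge vertex
when neighbours span several basins. At a ridge two basins merge iff the
ridge height `R` (the shallower pit depth minus the ridge depth — the
standard watershed saliency) is below `Threshold_R = 1.5` *and* the
pit-to-pit distance is below `Threshold_D = 20` (geodesic along the
surface by default, since Euclidean distance shortcuts across gyral
banks; configurable). After flooding, basins smaller than
`Threshold_A = 50` merge into the neighbour with the longest shared
border, iterated to a fixpoint. Units: `Threshold_D` in mm,
`Threshold_A` in mm^2 (the sources give bare numbers; these are the
natural units of the pipeline). A constant depth map yields an empty
segmentation with a warning.

In the scaled-down simulation workflow (`simulateFoldingCohort()`), the
dimensional thresholds are scaled with the geometry — `D` by the linear
scale `s` relative to a 40 mm hemisphere and `A` by `s^2` — because a
desk-scale brain is a scaled physical model; `Threshold_R` is scale-free
under this DPF and applies unchanged. Without this correction the
unscaled `D = 20 mm` spans most of a 12 mm model and over-merges basins.

# Pit matching and SDSP

* **Affinity**: `A(i,j) = exp(-||Pi - Qj||^2 / sigma)` with `sigma = 100`
  (squared distance divided by `sigma` exactly as printed; the inferred
  units of `sigma` are mm^2).
* **RRWM**: the published reweighted-random-walk matching operates on
  pairwise candidate affinities; here the stated inputs are the unary
  Gaussian affinities, so the walk uses them as node weights — an
  affinity-weighted propagation alternating with a reweighting jump
  (exponential inflation, 10 Sinkhorn sweeps) mixed at jump probability
  0.2, iterated to 1e-8 or 300 iterations. Optional pairwise
  geometric-consistency terms are available but off by default.
  Hyperparameters follow the original publication and are configurable.
* **Discretization**: Hungarian assignment (Jonker–Volgenant) on
  `-log M`, giving `min(I, J)` one-to-one matches, followed by a greedy
  polish (pair swaps, replacements by unassigned pits, 3-cycles) applied
  while the total affinity increases — the soft iteration can flatten
  rankings among nearly-zero affinities, and the polish removes those
  artefacts. The tests verify the discretized matching attains at least
  0.99 of the brute-force-optimal total affinity on all seeded instances
  with up to 8 pits a side and recovers noiseless permutations exactly.
* **Coarse rescaling**: six per-half-axis factors
  `f = mean |P coord| / mean |Q coord|` computed from the pits on that
  half-axis; rescaled P divides by the factors, mapping the early brain
  onto the later brain's scale. Absolute values are used in the means
  (signed means of a negative half-axis would flip sign); coordinates of
  exactly 0 count to the positive side (deterministic, measure-zero
  rule); a half-axis empty in the reference yields factor 1 with a
  warning. Both brains must share the anatomical origin, which holds for
  atlas-registered scans and for all synthetic cohorts.
* **Refinement**: least-squares rigid alignment (Kabsch, det +1) of the
  strongly paired pits (similarity > 0.5, strict), then re-matching and a
  final strong-pair filter. Fewer than 3 pairs or a collinear
  configuration falls back to the identity with a warning. The second
  stage is rigid (rotation + translation); a uniform-scale option exists
  behind a flag.
* **SDSP** is the mean similarity over the final strong pairs, 0 with a
  `no-strong-pairs` flag when none survive. Note the scoring uses only
  retained pairs: two brains sharing a handful of coincidentally close
  pits can score high on that handful, which is why cohort analyses work
  with realistic pit counts (tens per brain) where such flukes average
  out.

A property worth stating precisely: matching a cloud against a rigidly
moved copy of itself recovers SDSP = 1 to machine precision when the
coarse stage is disabled (same-scale brains). With the coarse stage
enabled the six-factor rescale is not exactly rigid-neutral, and the
recovered SDSP is high but not 1 (about 0.98–0.998 at rotations up to
15 degrees in the tests). This is inherent to composing a half-axis
rescale with a rigid refinement.

# Synthetic data

`makeSmoothBrain()` builds geodesic-sphere ellipsoids (default semi-axes
40/33/28 mm, fetal-hemisphere scale) with radial undulations summed from
randomly oriented zonal waves of prescribed frequency and amplitude,
emulating primary folds; amplitudes are validated against the embedding
bound (min semi-axis / 4). `makePitCloudCohort()` draws first-timepoint
pits in an ellipsoidal shell and produces second-timepoint clouds by six
independent half-axis growth factors (default 1.1–1.5), a small residual
rigid motion (defaults 3 degrees / 1 mm, reflecting atlas-registered
scans sharing an anatomical origin), isotropic jitter (1 mm), and pit
birth (default 20%, placed near midpoints of close pit pairs to mimic
secondary sulci branching; configurable off). Default pit counts (30–60)
emulate per-hemisphere counts of later-gestation fetal brains.
`makeDepthPhantom()` puts analytic Gaussian depth bumps with prescribed
pit and saddle depths on a sphere, providing exact basin ground truth for
the watershed.

What the synthetic data do *not* emulate: real sulcal anatomy (no shared
sulcal layout across subjects — inter-subject similarity is therefore
purely geometric), MRI segmentation noise and topology defects, regional
cortical-thickness variation, and hemispheric asymmetries. Passing tests
show the algorithms are correct and self-consistent under known ground
truth, not that the biological conclusions transfer to any particular
scanner or cohort.

# Desk-scale study conditions

The simulated cohorts use brains of ~12.5/11.5/10.5 mm semi-axes with the
anatomically plausible 1.4 mm cortex, 1.1 mm surface edge, three
undulation modes (frequencies 3/5/7, amplitudes 1.5/1.05/0.53 mm), growth
ratio 4, a white-matter growth target of 1.35, 10000 explicit steps and
seven emitted stages — a few times 1e4 tetrahedra per subject, versus
millions at full scale. These sizes keep a full five-subject cohort
(simulation, pit extraction at eight stages, all-pairs matching) within
minutes while reproducing the qualitative phenomenology: folds nucleate
at the seeded primary undulations, pit counts rise and then stabilise,
and early-stage models match their own late-stage models.

# Known limitations

* The remesher requires star-shaped genus-0 input; it is a conditioning
  tool for smooth early-stage surfaces, not folded ones.
* Penalty self-contact is desk-scale: deep, tightly appressed folds at
  much larger growth would need a proper contact solver.
* Growth beyond `theta_w ~ 1.4` at these resolutions approaches element
  inversion in sulcal fundi; the default target stays below that.
* The DPF calibration gain is a package convention; absolute DPF values
  are not comparable with other implementations, though rankings and
  basin structure are.
* t-tests in `stageCourse()` are per-comparison two-sided without
  multiplicity correction (a Bonferroni option exists), mirroring
  per-comparison reporting conventions.
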