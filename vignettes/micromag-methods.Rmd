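---
title: "Modelling magnetic cell guidance on micro-magnet arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling magnetic cell guidance on micro-magnet arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micromag)
```

## The physical picture

A cell whose membrane carries superparamagnetic microbeads acquires a
magnetic moment proportional to the number of beads. Above a patterned
thin-film magnet the stray field **B** is strongly inhomogeneous, and a
bead below saturation has moment **m** ∝ **B**, so the attraction force is

F = k (**B**·∇)**B** = (k/2) ∇|**B**|²,

the second form holding because ∇×**B** = 0 outside the magnetic material.
At cellular scales inertia is negligible (Re ≪ 1) and the force is balanced
instantaneously by Stokes drag 3πµDu, so each object moves at terminal
velocity u = F/(3πµD). Two consequences carry the package's headline
predictions:

- speeds of co-located objects scale as (moment/diameter): doubling the
  bead count doubles the speed, and a free 2.8 µm bead moves 10/2.8 ≈ 3.6×
  faster than a 10 µm cell carrying one bead;
- trajectories are overdamped gradient ascent on |**B**|², terminating at
  local maxima of the force landscape ("hot spots") — the pole tips of an
  in-plane magnetized bar.

## Stray-field model

Each pattern shape is a uniformly magnetized rectangular prism. Its field
is computed from the equivalent surface-charge model: every magnetization
component M_i places sheets of charge ±M_i on the two faces normal to axis
i, and the field of a uniformly charged rectangular sheet has a closed
corner-sum form (log terms in-plane, an arctan term normal to the sheet).
The kernel is validated in the tests against an independent
Gauss–Legendre surface integration to 10⁻⁶ relative and against the
point-dipole limit at 100× the prism size to 1%.

Choices worth knowing:

- **Fixed, uniform magnetization.** The films are magnetized by an external
  magnet along a fixed axis (in-plane for permalloy bars, out-of-plane for
  CoFe/Pd). We do not solve a self-consistent susceptibility problem; µ0M
  defaults to 1 T and all shipped claims (hot-spot count, anisotropy,
  speed ratios) are invariant to this scale. The absolute induced
  magnetization of the films is not known, so absolute field values carry
  this free factor; a calibration helper (`calibrate_k_lin`) pins the
  force scale to one observed speed instead.
- **True film thickness.** The analytic kernel is exact at nanometre
  thickness, so no thickness/magnetization rescaling is needed; the
  thin-film equivalence (field depends on M·t when t is much smaller than
  the observation distance) is demonstrated as a test rather than used as
  a workaround.
- **Points in a charge-sheet plane.** The sheet-normal field component has
  a jump across the sheet; exactly in the sheet plane (but outside the
  sheet) its two-sided limit is 0, and the kernel returns that limit for
  points within 1 nm of the plane. This keeps evaluations on symmetry
  planes exactly symmetric.
- **Rotated shapes** (zigzag segments) are handled by rotating evaluation
  points and magnetization into the shape frame and rotating the field
  back.

Forces are central differences of the analytic field (step 0.05 µm, well
below the ~2 µm feature scale at the standard 2 µm evaluation height).
Both force forms are implemented independently and agree to 10⁻³
relative; the sampled force map is curl-free to the same tolerance once
the grid is fine enough (the discrete curl of a sampled gradient field
vanishes only to O(spacing²); 0.25 µm suffices at 2 µm height).

## Hot spots and anisotropy

Hot spots are strict local maxima of |F| above 5% of the global maximum
(8-connected, plateaus merged to their centroid; the detection rule is a
package choice, as no published rule exists). For the 200 × 50 µm² bar at
2 µm this yields exactly two spots at the pole tips, and the peak force
along the long-axis midline (x = 0) exceeds the transverse-line peak
(y = 80 µm) by ≈ 10³·⁰⁵ — the line maxima are sampled both by grid
extraction and by dense analytic sampling, which agree.

## Kinetics

`simulate_trajectory` integrates x' = F/(3πµD) with explicit adaptive
steps capped in displacement (default 0.5 µm, half the standard grid
spacing), stopping on hot-spot capture (default radius 5 µm, one cell
radius), domain exit, or a time budget; tracks are reported at 1 s
intervals, the cadence of the time-lapse data the generator emulates.
Near a narrow ridge of |B|² an explicit step can overshoot the crest and
descend briefly; the overshoot shrinks with the square of the step cap,
and the gradient-ascent tests run at cap 0.1 µm with a 0.5% tolerance.
There is no Brownian term (an optional Gaussian frame-displacement noise
exists but defaults off), no wall-drag (Faxén) correction, and the drag
diameter is the cell's even when beads are attached — all deliberate
simplifications matching the drag-balance model.

Default medium viscosity is 8.9·10⁻⁴ Pa·s (water-like culture medium at
room temperature); it cancels in every ratio-based claim.

## Geometry and the uniform-landing null

A 10 µm cell touches a magnet when its centre is within one contact
margin of the footprint, so the touchable ("effective") area is the
footprint dilated by a disk. The default margin is 10 µm (one cell
diameter, the convention behind the reported effective areas); the
physically minimal touching criterion would be the 5 µm cell radius, and
the radius is a parameter. Dilation of the
vector pattern is analytic (a pixel is occupied iff its centre lies
within r of a shape, using exact point-to-box distances); raster masks
can also be dilated morphologically (EBImage disc brush) and the two
routes agree. For the bar array (unit cell 200 × 400 µm²) the nominal
fraction is 10,000/80,000 = 0.125 and the effective fraction at 10 µm is
(10,000 + 500·10 + π·10²)/80,000 ≈ 0.191, matching the closed-form
Minkowski area A + Pr + πr² and a 0.1 µm rasterization oracle within 1%.
The effective fraction is the null probability p₀ for the proportion
test. The line/web/zigzag presets ship with package-chosen default
dimensions (none are published), so their fractions are
configuration-dependent.

## Statistics

- **Velocity fits.** The speed of a tracked object is the OLS slope of
  distance against time. By default the distance is measured from the
  first frame ("net"); the cumulative path-length variant is available
  (`method = "path"`) but is biased upward under localization noise —
  each frame's error adds its modulus to the summed step lengths, giving
  a bias ≈ σ²/(v dt²) (+0.025 µm/s at the generator defaults, several
  standard errors) — while the net fit is unbiased and the two coincide
  exactly for the straight-line motion the model predicts. The recovery
  test (100 seeds, σ = 0.5 µm, 60 frames) checks the slope against OLS
  sampling theory.
- **Proportion test.** One-sample test of the touching fraction against
  p₀: a continuity-corrected z statistic when np₀ and n(1−p₀) reach 5,
  exact binomial otherwise, both two-sided. Exact enumeration at n = 100,
  p₀ = 0.175 puts the true size of the corrected z test at 0.034
  (conservative, as continuity corrections are), the uncorrected z at
  0.064, and the exact test at 0.048; the calibration test therefore
  exercises the exact method, and users testing small samples should
  prefer it too.
- **Welch t-test** for two-arm comparisons, two-sided, α = 0.05
  throughout, no multiple-testing correction — the conventions of the
  assay this package models. The degenerate zero-variance/equal-means
  case reports p = 1 with a flag.
- **Occupancy.** Cells touching the pattern (exact distance ≤ touch
  radius), hot spots occupied (≥ 1 cell within the capture radius), and
  cells per bar (nearest-centroid assignment), with p₀ attached.

## Synthetic-data generator

The generator emulates the statistical structure of the experiment, not
its images:

- **Labeling.** A cell binds ≥ 1 bead with probability p_bind; bound
  cells carry 1 + Poisson(λ) beads. The MMP-SA preset uses
  p_bind = 0.823 and an overall mean of 2.8 beads per cell averaged over
  all cells — the "per cell" average is interpreted as over the whole
  population, so λ = 2.8/0.823 − 1 ≈ 2.40; the IgG control uses 0.127
  and 0.2. A plain Poisson cannot match both the binding fraction and
  the mean, hence the zero-inflated shifted form; the count law is a
  pluggable model object.
- **Landings** are i.i.d. uniform over the substrate extent — the null
  the proportion test assumes.
- **Tracks** are straight constant-speed motion (default 10 µm/s, i.e.
  ~50 µm in 5 s, 1 s frames) plus i.i.d. Gaussian localization noise
  (default σ = 0.5 µm, a sub-pixel tracking scale; no published value).

Every stochastic call requires an explicit seed and runs in a local RNG
scope; bundles written by `generate_experiment` are byte-identical under
a fixed (config, seed) and are staged atomically. What the generator does
*not* model: per-experiment variance between biological replicates,
bead-count measurement error, cell–cell interactions, adhesion after
capture, or image formation — so passing tests validate the pipeline's
statistics, not the biology of any particular dish.

## Problem sizes and numerical defaults

The standard force map is 0.5 µm spacing over one bar neighbourhood
(161 × 521 nodes, ~1 s to evaluate); conservativity is checked at
0.25 µm; area-fraction oracles rasterize at 0.1 µm; the generator
calibration uses 10,000 cells; the type-I calibration simulates 10,000
binomial draws; velocity recovery uses 100 seeds × 60 frames. These sizes
were chosen to estimate each quantity well inside its acceptance
tolerance.

## Known limitations

- Absolute fields and forces carry the unknown induced-magnetization and
  susceptibility scales; only one observed speed is needed to calibrate
  them, but no first-principles absolute prediction is attempted.
- The external permanent magnet used to pull cells across a dish is not
  modelled (its field profile is unpublished); constant-velocity tracks
  stand in for it.
- Polyline joints are covered by overlapping segment boxes (a raster-level
  approximation of mitring); areas of self-overlapping strokes are
  measured by rasterization, not summed analytically.
- The proportion test's z variant is conservative at small n; use the
  exact method there.
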