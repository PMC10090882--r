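---
title: "Methods: comparative allometry of the amniote nasal cavity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative allometry of the amniote nasal cavity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nasallom)
```

## The scientific question

Endothermic amniotes (birds, mammals) carry respiratory turbinates in their
nasal cavities; ectotherms do not. If the turbinate's job is heat and water
exchange for the whole body, nasal-cavity size should scale with *body
mass* differently in the two groups. If instead its primary job is
selective brain cooling, the difference should appear against *head size*
(skull volume, or the volume of the minimum convex hull of the skull — a
soft-tissue-free head model) while the body-mass relation stays shared.
`nasallom` implements the statistical machinery to ask that question, the
morphometry to produce the size measurements from labelled CT volumes, and
the osteologically constrained reconstruction needed to place a fossil
skull's airway relative to the two groups' allometric lines.

## The statistical model

All variables are log10-transformed, so allometries are straight lines
$y = a_g + b_g x$ with group-specific intercept and slope. Three line
fitters are provided:

* **OLS** — ordinary least squares (`fit_ols()`).
* **SMA** — standardized major axis, `b = sign(r)\,s_y/s_x`
  (`fit_sma()`): symmetric in the axes, appropriate when neither variable
  is an error-free predictor.
* **PGLS** — generalized least squares with residual covariance
  $\sigma^2 C$, where $C_{ij}$ is the root-to-MRCA path length of tips
  $i,j$ under Brownian motion on a time-calibrated tree
  (`bm_covariance()`, `fit_pgls()`). $\hat\beta = (X^\top C^{-1}
  X)^{-1} X^\top C^{-1} y$, computed through a Cholesky factor of $C$;
  the residual scale uses the unbiased $n-2$ denominator; with $C = I$
  the fit reduces exactly to OLS, and $\hat\beta$ is invariant to
  rescaling $C$.

Species with several specimens are kept as separate operational units by
replacing their tip with a polytomy whose pendant branches are 1 Ma long,
shortening the stem by 1 Ma so the tree stays ultrametric
(`expand_conspecific_tips()`).

### The conditional comparison scheme

For each comparison (`compare_groups()`), the **slope difference** is
tested first: a Wald $t$ on the group-by-size interaction in the pooled
(G)LS model ($df = n-4$) for OLS/PGLS, and a likelihood-ratio
common-slope test (correlation between residual and fitted axes at the
common slope, $\chi^2_{k-1}$) for SMA. Only when the slope test does
*not* reject at $\alpha$ is the **intercept difference** tested at a
common slope: classical ANCOVA $F$ for OLS, a Wald $t$ on the group dummy
in common-slope GLS for PGLS (phylogenetic ANCOVA), and the elevation
test at the common SMA slope for SMA. When slopes already differ the
lines differ and an elevation comparison is meaningless; the report
records "not tested" (rendered as a dash in CSV exports). Raw p-values
are reported per comparison; no multiple-testing correction is applied.

Two numerical details are worth recording. First, the SMA elevation
variance uses the curvature (observed information) of the common-slope
likelihood-ratio profile rather than the closed-form asymptotic slope
variance; the closed form is anticonservative when the two groups'
$\bar x$ are well separated, which is the rule rather than the exception
for phylogenetically clustered groups. The statistic is referred to
$t_{N-4}$. Second, Wald statistics on noise-free data (zero residual
variance) are defined as 0 when the coefficient is 0, so exact synthetic
lines yield $p = 1$ instead of 0/0.

PGLS assumes pure Brownian motion; Pagel's $\lambda$ is deliberately not
estimated. A singular $C$ (for instance, duplicated zero-length tips) is
reported with a suggestion to jitter, never silently regularised.

## The comparison grid and pipeline

`run_full_analysis()` executes the study design: the whole nasal cavity
against body mass, skull volume and hull volume, plus the respiratory
region against the two head-size proxies (five comparisons), each with
surface area and volume as response, for each requested method. Mammals
are excluded from respiratory-region cells (their respiratory/olfactory
boundary cannot be drawn consistently from epithelium maps), and the
pipeline enforces this structurally. Fossil rows (thermoregulatory class
`NA`) never enter any fit; they are placed afterwards.

Body-mass provenance follows a precedence: a direct measurement, else a
species mean, else a power-law estimate from a length measurement
(`estimate_crocodylian_mass()`). The power-law coefficients are
configuration values, not constants baked into the package, because
published crocodylian length–mass equations differ by species and length
measure; the caller records which one was used.

## Morphometry

A `labeled_volume` is a 3D integer grid with per-axis spacing in mm;
voxel $[i,j,k]$ (0-based) is centred at $\mathrm{origin} + (i+\tfrac12)
\cdot \mathrm{spacing}$, with the x axis rostrocaudal. Volumes are voxel
counts times the voxel volume (exact for the voxelised region). Surface
areas are measured on a triangulated isosurface: the binary mask is
zero-padded, smoothed with a separable Gaussian ($\sigma = 0.9$ voxels),
and the 0.5 level set extracted by marching tetrahedra with linear
interpolation. On spheres of radius $\ge 15$ voxels this recovers
$4\pi r^2$ to better than 0.5%; raw voxel-face counting would
overestimate by up to ~50%, and unsmoothed marching tetrahedra by ~27%.
Objects too small to survive smoothing fall back to the unsmoothed
binary triangulation, whose faceting constant is documented: a single
1 mm voxel measures 3.62132 mm². Label boundaries created by the
respiratory/olfactory split are *included* in each region's area
(a closed-region measurement); whether segmentation suites include such
cut faces is not standardised, so the convention is fixed and stated
here.

The convex-hull head model is the quickhull of **all** vertices of the
bone isosurface (not voxel centres), and its volume the signed
tetrahedron sum over outward-oriented hull facets. `mesh_volume()`
validates watertightness (every directed edge used exactly once) before
integrating.

## Airway reconstruction and fossil placement

`crop_main_airway()` applies four osteological constraints to a
bony-bounded cavity: (I) a plane at the rostralmost bony nostril, (II) a
boundary keeping the main passage dorsal to the maxillary antrum
(a plane in the phantoms; its normal must point toward the airway and is
validated against an interior seed point when one is supplied), (III) a
transverse plane at the caudal edge of the bony choana, and (IV) a
caudal cap through the rostral terminus of the mesethmoid septum,
implemented as a plane normal to the rostrocaudal axis because only a
terminus point is anatomically defined. The nasal vestibule is included
in the main airway. Cavity voxels caudal of the choana up to the
mesethmoid cap become olfactory; everything else that fails a constraint
is relabelled `excluded`, so the three output labels partition the input
cavity exactly, and adding a constraint can only shrink the airway.
Mucosal constriction is handled only as the scalar 40–60% soft-tissue
fraction (`soft_tissue_corrected_range()`); finer soft-tissue modelling
is out of scope. For a skull missing one side's bones, the preserved
antimere volume is added once (`add_mirrored_component()`).

`place_fossil()` locates a fossil between the two fitted lines in log10
space by $\rho = (y - \hat y_{ecto}) / (\hat y_{endo} - \hat y_{ecto})$:
0 on the ectotherm line, 1 on the endotherm line, 0.5 exactly midway.
$\rho$ is reported for the bony-bounded volume and for both soft-tissue
corrected endpoints; exchanging the lines maps $\rho \mapsto 1-\rho$.

## The synthetic-data generator

Because the raw measurements behind such studies live in supplementary
tables, every stage here is exercised on synthetic data whose truth is
known:

* **Trees** — Yule, conditioned on the tip count, rescaled to a fixed
  depth (default 300 Ma, an amniote-scale root age). The simplest
  ultrametric generator with direct depth control.
* **Traits** — body mass evolves by Brownian motion (rate
  `sigma_x2 = 0.007` log10²/Ma, giving a ~3-orders-of-magnitude size
  range over the tree); residuals are Brownian too (rate
  `sigma_e2 = 5e-6`, tip s.d. ≈ 0.04 log10 units — the tight-scatter,
  high-$r^2$ regime in which allometric method checks are informative),
  with an i.i.d. option for robustness checks. Group assignment defaults
  to `by_clade`: one subclade (the internal node closest to half the
  tips) forms the endotherms, mimicking the single phylogenetic origin
  of endothermy — deliberately the hardest case for between-group tests.
* **The full specimen table** (`simulate_specimen_table()`) encodes the
  brain-cooling scenario: nasal responses follow body mass with *no*
  group term (mass comparisons null by construction), while skull volume
  carries a clade offset (`head_offset = -0.3` log10: endotherm heads
  smaller for their mass), so nasal size relative to head size differs
  between groups. Surface-area residuals are 2/3 of the volume residuals
  plus a small independent part, as when both are measured on one
  segmented cavity. The hull sits a fixed 0.18 log10 above the skull and
  the respiratory region is ~55% of the whole cavity.
* **Phantoms** (`generate_skull_phantom()`) — a box-shell "skull"
  enclosing an axis-aligned ellipsoidal cavity split by a plane. Every
  measurement has a closed form: ellipsoid volume $(4/3)\pi abc$, plane
  partitions via the spherical-cap formula after rescaling to the unit
  ball, and area via the Thomsen approximation ($p = 1.6075$, error
  ≤ 1.1%, hence area checks use a 2–3% tolerance). The default split
  plane passes through the cavity centre, which falls *between* voxel
  centres, so the voxelised split matches the analytic slab without a
  half-voxel bias. Default semi-axes (26, 18, 16) mm at 1 mm spacing
  keep voxelisation error near 0.01% for volumes.

What the generator does **not** emulate: real skull anatomy (turbinates,
sinus recesses, curved antrum walls), measurement error in the size
proxies, non-Brownian trait evolution, and taxon sampling biases.
Passing tests therefore demonstrate correctness of the computational
pipeline under its stated model, not robustness of the biological
conclusion to violations of that model.

## Calibration design

The type-I calibration study (`type1_calibration()`) evaluates each
estimator under its own residual model: OLS and SMA tests under i.i.d.
residuals, PGLS tests under Brownian residuals, always with a
Brownian size trait and clade-clustered groups. Running OLS on
Brownian-correlated residuals with a clade-clustered group would measure
the well-known phylogenetic confounding of non-phylogenetic tests —
interesting, and visible in any full OLS run on the default generator —
but it is a property of the data-generating mismatch, not of the test's
calibration. Rates are estimated from 1000 null simulations on a fixed
50-tip tree.

The contrast-replication study (`qualitative_contrast()`) generates 200
independent synthetic studies (50 species each, so roughly 25 per group)
and scores each run: all head-size cells significant, and no body-mass
cell significant. One structural point deserves honesty: the
slope-then-intercept scheme gives every comparison a *compound*
false-positive rate of about $\alpha + (1-\alpha)\alpha \approx 9.7\%$
even when both tests are individually exact, so with two (strongly but
not perfectly correlated) response cells per proxy, the expected
fraction of runs with fully silent body-mass comparisons is ~87%, not
$1-\alpha$. Interpreting per-comparison significance under this scheme
should account for that compounding.

## Problem sizes and runtimes

The shipped test suite uses 4–50-tip trees, 1000-simulation calibration,
200-run contrast replication, and phantoms up to 88×68×64 voxels —
sizes chosen so the whole suite runs in a few minutes on one core while
keeping Monte-Carlo standard errors small relative to the tolerances
asserted.

## Known limitations

* PGLS is pure-BM; no $\lambda$, OU, or measurement-error-in-x models.
* The antrum boundary accepts a plane or triangulated surface in
  principle, but only planar boundaries are exercised; real antrum walls
  are curved.
* SMA common-slope and elevation tests are asymptotic; at very small
  group sizes a permutation reference would be preferable.
* The isosurface area of thin (1–2 voxel) structures is governed by the
  faceting fallback and should not be treated as accurate.
* The generator's tight residual scatter means power estimates from it
  are upper bounds for noisier empirical data.
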