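---
title: "Hemisphere-restricted anatomical connectivity mapping: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hemisphere-restricted anatomical connectivity mapping: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(hemiacm)
```

## The method

Anatomical connectivity mapping (ACM) quantifies, for every voxel of the
white matter, how many probabilistic streamlines seeded throughout the
white matter pass through that voxel. Regions traversed by large, coherent
fibre systems accumulate high counts; focal damage, or loss of fibre
populations that compete for streamline propagation, changes those counts
in characteristic ways.

`hemiacm` implements a hemisphere-restricted variant: streamlines are
seeded only in one hemisphere's white matter and any streamline that
touches the mid-sagittal voxel plane — or crosses it — is discarded in
full, exactly as an exclusion ROI over the whole mid-sagittal plane would
do in a standard tracker. Left and right maps therefore reflect purely
ipsi-hemispheric connectivity, which makes their asymmetry interpretable.
Asymmetry is summarised by the lateralization index

$$\mathrm{LI} = 100\,\frac{L - R}{L + R} \in [-100, 100],$$

where $L$ and $R$ are mean values (ACM counts, FA, MD, or lesion volume)
over paired left/right ROIs. Positive values mean left dominance.

The package exercises the whole chain on synthetic phantoms: signal
generation, shell calibration, tensor fitting, tracking, ROI construction,
lateralization profiles, and group statistics with permutation-based
family-wise error control.

## The phantom

`default_phantom_spec()` defines a 40×40×40 grid at 2 mm isotropic
resolution (the mid-sagittal plane is the single voxel column at x index
20). Each hemisphere holds

* a vertical, corticospinal-tract-like bundle (radius 3.2 mm, 34 axial
  layers, volume fraction 0.25), and
* a shorter horizontal bundle (5 voxel columns) crossing it orthogonally
  at mid-height with volume fraction 0.75.

Each bundle voxel carries one fibre population (unit direction +
amplitude = volume fraction); crossing voxels carry both. The remaining
signal fraction is an isotropic compartment (0.6·10⁻³ mm²/s in tissue,
3.0·10⁻³ in CSF). Population tensors are axially symmetric with axial/radial
diffusivities 1.9/0.2·10⁻³ mm²/s.

Two geometric choices matter and were fixed by design:

* **The crossing population dominates the local fibre orientation
  distribution (0.75 vs 0.25).** During tracking the propagation direction
  is re-anchored each step to the population maximising
  amplitude × |cos θ| to the incoming direction. In a crossing voxel a
  corticospinal streamline whose dispersion has tilted it beyond
  $\arctan(a_\mathrm{cst}/a_\mathrm{cross}) \approx 18°$ is captured by the
  crossing population and terminated by the curvature limit. Intact
  crossing fibres therefore *steal* streams from the vertical tract;
  damaging them releases those streams. This is the mechanism by which
  crossing-fibre damage increases connectivity counts along the
  intersected tract.
* **The crossing segment is short relative to the vertical tract
  (5 vs 34 voxel columns).** Visitation counts in the crossing region are
  then dominated by vertical through-traffic, as in the brain, where the
  corticospinal tract's coherent traffic dominates its crossing zone. With
  a long crossing bundle, the bookkeeping loss of the crossing tract's own
  streamlines after damage would mask the competition effect.

Lesions are spheres in which fibre amplitudes are multiplied by
1 − severity (the removed fraction becomes isotropic). Two extensions over
the minimal model proved necessary to express the biology: a lesion may
target a *named bundle* only (tract-specific axonal degeneration), and a
lesion may be *invisible* — excluded from the binary lesion mask — which
models diffuse damage in normal-appearing white matter as opposed to focal,
segmentable lesions. Cohort-level crossing-bundle damage uses invisible
bundle-targeted lesions; focal lesions are small (1.2 mm radius, severity
0.95), visible, and placed uniformly along the bundles with a per-subject
left/right imbalance drawn from a Beta(2, 2) law. At this phantom scale a
focal lesion nicks a bundle rather than transecting it; larger radii would
let a single lesion sever the 3-voxel-wide tract, which has no analogue at
brain scale.

## Signal model and acquisition

`simulate_dwi()` uses a multi-tensor mixture: per voxel,

$$S(b, \mathbf g) = c_\mathrm{shell}\, S_0 \Big( \textstyle\sum_k a_k
 e^{-b\,\mathbf g^\top D_k \mathbf g} + f_\mathrm{iso} e^{-b d_\mathrm{iso}}
 \Big),$$

with optional Rician noise (magnitude of the signal plus complex Gaussian
noise; `noise_sd = 0` reproduces the closed form exactly, which the test
oracles rely on). The default scheme has three shells — 6 directions at
b = 300, 62 at b = 1000, 62 at b = 2000 s/mm², one b0 each — on a
deterministic spherical Fibonacci lattice, with per-shell intensity scale
factors (1.0, 1.1, 0.9) emulating TE/TR-driven inter-shell offsets.

`calibrate_shells()` removes those offsets: the overall mean b0 is the
voxel-wise average of the b = 1000 and b = 2000 shells' b0 images (which
shells contribute is configurable, since other choices are defensible);
each shell's volumes are divided by its shell-b0/mean-b0 calibration
image. Voxels with an undefined calibration (zero mean b0) are flagged in
a QC mask and passed through unchanged rather than zeroed or dropped. The
operation is idempotent.

`fit_tensor()` is a weighted least-squares fit of the log signal (weights
are squared predicted signals, two reweighting passes — the standard WLS
compromise between the bias of OLS-on-logs and the cost of full nonlinear
fits). Non-positive signals are excluded per voxel, not clamped, to avoid
log-domain bias; voxels with fewer than 7 usable volumes or non-positive
fitted MD are marked unfit. FA is clipped to [0, 1]. For genuinely
multi-compartment voxels the fitted tensor is *not* the mixture's
effective (small-b) tensor — at b = 2000 the bi-exponential decay is far
from log-linear — so exact-recovery claims are made, and tested, only for
single-compartment voxels. `extract_peaks()` turns a fit into a
single-population orientation field (principal eigenvector, amplitude =
FA, floor 0.1); multi-peak tracking is exercised against the phantom's
ground-truth field, which is also what the cohort pipeline uses.

## Tracking

For each white-matter voxel of the chosen hemisphere,
`seeds_per_voxel` (default 300, a count previously shown to give stable
ACM estimates; the package's stability test compares the coefficient of
variation at 30 vs 300) streamlines start at uniform positions inside the
voxel and propagate bidirectionally:

* step size 0.5 × voxel edge (1 mm);
* next direction ~ von Mises–Fisher around the selected population
  direction (sign-aligned with the incoming step), concentration
  `dispersion_kappa = 30` — about 13° mean angular deviation per step,
  comparable to probabilistic FOD samplers; `kappa = Inf` is the
  deterministic mode used by the enumeration oracles;
* termination on: maximum local population amplitude < 0.1, turn > 45°,
  white-matter mask exit, or length > 250 mm;
* streamlines shorter than 4 mm are discarded; any streamline with a point
  in a midline or contralateral voxel is discarded in full and accounted
  separately, so launches always reconcile:
  retained + midline-excluded + too-short = launched.

Counting is once per streamline per voxel ("number of streamlines running
through each voxel"), with segments supersampled at half the step size so
no traversed voxel is skipped; per-step counting would double-count slow
turns. Voxel membership uses 0-based indices under the NIfTI affine; the
midline is defined in voxel space, so the exclusion contract is exactly
testable. Whether a streamline should be counted once or per pass is not
uniquely determined by the method's description; visitation counting was
chosen because it makes counts interpretable as "streamlines through the
voxel" and keeps the enumeration oracle exact.

## ROI rules and lateralization

`make_nawm_mask()` implements the normal-appearing-white-matter rule
literally: WM ∧ ¬lesion ∧ ¬(FA < 0.3) — a voxel at exactly FA = 0.3 is
kept. `make_cst_mask()` includes voxels with tract probability strictly
above 10%. The synthetic tract atlas is a Gaussian fall-off of distance to
the bundle centerline (σ = radius/2), so the >10% contour sits near the
bundle boundary. Since all synthetic subjects share one grid, the
population-template registration step of a real study collapses to the
identity here; it is orthogonal to the method core. Slice-wise LI profiles
use per-slice ROI means (the same LI-of-means construction as the whole-ROI
index); slices with an empty side are flagged undefined rather than
imputed.

## Statistics

* `classify_fatigue()`: motor-fatigue classification at FSMC-motor ≥ 27
  (instrument range 10–50).
* `group_ancova()`: the repeated-measures ANCOVA is fitted as a linear
  mixed model on long-format data (side as within-subject factor, group
  between, random subject intercept) with age, sex and the total
  individual ACM count as covariates; omnibus F tests use Satterthwaite
  degrees of freedom, and pairwise group contrasts are computed only when
  the omnibus test is significant at 0.05. In the balanced designs used
  here, the between-group and interaction F statistics coincide with OLS
  on subject means and left-right differences, which is how the tests
  validate them against hand-coded projection matrices.
* `adjusted_correlation()`: partial Pearson correlation by residualising
  both variables on the covariates (with intercept), df = n − k − 2. The
  exact covariate adjustment used by point-and-click statistics packages
  is ambiguous; residualisation is the transparent choice and is
  documented as such.
* `tfce_transform()`: TFCE with the de facto standard H = 2, E = 0.5,
  26-connectivity and dh = max/100, computed by a descending-threshold
  incremental union-find (exact, not an approximation; verified against a
  per-threshold connected-component brute force at 10⁻⁹).
* `permutation_test()`: pooled-variance two-sample t maps, TFCE, and a
  max-statistic null over `n_permutations` relabelings (default 5000;
  exhaustive enumeration replaces sampling when fewer labelings exist).
  FWE p values use the plus-one estimator (b+1)/(m+1): unbiased under
  exchangeability and never zero. The t contrast is directional; test the
  negated maps for the opposite direction.
* `slice_group_test()`: per-slice Welch t tests, deliberately uncorrected,
  mirroring exploratory slice-wise profiles.

## What the synthetic cohort does and does not show

`make_cohort()` draws, per subject, crossing-bundle damage severities
around group means (fatigued-type: left 0.85, right 0.10; non-fatigued
type: reversed; controls: none; SD 0.10, clipped to [0, 1]), FSMC motor
scores increasing with left-hemisphere crossing damage and consistent with
the ≥ 27 cutoff, focal lesions as above, and demographic covariates. One
cohort seed fixes everything downstream, including per-subject tracking
seeds.

Passing the cohort-level tests shows that the *implemented pipeline*
transduces lateralized crossing-fibre damage into the expected signs:
higher ACM-LI in left-damaged than right-damaged groups, a positive
adjusted correlation between corticospinal ACM-LI and the fatigue score,
and a negative adjusted correlation between whole-NAWM ACM-LI and
lesion-load LI. It does not show that real fatigue has this mechanism:
the phantom has no gyrification, no distortion or motion artefacts, no
registration error, a two-bundle anatomy, and damage generated exactly
under the hypothesis being recovered.

## Problem sizes and numerical choices

Tests and the acceptance script run at deliberately reduced scale chosen
as the package's own desk-scale defaults: 10–30 tracking seeds per voxel
(launch bookkeeping is asserted at 300), cohorts of 10 per group,
permutation calibration with 500 permutations × 100 replicates on small
maps. Ties in population selection break to the lowest index; principal
eigenvectors are sign-normalised on their largest component; degenerate
inputs (empty masks, zero-variance slices, undefined calibration voxels,
zero-sum LI denominators) raise errors or flags rather than silently
producing numbers. All randomness flows through R's RNG — including
inside the compiled tracker — so a single `set.seed` reproduces any run
bit for bit.

## Known limitations

* The forward model is a tensor mixture, not a full spherical-deconvolution
  FOD; orientation dispersion within a population is represented only by
  the tracker's sampling kappa.
* Peak extraction from the tensor yields a single population per voxel;
  crossing-aware tracking requires the ground-truth field (or an external
  FOD source mapped into an `orientation_field`).
* The permutation engine covers two-sample designs; regression-style
  permutation (e.g. correlation maps) is out of scope.
* Lesion placement follows a simple uniform-along-bundle prior; real
  lesion topography (periventricular clustering) is not modelled.
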