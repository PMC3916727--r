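---
title: "Population receptive field mapping with prfmap: models, assumptions, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population receptive field mapping with prfmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prfmap)
```

## The problem

Retinotopic visual field maps (VFMs) — V1, V2, V3, hV4 and beyond — represent
the contralateral visual hemifield on the cortical surface with two orthogonal
gradients: eccentricity (distance from fixation) and polar angle. fMRI can
measure both gradients voxel by voxel with the population receptive field
(pRF) method: each voxel's aggregate receptive field is modeled as a 2D
isotropic Gaussian in visual space, with a preferred center $(x, y)$ and
spread $\sigma$. Changes in these maps — a shrunken foveal representation, or
enlarged foveal pRFs — are candidate cortical correlates of the visual decline
seen in healthy aging and in neurodegenerative disease.

`prfmap` implements this analysis end to end: the moving-bar stimulus, the pRF
forward model and fitter, eccentricity-band statistics of each map, and
two-group comparisons. Because real per-voxel data for such studies are rarely
published, the package also ships a synthetic cortical sheet generator with
known ground truth, so every stage can be validated quantitatively.

## The stimulus

`make_bar_sequence()` generates the standard bar-aperture movie: a bar of
width 2.75° (default: field radius / 4; the width is a convention of this
stimulus class, not a measured constant) stepping across an 11°-radius field
every 2 s, in eight configurations — four orientations (0°, 45°, 90°, 135°
from vertical), each swept in two opposed directions. One cycle is 192 s:
four 48-s periods, each holding two sweeps, with the last 12 s of every
period replaced by a mean-luminance blank. Blanks therefore recur at 4
cycles per scan, a frequency the bar itself never produces, which is what
makes them useful for separating stimulus-driven signal from baseline.

Two details are conventions fixed by the package (any fixed choice preserves
the model, because fitting always uses the actual generated sequence):

* **Sweep truncation.** Each sweep nominally takes 12 steps to cross the
  field diameter; the terminal blank replaces the last 6 steps of the second
  sweep in each period. Truncated configurations appear in both sweep
  directions across the cycle, so the union of bar positions still covers the
  full field — an invariant the test suite checks.
* **Configuration order.** Orientations are paired per period as (0°, 90°),
  (45°, 135°), (0°, 90°), (135°, 45°), first two periods sweeping in the
  positive normal direction, last two in the negative.

Apertures are binary on a 101×101 grid (side = field diameter); the
checkerboard texture and its 2 Hz contrast reversal are not modeled, since
the Gaussian pRF model is agnostic to the pattern inside the aperture.

## The pRF model and fitter

For a pRF $(x, y, \sigma)$ the predicted response at frame $t$ is the overlap

$$ r(t) = \sum_{\text{cells } c} A_t(c)\,
   \exp\!\left(-\frac{(c_x - x)^2 + (c_y - y)^2}{2\sigma^2}\right) $$

convolved causally with a hemodynamic response function and truncated to the
sequence length. The HRF is the canonical difference of gamma densities
(peak delay 6 s, undershoot delay 16 s, dispersions 1 s, undershoot ratio
1/6, 32 s support), parameterised with shape = delay/dispersion and scale =
dispersion; a single-gamma variant is available via `undershoot_ratio = 0`.
Sampled at the 2 s frame duration, the kernel's maximum falls on the 6 s
sample.

`prf_fit()` scores every candidate in a bank (`prf_grid()`: default 25×25
centers spanning ±11° and 16 log-spaced σ from 0.25° to 11°) by the variance
its prediction explains after fitting an amplitude and intercept by least
squares. The amplitude is constrained nonnegative — a pRF predicts positive
BOLD modulation — so candidates whose best unconstrained amplitude would be
negative score zero. With that constraint, variance explained reduces to the
squared positive part of the Pearson correlation between prediction and data,
which is what makes the exhaustive search cheap: one matrix product scores
the whole bank for all voxels at once. The grid optimum is optionally
polished by a Nelder–Mead search over $(x, y, \log\sigma)$ (`refine = TRUE`),
which matters whenever true centers fall between lattice points: the default
lattice spacing is 0.92°, so grid-only eccentricity errors can approach half
of that per axis.

Numerical conventions worth knowing:

* Ties in variance explained resolve to the first candidate in scan order —
  ascending σ, then y, then x — making fits bit-reproducible.
* An all-constant voxel returns `variance_explained = 0` with a `no_signal`
  flag rather than an error.
* Polar angle uses the quadrant-aware `atan2(y, x)` (the one-argument
  arctangent form seen in print is ambiguous across hemifields), with
  `(0, 0)` assigned angle 0 by convention.
* Variance explained is clipped to [0, 1] and is invariant to positive
  rescaling and offsets of the data; `ve_to_coherence()` maps it to the
  traveling-wave coherence convention ($\mathrm{coh} = \sqrt{VE}$, so the
  usual 0.20 coherence threshold equals VE 0.04; the often-quoted baseline
  noise pair 0.15/0.03 is approximate, since $0.15^2 = 0.0225$).

Preprocessing follows the usual pipeline: per-scan polynomial detrending
(default order 2 — removes drift below ~1 cycle/scan while leaving the
4-cycles/scan blank structure essentially untouched) and pointwise averaging
of repeated scans (`detrend_ts()`, `average_scans()`).

## The synthetic cortical sheet

`build_sheet()` lays each map (V1, V2d/V2v, V3d/V3v, hV4, both hemispheres)
on a regular cortical lattice and assigns ground truth from a complex-log
retinotopic template: eccentricity along the cortical axis $u$ follows
$\varepsilon(u) = a(e^{u/k} - 1)$ with $a = 0.75°$ and $k$ set so the 11°
field spans 40 mm in V1 (V2/V3/hV4 scaled by 0.8/0.7/0.5), so equal cortical
steps over-represent the fovea — with the defaults, 60% of V1 area carries
the central 3°. Polar angle is linear along $v$, a full hemifield for V1 and
hV4 and quarterfields for the V2/V3 components. pRF spread follows
$\sigma = m\,\varepsilon + b$ per map (V1: $0.1\varepsilon + 0.5$, V2:
$0.15\varepsilon + 0.7$, V3: $0.2\varepsilon + 0.9$, hV4:
$0.25\varepsilon + 1.1$), ordered as in published size-vs-eccentricity
measurements. These constants are calibration choices — the organization,
not the exact numbers, is what published maps constrain — and all are
configurable.

Scenario presets perturb this template:

* **aging** multiplies the area of nodes below 3° by 0.6 and their σ by 3.6.
  The σ factor is anchored so the ground-truth mean σ in the most foveal V1
  band is ≈2°, matching the reported magnitude of foveal pRF enlargement in
  aging V1; the area factor encodes the direction (central surface-area
  loss), not a published effect size.
* **ad_scrambled** permutes eccentricity between ~4 mm cortical patches
  (polar angle untouched) and halves response amplitude — patchy, disordered
  eccentricity maps with reduced variance explained.
* **ad_truncated** compresses eccentricity into `[0, 5°]` — maps lacking
  their peripheral representation.

`simulate_bold()` generates raw scans: the truth pRF's prediction normalized
to unit SD and scaled by the node amplitude (so amplitude is the per-scan
signal SD in percent-signal units), plus AR(1) Gaussian noise (lag-1
coefficient 0.3, marginal SD 0.2 — per-scan SNR 5 at the default amplitude
of 1) and a random linear-plus-quadratic drift (scale 0.5). Per-subject
variability comes from `jitter_config()`: multiplicative lognormal jitter
(SD 10%) on $a$, the cortical length, and the σ-law coefficients.

What this generator does **not** emulate: folded cortical geometry and
partial-volume mixing, vascular and motion artifacts, spatially correlated
noise, HRF variability across cortex and age, and attentional/fixation
effects. Passing tests therefore demonstrate that the estimator and
statistics recover what this generative model encodes — not that real
young/aging/AD cohorts would show these effect sizes.

## Eccentricity-band statistics

`make_ecc_bands()` builds the ten 1°-wide half-open bands covering [0, 10)
centered on half degrees. Per band and map, `band_profile()` computes
summed cortical surface area (nodes at VE ≥ 0.04), mean variance explained
(all nodes, deliberately unthresholded — it is a responsivity measure, and
thresholding it would bias groups with lower signal quality), and mean σ
(thresholded). Band membership uses *fitted* eccentricity; values ≥ 10° fall
outside the band set. `percent_distribution()` divides band areas by the
map's total banded area (×100): a two-dimensional cortical-magnification
summary that, unlike the classical mm/deg curve, integrates across polar
angle. Reporting is conventionally restricted to the bands centered
1.5°–9.5° (the bar stimulus measures neither the exact center of gaze nor
the field edge cleanly), while the denominator keeps all ten bands —
`percent_distribution()` exposes both choices.

`subject_band_profiles()` computes all statistics per hemisphere, averages
between hemispheres, and only then are subjects combined — matching the
convention that hemisphere averaging precedes group analysis.

## Group comparisons

`manova_bands()` compares two groups on a band subset with Wilks' Λ,
converted to its exact F for the two-group (Hotelling $T^2$) case:
$F = \frac{N-p-1}{p}\,\frac{1-\Lambda}{\Lambda}$ on $(p, N-p-1)$ df. With
the study-sized cohorts (5 vs 4) this gives F(3, 5) for the central-3°
subset (bands 0.5/1.5/2.5) and F(7, 1) for the peripheral subset
(3.5–9.5). Degrees of freedom are always reported as (df-effect, df-error);
published reports sometimes print the pair in the opposite order. A
singular within-group covariance (e.g., a band that is structurally empty
for every subject, which happens when a coarse candidate lattice leaves an
eccentricity annulus unreachable) raises an explicit error naming the
deficient dimension rather than returning a misleading statistic.
`anova_total_area()` (one-way F via `aov`) and `ttest_two_sample()` /
`ttest_from_summary()` (pooled-variance t) cover the univariate
comparisons. No multiple-testing correction is applied across maps and
statistics, matching common practice for these small exploratory cohorts;
`p.adjust` can be applied to the tidy output when desired.

## The pipeline

`run_pipeline()` ties the stages together for simulated cohorts:

```{r, eval = FALSE}
res <- run_pipeline(pipeline_config(scenarios = c(young = 5, aging = 4),
                                    seed = 1))
res$stats      # tidy MANOVA/ANOVA table per map, statistic and band subset
res$profiles   # subject-level hemisphere-averaged band profiles
```

Runs are bit-reproducible from `(config, seed)`; per-subject seeds derive
from the master seed. With `out_dir` set, profiles, totals, group statistics
and a provenance log are written as plain-text files. There is no shell
entry point: the exported functions are the interface, and `scripts/`
contains a worked driver.

## Problem sizes and defaults

The defaults are sized for interactive use on one CPU. A full-resolution
single-subject fit (101×101 stimulus grid, 10,000-candidate bank, ~700
nodes, 8 scans, refinement) takes a couple of minutes; `pipeline_config()`
therefore defaults to a reduced configuration (61-cell grid, 17×17×10 bank,
4 scans, no refinement) that preserves band-level statistics, which are
aggregate quantities and tolerate coarser per-node precision. The validation
suite uses three tiers: full resolution for single-subject parameter
recovery (median eccentricity error < 0.5°, median relative σ error < 25%
at SNR 5 with 8 scans); the reduced configuration for repeated cohort
simulations (direction-of-effect checks); and a ground-truth fast path
(`truth_estimates()`, which skips the BOLD stage and adds 5% band-level
measurement noise — a stand-in for fitting variability) for the MANOVA
type-I-error calibration, where thousands of cohort pairs are needed and
the question concerns the test, not the fitter.

## Known limitations

* The pRF model is the classical isotropic Gaussian with a fixed canonical
  HRF: no compressive spatial summation, surround suppression, per-subject
  HRF estimation, or anisotropic pRFs.
* Map boundaries are taken as given labels (known in the synthetic sheet);
  delineating boundaries from data is out of scope, as is any anatomical
  processing (segmentation, flattening, coregistration).
* Surface areas come from per-node area values supplied with the data; for
  real data the user must provide per-voxel areas computed on the 3D
  cortical manifold.
* The synthetic effect sizes are calibration choices anchored to one
  published magnitude (the ~2° aging foveal σ in V1); directions, not sizes,
  are the validated quantities for everything else.
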