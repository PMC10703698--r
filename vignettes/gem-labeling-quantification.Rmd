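---
title: "Quantifying GEM-tag labeling: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying GEM-tag labeling: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gemquant)
```

# The measurement problem

Genetically encoded multimeric particles (GEMs) are ~25 nm icosahedral
encapsulin shells that can be coupled on demand to GFP-fusion target
proteins. Because the shell is large and structurally distinctive, it is
directly visible in cryo-electron tomograms of FIB-milled lamellae, and its
fluorescent handle makes it trackable by light microscopy. Turning such
images into statements like "83% of particles lie within 50 nm of the
mitochondrial surface" or "a 138-fold enrichment over random placement"
requires a chain of quantification steps, each with conventions that affect
the numbers. This package implements that chain — and a synthetic-data
module that generates inputs with known ground truth, so every stage can be
validated end to end.

# The tomographic pipeline

## Detection postprocessing

A detection network emits a per-voxel particle-presence probability map.
`postprocess_probability_map()` converts it to particle coordinates by

1. binarizing at a threshold (default 0.5),
2. zeroing everything outside the lamella mask,
3. labelling connected components, and
4. keeping components whose voxel count, rescaled to a 13.7 Å reference
   pixel size by `(voxel_size / 1.37 nm)^3`, lies in [5,000, 50,000].

Two conventions are not dictated by the procedure itself and are explicit
design choices here:

* **Connectivity.** Components are labelled with the 26-neighbourhood
  (face + edge + corner) by default. This merges diagonal voxels of a
  single blob and is the conservative choice for not splitting a particle
  in two; a 6-neighbourhood mode is available
  (`detection_params(connectivity = "face")`).
* **Coordinate.** The particle centre is the probability-weighted centroid
  of its component (sub-voxel), not a bounding-box centre, matching the use
  of refined coordinates downstream.

The size filter is interpreted as a *physical-volume* bound anchored at the
13.7 Å reference: maps binned differently rescale their counts by the cube
of the voxel ratio, so accept/reject decisions are invariant under
resampling (tested as a property).

`preprocess_volume()` reproduces the standard filter chain used before
detection: Fourier Gaussian low-pass (cutoff 0.25 cycles/voxel), Gaussian
high-pass (5 voxels), zero-mean/unit-sd normalization, then a ±3σ clamp, in
exactly that order with no re-normalization after clamping. The Gaussian is
parameterized as an amplitude `exp(-f²/(2c²))`; filter dialects differ in
where they put the factor of 2, and this choice is pinned here and tested
against the analytic transfer ratio on white noise.

`detect_shells()` is a matched-filter stand-in for the network itself
(which is out of scope): normalized cross-correlation with a zero-mean
hollow-shell kernel, followed by greedy non-maximum suppression (highest
score first, lexicographic tie-break). It exists so the synthetic pipeline
can be exercised without a trained model; it achieves perfect recall and
precision on clean synthetic volumes but is not a substitute for a learned
detector on real data.

## Curation accounting

Manual curation of detector peaks is tracked by `curation_ledger()` /
`apply_curation()`: final count = peaks − Σ discards + manual additions,
with free-form discard categories (defaults: organelle-interior,
surface-damage, visual-reject). The arithmetic is trivial; the point is an
auditable provenance trail from detector output to the particle counts used
in statistics.

## Distances and enrichment

`surface_distances()` computes, for each particle, the Euclidean distance
from its centre to the nearest structure voxel — via an exact 3D Euclidean
distance transform, sampled at the continuous particle centre by trilinear
interpolation — and subtracts the 12.5 nm particle radius. Negative surface
distances mean particle–structure overlap.

Conventions adopted (and why):

* **"Within 50 nm" is a surface-distance criterion** (after radius
  subtraction) for all targets, and the boundary is inclusive; negative
  distances count as within, since physical overlap is maximal proximity.
* **Sampling.** Trilinear interpolation of the distance field is the
  default; nearest-voxel sampling is available as a compatibility switch
  (`sampling = "nearest"`).
* **Enrichment denominator.** `volumetric_enrichment()` computes
  `fold = f_P / f_V`, where `f_P` is the fraction of particles within the
  proximity cutoff of the structure and `f_V` the fraction of the lamella
  volume occupied by the structure dilated by 50 nm (exact Euclidean
  dilation) and clipped to the lamella. The lamella mask *is* the "total
  imaged volume"; excluding organelle interiors from the denominator is
  possible by passing a restricted lamella mask but is off by default.
* **Pooling.** Across tomograms, counts and voxel volumes are summed before
  dividing (`pool_enrichment()`), never averaged per-tomogram folds: small
  tomograms would otherwise dominate.

Under uniform random placement the fold statistic converges to 1; the test
suite verifies this at n = 2000 within Monte-Carlo error, and verifies the
distance transform against exhaustive nearest-voxel search and dilation
against lattice-ball enumeration.

# The fluorescence pipeline

`overlap_fractions()` reports both directions of segmentation overlap
(tag-on-target and target-on-tag); an empty mask yields a missing value,
never a silent zero. `per_grid_normalize()` divides each cell's intensity
by the mean of all cells on the same grid, with optional per-batch
correction factors. `compare_to_baseline()` runs a Kruskal–Wallis test and
Dunn's z tests against the baseline timepoint only, two-sided, with a
Bonferroni-type multiplication by the number of baseline comparisons
(capped at 1) — the "multiplicity-adjusted, compared to 0 min" convention
of common statistics packages. The exact adjustment convention of any given
commercial package is not pinned; the Bonferroni family-restriction is
documented as this package's convention and checked against a direct
rank-formula oracle. `rank_correlation()` defaults to Spearman (the
correlation flavour is otherwise unstated; Pearson is a flag away).

# FRAP fitting

`normalize_trace()` performs single normalization: background-subtract,
then divide by the prebleach mean (10 prebleach frames by default, 50 ms
frame interval), so the prebleach level is exactly 1. `fit_recovery()` fits

$$I(t) = I_\infty - (I_\infty - I_0)\,e^{-k (t - t_0)}$$

to the post-bleach frames by Levenberg–Marquardt least squares and reports
the half-life ln(2)/k. The time origin `t0` is the first post-bleach frame
and the bleach frame itself is excluded — intensity during the bleach is
ill-defined. Initialization is deterministic (I₀ = first post-bleach value,
I∞ = mean of the last 10% of frames, k from a log-linear regression), so
fits are reproducible. Non-recovering traces (k ≤ 0 or I∞ ≤ I₀) raise an
identifiability error with diagnostics rather than returning a misleading
fit. Both mean-trace fitting (one fit to the averaged trace, via
`mean_trace()`) and per-trace fitting with `aggregate_fits()` (mean ± sd
across traces) are provided; the ± spread reported by `aggregate_fits()` is
across traces, and is labelled as such.

```{r frap-example}
cfg <- frap_sim_config(true_half_life = 1.0, noise_sd = 0.05,
                       n_traces = 20, seed = 42)
fits <- lapply(simulate_frap_traces(cfg),
               function(tr) fit_recovery(normalize_trace(tr)))
agg <- aggregate_fits(fits)
round(c(mean = agg$mean_half_life, sd = agg$sd_half_life), 3)
```

# What the synthetic generators emulate — and what they do not

The generators define the study conditions under which the pipeline is
validated:

* `simulate_scene()` builds a slab lamella (default tilt 0°) containing a
  membrane plane, sphere or tube rasterized one voxel thick, and places
  25-nm hard-sphere particles: bound particles at surface distances drawn
  from a normal distribution (redrawn until geometrically admissible, up to
  1000 retries — unbiased in the bulk since the truncation only trims
  draws the geometry forbids), background particles uniform in the lamella
  outside the structure interior. Untilted membrane planes are snapped to
  the nearest voxel-centre layer so the rasterized membrane is exactly one
  voxel thick and recorded truth distances are reproducible to within a
  voxel diagonal.
* `render_probability_map()` paints spherical blobs (default radius
  13.7 nm) with peak values in (0.5, 1], a 5% quadratic edge taper (so the
  map maximum is at the particle centre), decoy blobs sized below/within/
  above the size filter, and additive Gaussian noise clamped to [0, 1].
* `render_density_volume()` draws particles as negative-contrast hollow
  shells over Gaussian noise, with an optional Fourier missing wedge
  (off by default — detection must not rely on it).
* `simulate_coloc_timecourse()` uses first-order saturation
  `f(t) = f_max (1 − e^{−t/τ})` for the expected bound fraction. This is a
  modelling choice of the generator: the recruitment data being emulated
  are reported empirically, without a kinetic model, and first-order
  binding is the simplest defensible stand-in.
* `simulate_frap_traces()` generates exact single-exponential recovery with
  constant background and Gaussian noise.

None of these emulate tomographic image formation (no CTF, dose weighting,
tilt-series projection or reconstruction artefacts), icosahedral symmetry
(spheres suffice for detection geometry), segmentation error in the
structure masks, or non-exponential FRAP physics (diffusion-limited
recovery, bleach-profile effects). Passing the synthetic suites therefore
demonstrates that the *quantification chain* is correct under its stated
assumptions — not that a detector or segmentation will perform equally on
real tomograms.

Default study conditions follow the emulated analyses where stated: voxel
size 1.37 nm, particle radius 12.5 nm, probability threshold 0.5, size
filter 5,000–50,000 voxels, proximity cutoff and dilation 50 nm, 10
prebleach frames at 50 ms. Where the emulated work states no value, the
defaults are chosen once as field-realistic (lamella thickness 100–150 nm,
typical of FIB lamellae; bound-distance spread 6 nm; blob peak range
0.8–1.0) and are not tuned.

# Numerical choices and degenerate inputs

* All randomness is seeded per generator config; identical configs give
  bit-identical outputs, and the full pipeline writes byte-identical
  artifacts for identical seeds.
* Problem sizes used in the validation suites are deliberately modest
  (64³–110³ voxel scenes for most properties; a 420×420×120 scene with 200
  particles for distance-recovery; 100 FRAP traces), which keeps the whole
  suite under a minute while leaving sampling error well inside the stated
  tolerances.
* Anisotropic voxels are rejected at construction — the emulated tomograms
  are isotropically binned, and supporting anisotropy would complicate
  every distance computation for no present use case.
* Constant volumes (zero variance) raise a normalization error in
  preprocessing; empty structure masks, empty distance collections and
  zero-volume regions raise input errors rather than returning silent
  zeros; a dilation radius below one voxel warns and returns the input.
* The distance transform is the exact separable squared-EDT (no chamfer
  approximation); connected components use an explicit-stack BFS, immune to
  recursion limits. Both are implemented in C++ because no installed R
  routine provides exact 3D versions.
* Hard-sphere placement uses rejection sampling; requesting more particles
  than the geometry can hold fails loudly after 1000 retries per particle
  ("placement error") instead of degrading the configured distribution.

# Known limitations

* The matched-filter detector assumes approximately spherical,
  negative-contrast particles and clean backgrounds; it is a validation
  vehicle, not a production picker.
* Enrichment inference is reported as a point estimate; no confidence
  interval is attached (the emulated analysis reports none either). The
  uniform-null test quantifies the estimator's spread at n = 2000.
* 2D colocalization operates on single planes by default; the 3D mode is a
  straightforward extension via 3D masks but puncta segmentation is 2D.
* FRAP fitting assumes a single mobile population; two-component recovery
  will fit, poorly, as an averaged rate and is only detectable through the
  reported R².
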