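# gemquant

Quantification of encapsulin-based multimeric (GEM) tag labeling in
cryo-electron tomography and fluorescence microscopy.

GEMs are ~25 nm icosahedral encapsulin shells used as genetically encoded,
ligand-inducible tags for GFP-fusion proteins: large enough to be seen
directly in cryo-electron tomograms of FIB-milled lamellae, and
fluorescently labelable for light microscopy. `gemquant` implements the
quantification chain that turns such images into labeling statistics, plus
seeded synthetic-data generators that provide ground truth for validating
every stage end to end.

## What it computes

**Tomographic pipeline.** Detection probability maps are postprocessed into
particle coordinates (threshold 0.5, lamella masking, connected-component
size filter of 5,000–50,000 voxels at the 13.7 Å reference pixel size,
probability-weighted centroids), with EMAN2-style volume preprocessing
(Gaussian low-pass 0.25 cycles/voxel, high-pass 5 voxels, normalize, ±3σ
clamp) and auditable curation accounting (peaks − discards + manual
additions). Particle-to-structure proximity is measured as the **surface
distance**

    d_surface = d(center, nearest structure voxel) − r_particle,   r_particle = 12.5 nm

via an exact 3D Euclidean distance transform sampled at continuous particle
centres. Specificity is summarized by the volumetric fold-enrichment
(relative labeling index)

    fold = f_P / f_V,   f_P = (particles within 50 nm) / (all particles),
                        f_V = V(structure ⊕ 50 nm ∩ lamella) / V(lamella)

which equals 1 under uniform random placement.

**Fluorescence pipeline.** Mutual overlap fractions of tag and target
segmentations, Otsu-threshold puncta segmentation, per-grid intensity
normalization, Kruskal–Wallis + Dunn's baseline comparisons for recruitment
timecourses, and Spearman rank correlation for abundance–specificity
relationships.

**FRAP.** Single normalization (background-subtracted, prebleach mean = 1)
and single-exponential recovery fitting

    I(t) = I∞ − (I∞ − I₀) e^(−k(t − t₀)),   half-life = ln 2 / k

with per-trace aggregation (mean ± sd) and mean-trace fitting.

## Worked example

Simulate a lamella scene containing a 15-nm-radius membrane tube decorated
with 8 bound particles (surface distances ~ N(10, 4²) nm) plus 6 background
particles, render its detection probability map, and run the full pipeline:

```r
library(gemquant)

cfg <- run_config(
  scene = list(volume_shape = c(220, 220, 80), voxel_size = 1.37,
               lamella_thickness = 95, structure_kind = "tube",
               structure_params = list(radius_nm = 15),
               n_bound = 8, n_background = 6,
               bound_distance_mean = 10, bound_distance_sd = 4, seed = 5),
  prob_map = list(blob_radius = 16, seed = 6),
  seed = 5)
rep <- run_pipeline(cfg)
rep
#> <pipeline_report> ok
#>   detected particles : 14
#>   within cutoff      : 11/14 (78.6%)
#>   fold enrichment    : 2.01
rep$enrichment
#> <enrichment_result> 11/14 particles in region (f_P = 0.786)
#>   region volume fraction f_V = 0.3906 (39.1%)
#>   fold enrichment = 2.0
```

All 14 particles are recovered; the 11 within the 50 nm cutoff are the 8
bound particles plus 3 background particles that land near the tube by
chance, and the fold enrichment of 2.0 reflects that the dilated tube
occupies 39% of this (small) lamella — on real-scale lamellae the region
fraction is far smaller and folds correspondingly larger.

FRAP recovery on simulated traces:

```r
trs <- simulate_frap_traces(frap_sim_config(true_half_life = 1.0,
                                            noise_sd = 0.05,
                                            n_traces = 20, seed = 42))
agg <- aggregate_fits(lapply(trs, function(t) fit_recovery(normalize_trace(t))))
sprintf("half-life %.3f +/- %.3f s (n = %d)",
        agg$mean_half_life, agg$sd_half_life, agg$n_fits)
#> "half-life 1.005 +/- 0.068 s (n = 20)"
```

See `vignette("gem-labeling-quantification")` for the models, conventions
and design choices (connectivity, boundary rules, pooling, initialization).

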