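---
title: "Quantifying nanoparticle cluster uptake from transmission X-ray microscopy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nanoparticle cluster uptake from transmission X-ray microscopy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txmquant)
```

## The problem

Full-field transmission X-ray microscopy (TXM) at ~8 keV resolves, at a
lateral resolution of about 30 nm, the dense clusters that gold
nanoparticles (AuNPs) form after cells internalize them. From such images
one wants *per-cell* quantitative answers: how many clusters a cell has
taken up, how their sizes are distributed (the distribution's peak — the
mode — is the headline statistic), and where the clusters sit relative to
the nucleus. Two acquisition regimes matter: single 2D projection images,
and 3D tomographic reconstructions assembled from a projection series that
the sample holder typically restricts to about 140° of rotation.

Because raw micrographs for this kind of study are rarely deposited,
`txmquant` pairs the quantification machinery with a synthetic-scene
generator, so every step — thresholding, component labeling, moment-based
sizing, nucleus-relative localization, 2D-vs-3D comparison — can be tested
against exact ground truth. The same quantification functions accept
user-supplied grayscale TIFFs through `quantify_external()`.

## The phantom: what the generator emulates

`phantom_config()` + `build_phantom()` render one cell as a voxelized
ellipsoid (label 1) with an interior ellipsoidal nucleus (label 2), and
`n_clusters` randomly oriented, mildly anisotropic ellipsoidal clusters
(labels ≥ 3) with log-normal sizes. Choices a user should know about:

* **Nuclear exclusion is enforced, not emergent.** Every cluster voxel must
  lie in cytoplasm; this mirrors the observation that internalized AuNPs do
  not cross the nuclear membrane, and it is what makes
  "fraction of clusters inside the nucleus = 0" a meaningful end-to-end
  invariant of the pipeline.
* **Placement modes.** `uniform_cytoplasm` spreads clusters through the
  cytoplasm (EMT-like behavior); `perinuclear_shell` confines cluster
  centroids to a configurable signed-distance band outside the nuclear
  surface (HeLa-like behavior; the `"hela-like"` preset uses 500–1500 nm,
  i.e. a shell of 1 ± 0.5 µm).
* **Size model.** Sizes (defined as the mean of the three ellipsoid full
  axes) are log-normal: positive support and a single interior mode at
  `exp(meanlog − sdlog²)`. The presets put that mode at 140 nm (EMT-like)
  and 30 nm (HeLa-like) with `sdlog = 0.35`. Only empirical histograms are
  available for real cells; log-normal is the standard unimodal choice for
  aggregate sizes, and other families can be plugged in behind
  `sample_cluster_sizes()`.
* **Attenuation.** Scene values are linear attenuation coefficients at
  8 keV derived from standard mass-attenuation tables: ~0.4 µm⁻¹ for solid
  gold, ~0.001 µm⁻¹ for hydrated organic material, with the nucleus
  slightly denser (0.0015 µm⁻¹) as a mild stain would render it. Clusters
  are modeled as homogeneous gold-dense ellipsoids; the packing of ~15 nm
  primary particles inside a cluster is far below the 30 nm resolution and
  is not modeled.
* **Voxel pitch.** Default 15 nm — half the instrument resolution (Nyquist),
  so resolution-limited clusters span at least 2 voxels. Presets use 15–30
  nm depending on the cluster scale being studied.
* **Truth is measured on the rendered scene.** The catalog records the
  voxelized geometry (moment axes, centroid, signed nucleus distance of
  the rendered cluster), not the pre-voxelization request, so truth and
  measurement share the same discretization.
* **Disambiguation gap.** Clusters are rejected-and-resampled (up to
  `max_attempts`, then a capacity error) until they are voxel-disjoint with
  at least `min_gap_vox` (default 1) voxels between them, keeping the truth
  catalog unambiguous under resolution-limited imaging.
* **Determinism.** One integer seed drives every draw; the same config is
  byte-identical across runs.

Scene extents in the presets are a few micrometres — large enough to hold
the nucleus, the full perinuclear shell and ~100 clusters, while keeping a
complete tomographic simulation desk-sized. Real adherent cells are larger
laterally; since the quantification is per-cluster and per-cell, the
conclusions the tests support do not depend on the absolute cell size.

## Imaging model

`project()` implements an absorption-contrast parallel-beam forward model:
each transmission frame is `exp(−∫µ dl)` with the line integral taken at
one-voxel steps and bilinear in-plane interpolation (rotation axis = z).
Parallel-beam is appropriate for a zone-plate full-field TXM with a 24 µm
field of view. Phase contrast (used qualitatively for sub-100 nm clusters
in real instruments) is not modeled. Optional components:

* `add_photon_noise()` — Poisson counting statistics at a configurable
  expected background photon count per pixel;
* a Gaussian optics blur (`psf_fwhm`, default 30 nm in `pipeline_config()`
  to match the stated instrument resolution; oracle tests run without it);
* `normalize_background()` and `patchwork()` mirror the standard flat-field
  normalization and field-of-view mosaicking steps;
* `sinogramify()` converts frames to line-integral sinograms, clamping
  non-positive pixels at a configurable floor (only reachable with photon
  noise) and counting them in QC.

## Reconstruction

`reconstruct_fbp()` is slice-by-slice filtered back-projection with a ramp
filter (frequency-domain, zero-padded to a power of two), optional Hann
apodization for noisy data, and linear detector interpolation, over exactly
the acquired angles: a 140° series keeps its missing wedge, no in-painting.
Negative reconstructed values are retained — clamping would bias the
subsequent threshold selection. The angular weight is the mean angular step,
which makes a 1°-sampled 180° series quantitative (a homogeneous sphere
reconstructs to its true µ within a few percent) and degrades gracefully at
140°. `coverage_report()` flags limited-angle series using the effective
coverage span + step, so 0…179° at 1° counts as full half-circle coverage.

## Quantification

* **Threshold.** The interactive grey-value selection of practice is
  replaced by Otsu's rule (between-class variance maximization over a
  256-bin histogram of the observed range), computed inside the cell mask
  when one is available so empty background does not dominate; a manual
  override is a config key. Ties break toward the smaller threshold.
* **Labeling.** 8-connectivity in 2D, 26-connectivity in 3D (fixed,
  recorded in QC). Components below `min_size` (default 2 px/voxels — the
  instrument cannot resolve smaller) are discarded but counted.
* **Sizing.** Moment-equivalent ellipses/ellipsoids: axes from eigenvalues
  of the second central moment tensor of the pixel/voxel set, solid-body
  conventions `4√λ` (2D) and `2√5·√λ` (3D — a homogeneous ellipsoid has
  variance `a²/5` along semi-axis `a`). Each pixel/voxel contributes the
  1/12 variance of a unit cell, so degenerate lines and planes keep
  positive axes; single-pixel and coplanar components are flagged. The
  scalar size is the arithmetic mean of the axes; 2D and 3D records carry
  an explicit dimensionality tag and are never mixed silently.
* **Inside-cell rule.** "Clearly inside" is operationalized as: centroid in
  the cell mask *and* ≥ 90% of the component's pixels/voxels in the mask
  (fraction configurable); rejections are counted in QC.
* **Nucleus guard.** With few or no particles, the threshold can segment
  the (denser) nucleus itself; `drop_nucleus_regions()` discards 3D
  components mostly (≥ 50%) inside the nucleus mask and 2D components
  covering most of the projected nucleus. Genuine clusters can do neither.
* **Localization.** Signed centroid-to-nuclear-surface distances come from
  an exact Euclidean distance transform with nearest-site tracking; zero
  sits on the voxel faces between nucleus and cytoplasm and values are
  accurate to well under one voxel pitch.

## Statistics

Per-cell size histograms (`make_distribution()`, default 20 nm bins over
0–800 nm, overflow counted, never dropped), KDE-based mode estimation
(`estimate_mode()`, Silverman bandwidth, dense-grid argmax, ties toward the
smaller size, histogram fallback below n = 5), and two-sample
Kolmogorov–Smirnov comparison (`compare_distributions()`), chosen because
whole size distributions — not means — are what differ between conditions
and between 2D and 3D quantification of the same specimen. `ks.test()`'s
exact small-sample path is used automatically and flagged.
`uptake_report()` emits per-cell rows plus a pooled row, since published
per-cell histograms can be read either way.

## The 2D-vs-3D comparison

`run_pipeline()` always quantifies both arms of the same simulated cell:
3D on the reconstructed volume (clusters bright) and 2D on one projection
frame (clusters dark, masks projected along the beam). Clusters that
overlap along the beam merge in projection, so the 2D count is at most the
3D count and the 2D size distribution is shifted and reshaped — the
package's tests assert both the count ordering (every seed) and the KS
significance of the size-distribution difference on crowded scenes. The 2D
bias is measured, not corrected: no overlap deconvolution is attempted.

## Numerical choices and degenerate inputs

Sinogram floor 10⁻⁶ (clamp count in QC); FFT padding to the next power of
two above twice the detector width; reconstruction volumes keep negative
values; constant images raise a degenerate-histogram error rather than an
arbitrary threshold; empty size vectors produce an empty distribution, not
an error; an empty cell mask rejects everything with a warning; an empty
nucleus mask leaves distances `NA`-flagged rather than zero. All exported
lengths are nanometres (micrometres only where a report says so); voxel
units never leak into files.

## Problem sizes used by the tests

The oracle suites run on ≤ 32³ volumes and 16² masks; tomographic fidelity
checks use 128² slices; the end-to-end recovery condition uses a
(160, 256, 256) grid with 200 clusters, noiseless 180° acquisition; the
2D-vs-3D bias study runs 20 seeds of a (64, 96, 96), 60-cluster scene
through the full 140° pipeline. These sizes were chosen so the whole suite
demonstrates every claim on a single CPU in a few minutes.

## Limitations

* Absorption contrast only: no Zernike phase contrast, no zone-plate
  diffraction, no detector MTF beyond the Gaussian blur.
* Perfectly aligned, parallel-beam geometry: no registration, rotation-axis
  calibration or ring-artifact handling (synthetic data does not need
  them); FBP only, no iterative missing-wedge compensation.
* One cell per phantom; no vesicle biophysics or uptake kinetics — the
  generator reproduces the *statistical structure* the quantification
  assumes (sparse, nucleus-excluded, unimodal-size clusters), not the
  biology that produces it. Passing tests validate the measurement chain,
  not any biological claim.
* Touching clusters are treated as one (as merged aggregates are in
  practice); no watershed splitting.
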