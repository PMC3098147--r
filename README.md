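# txmquant

Quantifying metal-nanoparticle cluster uptake in single cells from
transmission X-ray microscopy (TXM), with a fully synthetic test bed.

Cells exposed to gold nanoparticles (~15 nm primaries) internalize them as
dense clusters large enough to image with a full-field TXM at ~30 nm
resolution and 8 keV. The scientific questions are per-cell and
quantitative: how many clusters did this cell take up, how are their sizes
distributed (the distribution **mode** is the headline statistic — large
clusters for EMT-like cells, ~30 nm clusters for HeLa-like cells), and
where do they sit relative to the nucleus (internalized AuNPs do not cross
the nuclear membrane; in HeLa-like cells they concentrate in a thin
perinuclear shell)? Answering them from images requires a chain of steps —
grey-value segmentation, connected-component counting, ellipse/ellipsoid
sizing, an inside-cell sampling rule, nucleus-relative localization — and
the answers differ systematically between a single 2D projection and a 3D
tomographic reconstruction, because clusters that overlap along the beam
merge in projection.

`txmquant` implements that chain end to end, for users who want to

* validate a TXM quantification protocol against exact ground truth
  (synthetic cell phantoms with known cluster catalogs),
* measure the 2D-vs-3D quantification bias under controlled conditions, or
* apply the same reproducible quantification to their own grayscale TIFFs
  (`quantify_external()`).

## The method in brief

* **Phantom**: one ellipsoidal cell, ellipsoidal nucleus, `n` randomly
  oriented ellipsoidal clusters with log-normal sizes, placed uniformly in
  the cytoplasm or in a perinuclear shell, never in the nucleus. Linear
  attenuation at 8 keV: gold ≈ 0.4 µm⁻¹, tissue ≈ 0.001 µm⁻¹.
* **Imaging**: parallel-beam Beer–Lambert projection
  `T = exp(−∫µ dl)`, optional Poisson photon noise and Gaussian optics
  blur; flat-field normalization and mosaicking utilities.
* **Reconstruction**: per-slice filtered back-projection (ramp filter,
  optional Hann window) over exactly the acquired angles — a 140° series
  keeps its missing wedge.
* **Quantification**: Otsu threshold (256 bins, manual override available),
  8/26-connected labeling, moment-equivalent axes
  (`axis = 4√λ` in 2D, `2√5·√λ` in 3D), size = mean of axes,
  centroid-in + ≥90 %-contained inside-cell rule, signed
  nucleus-surface distances from an exact distance transform.
* **Statistics**: per-cell histograms and KDE modes, two-sample
  Kolmogorov–Smirnov comparison of size distributions, per-cell +
  pooled uptake reports.

## Worked example

Simulate an EMT-like cell (60 clusters, size mode 140 nm, uniform
cytoplasmic placement), image it over 140° at 1° steps, reconstruct, and
quantify both arms:

```r
library(txmquant)

cfg <- preset_config("emt-like", n_clusters = 60L, seed = 42)
run <- run_pipeline(cfg)          # add out_dir = "emt_run" to write artifacts
run
#> <txm_run>
#>   true clusters: 60 | detected 3D: 60 | detected 2D: 33
#>   size mode: 3D 155 nm, 2D 130 nm
#>   2D vs 3D sizes: KS D = 0.233, p = 0.164

run$report
#>   cell_id n_clusters size_mean_nm size_sd_nm size_mode_nm ndist_mean_nm
#> 1   cell1         60        177.5      67.72        154.6         940.8
#> 2  pooled         60        177.5      67.72        154.6         940.8
#>   ndist_sd_nm frac_in_nucleus
#> 1       403.1               0
#> 2       403.1               0
```

Reading the numbers: all 60 generated clusters are recovered in 3D with a
size mode of 155 nm (generator mode: 140 nm), but the single 2D projection
of the *same cell* sees only 33 apparent clusters — axial overlap merges
the rest — which is exactly the bias that makes 3D analysis necessary.
`frac_in_nucleus = 0` is the nuclear-exclusion invariant surviving the
whole imaging-and-measurement chain. With an `out_dir`, every artifact is
written: phantom stacks + truth catalog, projections, reconstruction
(32-bit multi-page TIFFs with YAML sidecars), `clusters.csv`,
`report.csv`, `qc.yaml` (threshold used, connectivity, discarded/rejected
counts, angular coverage) and a full `manifest.yaml`.

External images work the same way:

```r
res <- quantify_external("my_stack.tif", pixel_pitch = 30,
                         cell_mask = "my_cell_mask.tif")
res$distribution   # size histogram + KDE mode
```

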