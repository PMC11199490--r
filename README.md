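# perilacunar

Spatial analysis of perilacunar/canalicular remodeling (PLR) in
synchrotron-radiation micro-CT (SRµCT) volumes of cortical bone.

Osteocytes resorb and deposit the bone matrix around their lacunae. During
lactation this remodeling mobilizes mineral: lacunae enlarge, lacunae near
vascular interfaces enlarge the most, and the matrix some distance from
the lacunar edge loses mineral. `perilacunar` turns micron-resolution 3-D
attenuation volumes into those measurements, end to end:

* **Phase retrieval** — single-distance Paganin retrieval
  `T = -(1/µ) ln(F⁻¹[F(I/I₀) / (1 + zδ|k|²/µ)])` with `µ = 4πβ/λ`, plus a
  Fresnel forward simulator (projection approximation) used to validate
  the retrieval by round trip.
* **Segmentation** — bone mask (auto threshold + morphological closing),
  the five-filter osteocyte-lacuna cascade (voids → 26-connected
  components → volume 65–700 µm³ → overlap with a median-filtered
  reference → z-edge removal → aspect ratio ≥ 0.05), vascular canals (two
  k = 3 median passes, ≥ 750 µm³), and endosteal/periosteal surface
  identification.
* **Spatial statistics** — exact Euclidean distance transforms; per-lacuna
  minimum distances to endosteum, canals, periosteum and their union (the
  vasculature); nearest-surface assignment; pooled volume quartiles Q1–Q4.
* **Mineralization profiles** — mean tissue mineral density (TMD) in
  half-open distance bins of one voxel spacing (1.3 µm) from the lacunar
  edge, per lacuna, per bone and per volume quartile.
* **Morphometry** — BV, BV/TV, cortical thickness (largest-inscribed-
  sphere local thickness), lacunar density Lc.Dn, mean lacunar volume
  Lc.V.
* **Statistics** — linear mixed models with a random intercept per bone
  for lacuna-level outcomes (lacunae are nested in bones), two-way ANOVA
  with Tukey contrasts and t-tests for bone-level outcomes, and the
  two-stage Hochberg (family gate) + Benjamini–Hochberg (bin localization)
  correction for distance-resolved profile comparisons.
* **Phantom generator** — synthetic cortical-bone volumes (annular cortex,
  medullary cavity, canals, ellipsoidal lacunae with truncated-lognormal
  volumes, perilacunar hyper/hypomineralized zones, partial-volume edges,
  noise) with complete ground truth, so the whole chain is testable
  without beamline data.

The methods vignette (`vignettes/perilacunar-methods.Rmd`) documents the
models, conventions and design choices in detail.

## Worked example

Generate a small two-cohort study (virgin vs lactating controls, a 25 %
lacunar-volume lactation effect injected) and run the full pipeline:

```r
library(perilacunar)

manifest <- data.frame(
  sample_id = c("v1", "v2", "l1", "l2"),
  cohort    = rep(c("virgin_control", "lactating_control"), each = 2),
  preset    = rep(c("virgin_control", "lactating_control"), each = 2))

base <- phantom_config(shape_voxels = c(48L, 128L, 128L),
                       cortex = list(outer_radius_um = 70,
                                     inner_radius_um = 30),
                       canals = list(count = 2L, radius_um = 4,
                                     orientation_jitter_deg = 3),
                       lacunae = list(target_count = 60L,
                                      volume_median_um3 = 160,
                                      sigma_log = 0.45,
                                      truncation = c(65, 700),
                                      axis_ratio_range = list(
                                        mid = c(0.4, 0.7),
                                        short = c(0.3, 0.5)),
                                      volume_scale = 1,
                                      endosteal_volume_scale = 1))

cfg <- pipeline_config(manifest, input_mode = "phantom",
                       preset_args = list(lacuna_volume_scale = 1.25),
                       base_config = base, seed = 42L)
res <- run_pipeline(cfg)

aggregate(volume_um3 ~ cohort, res$lacunae, mean)
#>              cohort volume_um3
#> 1 lactating_control   229.3757
#> 2    virgin_control   181.3642

res$stats$lacunar_volume[, c("comparison", "estimate", "se", "p_raw")]
#>                           comparison  estimate       se        p_raw
#> 1 virgin_control - lactating_control -48.01146 13.24608 0.0002894332
```

The lactating cohort's mean lacunar volume comes out ~26 % above the
virgin cohort's (the injected 25 % effect, measured through the full
segmentation chain at this small sample size), and the mixed model
(random intercept per bone) calls the difference significant. `res$out_dir` holds the per-lacuna table with
distances and quartiles, per-sample mineralization profiles, morphometry,
the per-filter QC ledger and a machine-readable run manifest; re-running
the same configuration reproduces every CSV byte for byte.

(The exact numbers above are what `run_pipeline()` printed for this
configuration and seed on the authors' machine; any machine reproduces
them exactly for the same seed.)

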