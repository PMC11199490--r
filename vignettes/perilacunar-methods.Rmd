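---
title: "Quantifying perilacunar remodeling from SRµCT volumes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying perilacunar remodeling from SRµCT volumes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perilacunar)
```

## The scientific problem

Osteocytes remodel the bone matrix around their lacunae and canaliculi
(perilacunar/canalicular remodeling, PLR). During lactation this remodeling
liberates mineral, enlarging lacunae and altering the mineral density of
the surrounding matrix. Synchrotron-radiation micro-CT (SRµCT) at ~1.3 µm
voxels resolves thousands of lacunae per cortical-bone sample together
with a calibrated attenuation (tissue mineral density, TMD) signal, which
makes three spatial questions tractable:

1. Do lacunae near particular vascular interfaces (intracortical canals,
   endosteum, periosteum) respond more strongly to lactation?
2. How close are lacunae to the vasculature, overall and by lacunar size?
3. How does TMD vary with distance from the lacunar edge, and where does
   lactation change it?

`perilacunar` implements the full measurement chain for these questions —
phase retrieval, segmentation, distance-transform spatial statistics,
distance-binned mineralization profiles, cortical morphometry, and nested
mixed-model inference — plus a synthetic cortical-bone phantom generator
with complete ground truth, so that every stage is testable without access
to beamline scans.

## The phantom generator: what it emulates

`generate_phantom()` renders an annular cortical cross-section (axis z)
with:

* a centred cylindrical medullary cavity (this is what lets segmentation
  distinguish the endosteal from the periosteal surface: the exterior
  background touches the volume's lateral border, the cavity does not);
* near-axial cylindrical canals with a configurable tilt jitter;
* ellipsoidal lacunae with random orientation, semi-axis ratios drawn from
  typical lacunar anisotropy (middle/longest in 0.4–0.7, shortest/longest
  in 0.3–0.5), and volumes from a lognormal law (median 160 µm³,
  σ~log~ = 0.45) truncated to the analysis's admissible range
  [65, 700] µm³. Lacunar volumes are right-skewed in cortical bone; the
  exact parameters are free configuration, not calibrated claims, since no
  reference volume table is available;
* a perilacunar mineral model: attenuation of a bone voxel equals
  `baseline * (1 + modifier(d))` where `d` is the distance to the nearest
  lacunar edge. The default modifier is a +10 % hypermineralized shell
  over 2.6–10.4 µm, and, in lactating presets, an additional −5 %
  hypomineralized annulus over 14–20 µm applied only around lacunae in the
  sample's top volume quartile — mirroring the Q4-restricted lactation
  finding the analysis is meant to recover;
* sub-voxel (3×3×3) sampling of the lacunar boundary (and a linear
  sub-voxel ramp across canal walls), so edge voxels carry partial-volume
  attenuation as in real scans;
* additive white Gaussian noise with standard deviation expressed as a
  fraction of the bone–background contrast (default 5 %).

Cohort presets (`cohort_preset()`) encode the four study groups
(virgin/lactating × control/osteocyte-targeted MMP13 knockout). When a
preset localizes its volume effect to endosteum-proximal lacunae, the
generator decides each lacuna's truth-side nearest surface with exactly
the convention the analysis uses — the minimum over the lacuna's voxels of
exact distance maps to the endosteal, canal and periosteal surfaces — so
the injected set and the measured set coincide up to segmentation noise.
The lactation effect sizes are deliberately **required arguments** rather
than defaults: they are study-level inputs (e.g. a 25 % lacunar volume increase
for the lactating control group, or a 49 % increase restricted to
endosteum-proximal lacunae) that the caller supplies. Lactating presets
additionally thin the cortex from the endosteal side (default 24 %
thickness reduction, within the reported 22–26 % control range) and scale
the lacuna count with the remaining annulus cross-section so lacunar
density stays constant, matching the observation that lactation reduces
bone mass but not Lc.Dn. The cohort volume effect is applied as a
multiplicative factor on the linear semi-axes (volume scales as the cube),
preserving shape statistics.

What the phantom does **not** emulate: anatomically realistic whole-bone
geometry, canalicular networks (below resolution), osteonal
microstructure, beam-hardening or ring artifacts, and spatially correlated
noise. Phase-contrast fringing is produced only by the phase module's
forward model, never baked into the phantom. Passing tests on phantoms
therefore demonstrates correctness of the measurement chain under the
stated geometric and noise model, not robustness to every artifact of real
beamline data.

## Phase retrieval

`paganin_filter()` implements single-distance, single-material phase
retrieval:

$$T = -\frac{1}{\mu}\,\ln\!\left(\mathcal{F}^{-1}\!\left[
\frac{\mathcal{F}[I/I_0]}{1 + (z\delta/\mu)\,|k|^2}\right]\right),
\qquad \mu = \frac{4\pi\beta}{\lambda},$$

with $|k|^2$ on the angular-frequency DFT grid of the detector pixel
pitch. The hydroxyapatite defaults at 18 keV are
δ = 2.01842317×10⁻⁶ and β = 1.48130805×10⁻⁸ (λ ≈ 6.888×10⁻¹¹ m,
µ ≈ 2.70×10³ m⁻¹). The propagation distance has **no default from the
study protocol** — it is a required acquisition parameter. Numerical
choices: images are padded to even dimensions by edge replication before
the FFT (avoids wrap-around bleed at bone borders), intensities are
clipped at a documented floor of 1e−8 before the log, and negative
retrieved thickness is preserved and counted in the QC summary rather than
clipped.

`fresnel_forward()` is the validation path: the projection approximation
(complex transmission $t = e^{-2\pi(\beta + i\delta)T/\lambda}$) followed
by paraxial Fresnel propagation. The retrieval is accepted when it inverts
this independent forward model for smooth objects to within 5 %. The
pipeline applies retrieval slice-wise on radiograph-like inputs;
tomographic reconstruction from projections is out of scope, and
volume-level analyses accept pre-retrieved volumes.

## Segmentation cascade

`segment_bone()` thresholds (automatic between-class-variance
maximization, or an explicit value — exact protocol thresholds are not
recoverable, so the override is first-class), closes with a Euclidean ball
(radius 1 voxel by default) and keeps the largest component.

`segment_lacunae()` applies the five-filter cascade on the thresholded
voids, 26-connected:

1. volume in [65, 700] µm³ (voxel count × spacing³);
2. at least one voxel overlapping a reference segmentation built by
   median-filtering the image (k = 3) and re-thresholding ("touch" is
   interpreted as shared voxels, the strictest reproducible reading);
3. no contact with the first or last z-slice (incomplete lacunae);
4. aspect ratio ≥ 0.05, where the aspect ratio is the shortest/longest
   principal extent from the eigenvalues of the component's
   voxel-coordinate covariance (extent = 4·√eigenvalue, with a
   spacing²/12 cube self-term so one-voxel-thin components are measured
   sensibly rather than degenerating to zero).

The filters are pure predicates on the fixed component set, so the
retained set is independent of their order; the QC ledger attributes each
removal to the first failing filter in the order above, and
candidates = retained + removed-by-each-filter holds on every run. Manual
cleanup of interactive workflows is replaced by a reproducible exclusion
list of component ids.

`segment_canals()` median-filters twice (k = 3), thresholds, removes void
components connected to the exterior or medullary background, and keeps
components ≥ 750 µm³. `identify_surfaces()` classifies the background of
the bone mask: the component touching the lateral border is exterior, the
largest enclosed component is the medullary cavity (smaller enclosed
components are intracortical pores), and the periosteum/endosteum are the
bone voxels 26-adjacent to each.

## Spatial statistics

Distances are exact Euclidean distance transforms (separable
lower-envelope algorithm, voxel-centre to voxel-centre, isotropic
spacing), computed in compiled code and verified voxel-for-voxel against a
brute-force oracle in the test suite. The "vasculature" is the union of
canals, endosteum and periosteum. Per lacuna, each surface distance is the
minimum over the lacuna's voxels (a centroid mode exists for sensitivity
analysis); the lacuna is assigned to the argmin surface with tie priority
endosteum > canals > periosteum. Pooled volume quartiles use the
25/50/75th percentiles of all lacunae across samples and cohorts with
half-open bins (ties always share a bin). Quartile-level distance
summaries keep the bone as the experimental unit: per-bone cell means are
emitted and cohort cells average the bone means.

## Mineralization profiles

`lacunar_edge_distance()` gives the distance from the lacunar voxel set
and the nearest-lacuna feature transform (exact ties resolved toward the
lower id). Profiles bin bone-tissue voxels by multiples of the voxel
spacing (half-open bins, default reach 26 µm = 20 bins, chosen to cover
the 12.5–20 µm band of interest with margin; the protocol states no
cutoff). Each voxel is attributed once, to its nearest lacuna, avoiding
double counting between neighbours; an `all_within_range` mode is provided
for sensitivity since the attribution rule is ambiguous in interactive
tools. Canal and non-bone voxels are excluded; empty cells stay missing
rather than zero. The innermost bins (≈0–2.6 µm) sit on partial-volume
boundary voxels and read low even for flat true mineral — the phantom
reproduces this and the QC output flags those bins. The
attenuation-to-TMD calibration is linear (`tmd_calibrate()`); the identity
is the correct choice for synthetic data, and real-scan use requires a
user-supplied phantom calibration.

## Morphometry

BV is the bone voxel count × spacing³. **TV is the volume enclosed by the
periosteal surface, medullary cavity and pores included.** This convention
is stated prominently because BV/TV depends entirely on it: with the
cavity inside TV, endosteal resorption lowers BV/TV — the lactation effect
the analysis must show — whereas an annulus-only TV pins BV/TV near 1
regardless of resorption and cannot reproduce the reported 18–23 %
reductions. Ct.Th is the mean local thickness by largest-inscribed-sphere
(distance-ridge) sphere fitting, computed on the pore-filled envelope
(thickness is a property of the cortical shell, not of its porosity).
Lc.Dn is the retained lacuna count over BV.

## Statistics

Per-lacuna outcomes are nested within bones, so group comparisons use a
Gaussian linear mixed model with a random intercept per bone, REML fit,
and Wald tests — the simplest structure consistent with repeated measures
per bone; no random slopes are included, and small-sample df corrections
(Satterthwaite/Kenward–Roger) are a documented limitation. A singular fit
(zero between-bone variance) falls back to pooled OLS with a warning
rather than failing.

Profile comparisons run per distance bin with a two-stage correction:
a Hochberg step-up gate across bins controls the family-wise "is anything
different" question, then Benjamini–Hochberg at α = 0.05 localizes the
significant bins; both adjusted sets are returned so the gate can be
audited. The per-bin response defaults to **per-bone bin means**: bones
are the experimental unit (N = 4–5 per group in the study design this
emulates), which avoids pseudo-replication from thousands of correlated
lacunae when the between-bone variance component is degenerate; the
per-lacuna mixed-model mode is available as configuration. Per-bone
outcomes (BV/TV, Ct.Th, mean Lc.V...) use a genotype × lactation two-way
ANOVA with Tukey HSD contrasts, or an unpaired two-tailed t-test for
two-group calls; α = 0.05 throughout.

## Reproducibility and numerical choices

* Every stochastic stage takes an explicit seed; a pipeline run expands
  its global seed into per-sample substreams (`seed × 1000 + row index`),
  so adding a sample never perturbs the others. Two runs with the same
  configuration produce byte-identical CSV outputs.
* Geometry metadata (voxel spacing, value kind) lives in a JSON sidecar
  next to every TIFF volume and is never inferred from file names;
  a missing spacing is an error, never a silent 1.0.
* Distance ties: nearest-surface assignment prefers
  endosteum > canals > periosteum; nearest-lacuna ties resolve to the
  lower id; quartile ties share a bin.
* Degenerate inputs fail loudly with the offending stage and sample named:
  empty masks, absent cavities (warning + empty endosteum), all-background
  volumes, crowded phantom geometry.

## Problem sizes used in the validation suite

The acceptance analyses generate 5 phantoms per cohort at 192 × 192 × 128
voxels and 1.3 µm spacing with ≈300 lacunae per virgin-control bone —
enough for stable per-bone means and pooled quartiles while keeping a full
two-cohort run in the minutes range on a single core. Sub-group analyses
(e.g. the endosteum-assigned subset, which holds only ~30 % of lacunae)
use denser phantoms of 450 lacunae per bone — a lacunar density at the
upper end of the murine cortical range — so the subset per-bone means stay
stable. Unit and property
tests use 48–96-voxel grids, where brute-force oracles (all-pairs distance
transforms, step-up recursions, hand-computed ANOVA sums of squares) are
exact and fast. Statistical calibration uses 200 replicates for CI
coverage (5 bones/group, 200 lacunae/bone, bone-level SD small relative to
lacunar SD, as in the data this emulates), 100 null replicates for the
false-discovery share, and 1000 for the Tukey family error.

## Known limitations

* Canaliculi are below the working resolution; all mineral statistics are
  lacuna-referenced.
* The Paganin filter assumes a single homogeneous material; multi-material
  or multi-distance retrieval is out of scope, as is tomographic
  reconstruction.
* Wald inference without small-sample df corrections is mildly liberal for
  very few bones; the calibration suite bounds this at the study's design
  size.
* The phantom's noise is white and Gaussian; threshold robustness under
  structured noise must be established on real data.
* Automatic thresholds are between-class-variance optima on the synthetic
  bimodal histogram; real scans may need the explicit-threshold override.
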