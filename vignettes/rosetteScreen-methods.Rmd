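---
title: "Methods: organoid lumen phenotyping with rosetteScreen"
author: "rosetteScreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: organoid lumen phenotyping with rosetteScreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The biological measurement

A self-organizing single-rosette cortical organoid (SOSR-CO) is an
iPSC-derived neuroepithelial sphere with one central apical lumen bounded
by tight junctions (ZO1) and apical f-actin — an in vitro proxy for the
closing neural tube. Failure of apical constriction, whether induced
pharmacologically (valproic acid and other HDAC/GSK3β inhibitors) or
genetically (*SHROOM3* knockout, including mosaic knockout mixtures),
enlarges the lumen, enlarges individual apical cell surfaces, and in the
knockout case deforms the lumen and shifts f-actin basally. The package
quantifies these phenotypes from two-channel fluorescence images: a
whole-cell/nuclear counterstain delineating each organoid body and a lumen
marker (ZO1-EGFP, ZO1 immunostain, or phalloidin-labelled f-actin) drawing
a bright ring along the apical lumen boundary.

# Segmentation

**Bodies.** The counterstain is Gaussian-smoothed (σ = 2 px at 1.3 µm/px),
thresholded (Otsu by default; a manual min/max intensity window is
available to reproduce contrast-threshold protocols), hole-filled, cleaned
of objects under `minAreaUm2`, and labelled with 8-connectivity (a
union-find merge over EBImage's 4-connected components; 8-connectivity
avoids splitting thin diagonal boundary runs). Border-touching labels are
recorded — their projected areas are censored — and excluded from
statistics by default.

**Lumens.** Within each body the marker is thresholded (Otsu on the
in-footprint intensities), the boundary ring is morphologically closed
(radius 3 px, bridging noise gaps) and filled, and the lumen is the filled
component eroded back to the ring centreline: with `r_out` and `r_in` the
equivalent radii of the filled component and its interior, the component's
Euclidean distance transform is thresholded at `(r_out − r_in)/2`. Two
choices deserve comment:

* *Margin exclusion.* Ring detection is restricted to the body footprint
  eroded by 12 % of its equivalent radius. The lumen is an interior
  structure; without this, the basal f-actin rim of knockout organoids is
  thresholded together with the ring, and hole-filling floods the entire
  body. The 12 % margin comfortably exceeds the rendered basal rim (outer
  10 % of the radius) while staying clear of the largest lumens the
  generator produces (off-centre reach ≤ 85 % of the radius).
* *Sub-resolution lumens.* If centreline erosion would erase a small lumen
  entirely, the component core is kept: the single minimum-area gate
  (`minLumenAreaUm2`, default 50 µm²) is applied once, to the filled
  candidate.

Each lumen is assigned to the organoid containing its centroid; orphans
(centroid on background) are flagged and not counted.

On noise-free synthetic fields, recovered body areas match polygon ground
truth within 2 % and lumen areas within 5 % for radii ≥ 30 px — the
acceptance suite asserts exactly this.

# Features

Per organoid, feature families are measured on both masks (body, largest
lumen) and both channels, ~435 numeric columns:

* **Shape** (per mask): area, Kulpa corner-corrected chain-code perimeter
  (keeps digitized-disk circularity ≤ ~1), circularity 4πA/P², roundness
  4A/(πL²), aspect ratio and eccentricity of the moment-equivalent
  ellipse, solidity against a boundary-corrected convex hull, extent,
  equivalent diameter, orientation, centroid. Lengths are calibrated to µm
  at measurement time; nothing is stored in pixels.
* **Intensity** (per mask × channel): 20 summaries (mean, sd, MAD, min,
  max, 9 quantiles, IQR, CV, skewness, kurtosis, integrated intensity,
  upper-decile mean).
* **Radial distribution** (per mask × channel): six rings of equal
  normalized thickness. Each pixel's radial coordinate is
  d = ‖p − c‖ / R(θ), the centroid distance divided by the
  centroid-to-edge distance along the same ray (piecewise-linear
  interpolation of the contour radius over angle, exact duplicate angles
  collapsed to the maximum radius). Edge-scaled rings make profiles
  comparable across organoid sizes, which cross-size heatmaps require.
  `frac_at_d` sums to 1 exactly; `mean_frac` is 1 in every ring for a
  uniformly lit object. If the centroid falls outside the object the
  coordinate falls back to a distance-transform normalization and the
  record is flagged. A brute-force per-pixel oracle reproduces the
  pipeline values to 1e-9 in the test suite.
* **Zernike** moment magnitudes to degree 9 (30 per mask × channel),
  computed on the unit disk scaled to the object's maximum radius with
  unit-sum intensity weights; rotation-invariant by construction.
* **Texture**: Haralick features at co-occurrence scales 1, 2 and 4 px
  (13 × 3 per mask × channel) via EBImage.
* **Engineered**: `lumen_count`, the study's phenotype metric
  `area_ratio_sqrt` = √(lumen area / organoid area), and the
  lumen-centroid offset. Undefined features (no lumen; single-pixel
  regions) are `NA` sentinels with boolean flag columns, never silent
  zeros, so the modeling stage must resolve them explicitly.

Group-level radial heatmaps divide each condition's 6-ring mean-fraction
vector by its own maximum (`maxNormalizeProfiles`), compensating for the
signal dilution of enlarged lumens; statistics always use the per-organoid
`mean_frac` values, with max-normalization applied only for display.

# Quality control

Retained records have exactly one lumen and projected body area in the
inclusive window **7854–31,415 µm²** — the circle-area conversion of the
100–200 µm diameter gate (π·50² rounds to 7854; π·100² truncates to
31,415). Outside it, objects are predominantly monolayer fragments (small)
or fusions of two fragments (large, typically multi-lumen). Both bounds
are treated as inclusive. Exclusions are counted once per record in the
precedence order border, unmapped, no-lumen, multi-lumen, too-small,
too-large.

# Apical surface measurement

High-magnification (100×, 0.11 µm/px default) ZO1 mosaics outline each
cell's apical footprint. Hand tracing is not reproducible software, so the
package substitutes an automatic surrogate with the same selection rules:
background-subtracted ridge enhancement (junctions bright; a constant
image is flagged; a uniform offset leaves segmentation unchanged), cell
interiors seeded from sub-median basins of the ridge map (≥ 9 px),
space-filling growth over the junction pixels by intensity-weighted
propagation, edge-cell flagging, then selection of the k = 30 non-edge
cells nearest the lumen centre (ties broken by label). On simulated
mosaics across mean areas 2.5–7.7 µm², estimated means land within 10 % of
generative truth, and the knockout/wild-type fold change reproduces the
>3× enlargement the defaults encode.

# The synthetic generator

The generator defines the study conditions the tests exercise:

* **Fields**: 768×768 px at 1.3 µm/px (a typical 10× high-content pixel
  pitch — explicit configuration, since absolute calibration of real data
  belongs to the user's config), 20–40 organoids per well, body radius
  ~ N(75, 15) µm truncated to [45, 105] (the 100–200 µm diameter
  population).
* **Lumen size**: the latent lumen radius fraction ρ follows a Hill curve
  in dose — ρ(c) = ρ₀ + (ρ_max − ρ₀)·cʰ/(cʰ + EC₅₀ʰ) with ρ₀ = 0.15,
  ρ_max = 0.60, EC₅₀ = 300 µM, h = 1.5. The assay shows a smooth monotone
  graded response without a printed functional form or dose table, so Hill
  is the minimal smooth monotone choice and every constant is
  configuration, not a claim. For mosaic knockout, ρ(f) is
  piecewise-linear in the knockout fraction with saturation at
  f_sat = 0.75, encoding the observed indistinguishability of the 75 % and
  100 % conditions — those two are generated identically by construction.
  Per-organoid biological scatter is N(0, 0.035) on ρ (a 10–20 % CV,
  typical of organoid assays).
* **Realism features**: lumen centres sit off the body centre by up to
  15 % of the radius (rosette lumens are visibly eccentric), and marker
  staining intensity varies per organoid (lognormal, sd 0.15 — antibody
  and conjugate-lot variability). Both matter statistically: with
  perfectly concentric, uniformly stained lumens, every intensity and
  single-ring statistic is exactly as informative as the area ratio and
  variable importance splits arbitrarily among them; eccentricity smears
  per-ring statistics and stain variability corrupts raw intensity
  summaries, while ratio-based metrics are invariant — which is why the
  area ratio dominates importance, as it does on real data.
* **Knockout dysmorphology**: lobed lumen boundaries (single radial
  Fourier harmonic, 5 lobes, amplitude 0.22·min(f/f_sat, 1)) and a basal
  marker rim over the outer 10 % of the radius with gain
  0.25·min(f/f_sat, 1).
* **Fusions**: with probability 0.05 an organoid is rendered as two
  overlapping bodies with two lumens — one ground-truth object that QC
  should (and does) exclude as multi-lumen or oversized.
* **Image formation**: Gaussian PSF (σ = 1.2 px), then Poisson noise
  (scale 200 photons/unit) and Gaussian read noise (sd 0.01), giving
  SNR ≈ 10 at the ring.
* **Apical mosaics**: jittered-grid seeds with density 1/mean-area
  tessellated into a discrete Voronoi mosaic (exact nearest-seed
  labelling), junctions drawn on label boundaries; wild-type and knockout
  means default to 2.5 and 7.7 µm². For dose-coupled mosaics the
  condition-mean apical area is linear in the true lumen area, pinned to
  those two endpoints — mirroring the empirically linear lumen-vs-apical
  relation.

What the generator does **not** emulate: 3D structure (the analysis runs
on maximum projections), uneven illumination, photobleaching, stage
drift, debris and non-organoid objects, partially imaged organoids at
field borders (placement keeps bodies interior, so border-flag handling
is tested on constructed fixtures), and any transcriptomic layer. Passing
tests therefore demonstrate correctness of the measurement and modeling
machinery under controlled imaging physics — not performance on real
plates, whose thresholds and calibration remain user configuration.

# Modeling

Features are centred to mean 0 and scaled to unit sample standard
deviation (zero-variance columns dropped and logged; the fitted transform
is reusable on new data). Random forests (ranger, 500 trees, bootstrap
resampling) are scored by 5-fold cross-validation using out-of-fold
predictions only; folds are drawn at the organoid level from the mandatory
seed. Variable importance is permutation importance from a full-data
forest (assessed out-of-bag), truncated at zero and normalized to sum to
100 %; permutation was chosen over impurity because the radial rings are
strongly correlated. `mtry` and the minimum node size are exposed — a
perfect-predictor sanity check needs `mtry = p` for the forest to isolate
the copied feature. Family roll-ups (summed % per feature family) support
statements like "radial features collectively dominate".

Group comparisons: `anova_fdr` (one-way ANOVA omnibus + all-pairs Welch
tests, Benjamini–Hochberg — the base test behind an "FDR-corrected post
hoc" is unspecified in common practice, and Welch+BH is the conservative
default), `kruskal_dunn` (Kruskal–Wallis + Dunn's z tests with tie
correction, Bonferroni-adjusted, as in standard Dunn post hoc software),
and `mannwhitney` (all-pairs Wilcoxon rank-sum, BH). Condition-mean
relations use OLS with r² the squared Pearson correlation.

# Numerical choices and degenerate inputs

* Perimeter: Kulpa-weighted chain code (0.948/1.340 per straight/diagonal
  step), ~0.5 % accurate on digitized circles, keeping circularity ≤ ~1.
* Solidity: pixel-count area over convex-hull polygon area corrected by
  half the hull perimeter (Pick-style boundary correction), clamped at 1.
* Radial binning: ring i covers ((i−1)/6, i/6], d clipped to [0, 1],
  d = 0 in ring 1; empty rings get mean_frac 0.
* Blur speckle: EBImage's FFT-based Gaussian blur leaves ±1e-16 residue on
  exact-zero backgrounds; ridge maps clamp values below 1e-8 to zero.
* All-background images segment to empty masks, not errors; constant
  images are flagged; single-pixel regions flag perimeter-based features
  undefined.
* TIFF float storage is defined on [0, 1]; fields exceeding 1 are divided
  by their maximum on write (fluorescence scales are relative).
* Determinism: segmentation and features are fully deterministic;
  generators and forests consume named substream seeds derived from one
  master seed, so identical (config, seed) reproduce plates bit-exactly.

# Problem sizes used by the test and acceptance suites

Parameter-recovery checks run on an 8-dose plate (50–1000 µM, 2 fields per
well, ~300 QC-retained organoids, full features) and a 6-level mosaic
plate (3 fields per well, ~50 retained per level, radial-centric feature
families); the saturation and monotonicity properties use the analytic
geometry sampler at n = 200–300 per condition; apical recovery uses single
512×512 px mosaics (≥ 300 cells each). These sizes give the statistics
comfortable margins (e.g. the 0 % vs 12.5 % knockout ring-2 contrast is
detected at p < 1e-10) while keeping a full run of the suite inside a few
minutes on one CPU.

# Known limitations

* The lumen-boundary erosion assumes an approximately annular ring; wildly
  non-annular marker topologies (e.g. open lumens imaged tangentially)
  will bias lumen areas.
* The ray-based radial coordinate is exact for star-shaped objects;
  strongly concave bodies fall back to the flagged distance-transform
  coordinate.
* Importance percentages depend on the estimator; permutation importance
  still splits credit among strongly collinear features.
* Generative constants (EC₅₀, Hill slope, noise levels) are configuration
  defaults chosen for realism, not estimates of any real compound's
  potency.
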