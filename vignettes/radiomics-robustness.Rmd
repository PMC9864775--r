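---
title: "Methods: quantifying radiomic-feature robustness to segmentation and preprocessing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying radiomic-feature robustness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A radiomic feature is only useful if it measures the lesion rather than the
hand that outlined it. This package treats alternative segmentations of the
same lesion as repeated "ratings" of one subject and asks, feature by
feature: how much of the variance is the patient, and how much is the
delineation? On top of that sits a second question: how much does the answer
itself move when the preprocessing that precedes feature computation —
gray-level bin width, texture neighbourhood distance, interpolator,
isotropic resampling resolution — changes within reasonable bounds?

## The feature panel

`extract_features()` computes 851 features per volume/mask/configuration:

* 14 shape features from the mask geometry only;
* 18 first-order statistics of the in-mask intensities;
* 24 GLCM, 16 GLRLM, 16 GLSZM, 5 NGTDM and 14 GLDM texture features from
  matrices built on the discretized region (93 intensity features in all);
* the same 93 intensity features on each of the 8 sub-bands of a
  single-level undecimated coiflet-1 wavelet transform (93 × 8 = 744).

The original-image block comes first (its 93 intensity features, then the 14
shape features), followed by the 8 sub-band blocks — 107 + 744 = 851 named
values in a stable order.

Pipeline order is: resample volume and mask to the isotropic target →
wavelet-transform the resampled volume → discretize each image over the
resampled mask → compute features. The wavelet is applied after resampling
so that all nine images share one grid and one mask; discretization is
re-anchored per sub-band (each sub-band has its own in-mask minimum), so a
sub-band's gray levels always start at 1. Both orderings are defensible;
this one keeps every downstream computation on a single grid and makes the
sub-band histograms well-conditioned regardless of the sub-band's dynamic
range.

### Preprocessing parameters

| parameter | default | grid | meaning |
|---|---|---|---|
| `bin_width` | 20 | 10, 20, 40 | fixed gray-level bin size (intensity units); discretization is `floor((x − min)/W) + 1`, anchored at the in-mask minimum so an additive intensity shift changes nothing |
| `pixel_distance` | 1 | 1, 2, 4 | Chebyshev offset (voxels) of the GLCM pair offsets and the NGTDM/GLDM neighbourhoods |
| `interpolator` | linear | nearest, linear, spline | intensity interpolation at resampling; `spline` is a prefiltered cubic B-spline (order 3), the common default of medical-image toolkits |
| `resolution_mm` | 2 | 1, 2, 2.5 | isotropic target spacing; masks are always resampled nearest-neighbour and stay binary |

The full factorial grid is 3 × 3 × 3 × 3 = 81 configurations.

### Numerical choices worth knowing

* **Mesh shape features.** Surface area and mesh volume come from a
  marching-cubes surface. Meshing the raw binary indicator overestimates the
  area of any smooth lesion by ~10% (the staircase never converges to the
  continuum surface), so the indicator is first smoothed with a small
  Gaussian (σ = 0.8 voxel) and the 0.5 iso-level is meshed; on digitized
  spheres this brings area and volume within a few percent of the analytic
  values. If a mask is so small that the smoothed field never reaches 0.5
  the raw indicator is meshed instead; a single-voxel mask gets `NA` mesh
  features (voxel-based features are still returned). The cell-wise
  triangulation is the classic 256-case marching-cubes table; its known
  face-ambiguity holes are negligible at these mesh sizes but make mesh
  area/volume exactly invariant only up to the cell triangulation under
  axis permutation (≈0.1%, tested at that tolerance).
* **Directional families.** GLCM and GLRLM use the 13 unique 3D directions;
  features are computed per direction and averaged (not matrix-merged — both
  conventions exist and give different values). Directions with no voxel
  pairs are excluded from the average.
* **Degenerate regions.** On a single-gray-level region: Correlation, Imc1,
  Imc2 and MCC are defined as 1 (the perfectly-dependent limit), NGTDM
  Coarseness is capped at 10⁶, NGTDM Contrast/Busyness/Strength fall back to
  0, and zero-variance Skewness/Kurtosis are 0. These are documented
  constants so that downstream agreement statistics always receive numbers.
* **GLDM.** Dependence is the count of neighbours within the Chebyshev
  radius whose level differs by at most α = 0; matrix column *j* corresponds
  to dependence *j* − 1 (i.e. emphasis weights use dependence + 1), keeping
  isolated voxels well-defined.
* **Percentiles** use the linear-interpolation convention; Kurtosis is
  uncorrected (Gaussian → 3).
* **Wavelet boundary handling** is symmetric (mirror) padding; the
  undecimated transform keeps every sub-band on the input grid so the mask
  applies without re-registration. The coif1 analysis taps are frozen
  package constants.
* **B-spline resampling** prefilters to interpolating coefficients with the
  standard recursive filter (pole √3 − 2, whole-sample mirror boundary,
  exact periodic initialisation for short signals), so resampling an
  already-isotropic volume at its own resolution is the identity for all
  three interpolators.

## The agreement model

`icc_agreement()` implements the two-way random-effects,
absolute-agreement, single-measure ICC — ICC(A,1) in the McGraw–Wong
nomenclature — from the two-way ANOVA mean squares, with the standard
F-based 95% confidence interval (Satterthwaite degrees of freedom). The
robustness statistic is the **CI lower bound**, and "excellent" means lower
bound strictly greater than 0.9.

Why absolute agreement rather than consistency: segmentation styles are a
systematic factor (a rough contour is systematically larger), and a feature
whose values shift with the style is not interchangeable across styles even
if it ranks patients identically. Absolute agreement charges that shift to
the denominator; consistency would not. The model label is recorded in every
output row. When both MS_C and MS_E are exactly zero (each style reproduces
each patient's value exactly) the ICC and both CI bounds are defined as 1;
an all-identical ratings matrix is an error, since agreement about nothing
is undefined.

Sensitivity aggregation across the fixed-parameter combinations uses the
**maximum** range — the worst case — and sensitivity is computed on CI lower
bounds, consistent with the lower bound being the robustness statistic.
Shape features depend only on the resampled mask, so their values are
bit-identical across bin widths and pixel distances and their sensitivity to
those two parameters is exactly zero — a structural fact the acceptance
suite asserts exactly, not approximately.

The coefficient of variation across a patient's three segmentations uses
the absolute mean in the denominator (features such as ClusterShade are
legitimately negative); records with |mean| below 10⁻⁸ × the feature's
cohort scale are flagged excluded rather than producing unstable ratios.
Spearman correlation (mid-ranks for ties) relates CV to lesion volume. No
multiple-testing correction is applied anywhere; the outputs are
descriptive tables, not hypothesis tests.

## The synthetic cohort: what it emulates, and what it does not

`generate_cohort()` produces, by default, 48 patients on a 64 × 64 × 48 grid
with (0.7, 0.7, 1.25) mm spacing — CT-like in-plane/slice anisotropy at desk
scale. Each lesion is an ellipsoid (largest semi-axis uniform in 5–12 mm,
per-axis shrink factors 0.7–1) with soft-tissue-like mean intensity (−20 to
+40) on an aerated-lung background (−800), plus a Gaussian-correlated
texture field (SD 20–60, correlation length 3 mm) and i.i.d. noise (SD
5–20). Everything is a pure function of `(n_patients, master_seed, ranges)`;
each patient has a derived sub-seed, split per segmentation style, so adding
a style never perturbs the others.

The three styles emulate accurate free-hand, rough free-hand, and rough
polygonal delineation: the rough styles add a 2 mm outward margin (the
free-hand one with smooth radial jitter of 1 mm amplitude; the polygonal one
as a per-slice 6–10-gon circumscribing the inflated cross-section), so both
are supersets of the accurate mask whenever jitter amplitude < margin. The
magnitudes are stated configuration, not estimates of radiologists'
behaviour — no quantitative description of the real rough contours exists to
calibrate against.

Two consequences of this design matter when reading results:

* The margin is *systematic*: every rough mask of every patient is larger.
  Absolute-agreement ICC charges this to the denominator, so synthetic
  shape-feature ICCs sit well below what consistency ICC would report (on
  the packaged seed, VoxelVolume has ICC(A,1) ≈ 0.72 where ICC(C,1) ≈ 0.95)
  and below values reported for expert radiologists on real lesions, whose
  rough contours are not uniformly 2 mm larger.
* For the same reason the CV-versus-volume Spearman correlation of shape
  features is strongly negative on phantoms (a fixed-width margin is
  proportionally larger on small lesions), where real cohorts show only a
  weak negative trend; the *sign* is the transferable observation.
* All phantom lesions are smoothed ellipsoids, so scale-free shape features
  (Sphericity, Flatness) have little between-patient variance and
  correspondingly low ICC — real tumours vary far more in shape. Passing
  the suite therefore demonstrates the *machinery* (ordering of shape vs
  texture robustness, structural zero sensitivities, determinism), not the
  clinical magnitudes, which are properties of real cohorts.

The generator also does not simulate CT physics (beam hardening,
reconstruction kernels) or inter-scanner variability: the emulated study
design is a single scanner, single protocol.

## Problem sizes used by the tests and the acceptance script

The packaged checks use sizes chosen to keep a laptop run comfortable while
still exercising every code path: oracle equivalence on 50 random ≤ 6³
fixtures per texture family (tolerance 10⁻⁹ against scalar-loop brute-force
enumeration); ICC against an independent ANOVA oracle on 100 random
matrices (10⁻¹²) plus a 500-replicate Monte-Carlo recovery of a generative
ICC of 0.9 (n = 100, k = 3, mean within ±0.02); shape-feature sensitivity on
a 4-patient cohort over a 2⁴ factorial smoke grid; and the cohort-level
shape-vs-GLCM comparison on the full 48-patient default cohort at one
reference configuration (bin width 20, distance 1, linear, 2 mm). Experiment
outputs are CSV-sharded per configuration with the configuration id in
every file name, so partial runs resume and outputs from different
configurations cannot be mixed.

## Known limitations

* Classic marching cubes (with indicator smoothing) trades exact
  permutation invariance for convergence to continuum surface measures.
* GLCM/GLRLM direction averaging and the GLDM dependence-plus-one column
  convention are choices among published alternatives; comparisons against
  other implementations should match conventions before matching numbers.
* The ICC model is fixed at A,1 by design; there is no consistency-model
  option precisely because the package's question is interchangeability.
* Feature *names* follow the `<filter>_<family>_<name>` convention of the
  widely used IBSI-aligned panels; where other toolkits differ at the level
  of individual feature naming, counts and definitions — not names — are the
  contract.
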