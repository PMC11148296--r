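---
title: "Malignant-subregion texture analysis of breast DCE-MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Malignant-subregion texture analysis of breast DCE-MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(habitex)
```

## The analysis in one paragraph

Breast tumors are kinetically heterogeneous on dynamic contrast-enhanced
MRI: individual voxels wash contrast out, plateau, or keep enhancing.
`habitex` classifies every lesion voxel by its time-intensity curve,
merges the washout and plateau voxels into a *malignant subregion*,
extracts a radiomic texture panel from that subregion on the first
post-contrast phase, screens the features between high and low Ki-67
expression cohorts (Ki-67 > 20% counting as high, the St Gallen
convention), reduces the significant set by correlation pruning and
minimum-redundancy maximum-relevance (mRMR) ranking, and evaluates a
support vector machine on the retained panel with ROC analysis, a
Youden-index operating point and stratified 10-fold cross-validation.
Because clinical DCE-MRI cohorts are rarely shareable, the package also
ships a phantom generator that emulates the whole data-generating
process with a known ground truth, which is how every downstream stage
is tested.

## Voxel-wise kinetic classification

Two enhancement ratios drive the segmentation, both of the form
$(SI_b - SI_a)/SI_a$:

* the **first-phase ratio** compares the first post-contrast phase with
  the pre-contrast scan; voxels above 50% are *enhancing*;
* the **late ratio** compares the last phase (360 s) with the first
  (60 s); enhancing voxels above +10% are *persistent*, below -10%
  *washout*, and the remainder *plateau*.

All three comparisons are strict, so a voxel sitting exactly on a
threshold falls to the non-enhancing class (first gate) or to plateau
(both band edges), which matches the wording of the rule ("greater
than", "less than", "the remaining voxels"). Voxels with a pre-contrast
signal at or below $10^{-6}$ of the volume maximum have an undefined
ratio and are labeled non-enhancing rather than raising an error; the
count is available from the subregion map. Classification runs on the
native acquisition grid — the ratios are properties of acquired voxels —
and the resulting malignant mask is resampled alongside the image
afterwards. Only the plain, first and last phases enter the rule, so the
map is invariant to permuting the middle phases.

The malignant subregion is the union of washout and plateau voxels. A
lesion without a single washout or plateau voxel has no malignant
subregion; such a study is excluded from feature extraction and recorded
in the cohort's exclusion list rather than failing the run.

## Preprocessing

Three operators are applied before texture computation, in this order:

1. **Normalization** (`normalize_mu3sigma()`): the whole first-phase
   volume is z-scored, multiplied by 100, and clipped at ±3 standard
   deviations. The combination of scale 100 and clip 3 makes the fixed
   bin width below meaningful across subjects.
2. **Resampling** (`resample_isotropic()`): to 1 mm isotropic voxels,
   separable Catmull-Rom cubic interpolation for the image and
   nearest-neighbor lookup for masks. The output grid shares the input
   origin and preserves the physical extent to within one voxel.
3. **Discretization** (`discretize_fixed_binwidth()`): gray levels are
   `floor((x - min) / 5) + 1`, computed within the malignant mask of
   each (possibly filtered) image. This is shift-invariant and
   equivariant under joint scaling of intensities and width.

The order normalize → resample → discretize was chosen so that bins
reflect the final voxel values; it is the main genuinely open design
point in the preprocessing chain, and both the normalization statistics
(whole volume rather than VOI) and the interpolator class are
configurable in `extract_config()`.

## The feature panel

Features are named `<image>_<family>_<name>` with image `original`,
`log_sigma_<s>_mm_3D` (Laplacian-of-Gaussian at scale *s* mm) or
`wavelet_<band>`. Three families are computed:

* **Shape (14)** — from the lesion mask only: mesh volume and surface
  area from a marching-tetrahedra triangulation, sphericity, the maximum
  3D diameter and the three maximum 2D diameters (the `Column` diameter
  drops the anterior-posterior axis, i.e. lives in the coronal plane),
  and principal-moment axis lengths with elongation and flatness.
  Surface area is measured on the iso-surface of a lightly smoothed
  indicator (Gaussian, 0.7 voxel) because the faceted surface of a
  binary mask overstates the area of any oblique face; mesh volume and
  diameters use the exact midpoint surface. A single-voxel mask is
  handled as the mesh of the voxel cube and never yields NaN.
* **First-order (18)** — population moments (Pearson kurtosis, so a
  normal sample sits near 3; skewness and kurtosis of a constant sample
  are 0), energies, robust statistics, and Entropy/Uniformity on the
  fixed-bin histogram.
* **GLCM (24)** — symmetric co-occurrence matrices at distance 1 along
  the 13 unique 3D directions, one matrix per direction, features
  averaged over directions. Entropies are in bits. Degenerate 1×1
  matrices follow the usual conventions (Idm = 1, ClusterShade = 0,
  Imc2 = 0, Correlation = 1).

With the default Laplacian-of-Gaussian scales {2, 4} mm and the 8
wavelet subbands this yields 14 + 11 × 42 = 476 features per subject.
The filtered images are computed on the full resampled volume before
masking. The wavelet decomposition is a single-level undecimated
separable transform with an orthogonal coiflet-1 pair under periodic
convolution, which is exactly invertible (`wavelet_reconstruct()`); the
low-pass filter is normalized to unit DC gain so the LLL band of a
constant volume is that constant. Subband letters are ordered (z, y, x).
Richer family sets (run-length, size-zone, ...) are deliberately out of
scope: the features retained by the screening and selection stages all
belong to the three families above.

## Screening, selection, evaluation

`screen_features()` compares each feature between cohorts with a pooled
two-sample t-test when both groups pass Shapiro-Wilk normality at
α = 0.05, and a Mann-Whitney U test otherwise; p-values are two-sided
and **unadjusted** by default (the screen mirrors a raw p < 0.05 call,
and the Manhattan plot line sits at $-\log_{10} 0.05 \approx 1.301$); a
Benjamini-Hochberg option exists via `adjust = "BH"`.

`select_panel()` then runs two stages. Correlation pruning repeatedly
takes the worst pair above |r| = 0.75 (Pearson by default) and drops the
member with the higher mean absolute correlation against the surviving
set; ordering and ties are resolved lexicographically so runs are fully
reproducible, and re-pruning a pruned set is a no-op. mRMR ranking uses
the mutual-information *difference* criterion: the first pick maximizes
MI(feature; label), later picks maximize relevance minus the mean MI
with already-selected features. MI is estimated by plug-in entropy on
equal-frequency bins (⌊√n⌋ capped at 10); the same binning is used for
feature-feature MI. Whether pruning should be iterative or single-pass
is not fixed by any convention; the iterative variant with deterministic
ordering was chosen because its output is insensitive to column order.

`evaluate_panel()` fits a radial-kernel SVM (cost 1, kernel width 1/d on
standardized features, class weights inversely proportional to class
sizes because the cohorts are imbalanced, Platt probability calibration
so the reported cutoff is a probability), and reports: the rank AUC with
a DeLong-type asymptotic 95% interval, the Youden operating point
(ties toward higher specificity) with accuracy / sensitivity /
specificity / PPV / NPV, univariate per-feature AUCs oriented to be at
least 0.5, and stratified 10-fold cross-validation. By default feature
selection happens once on the full cohort and only the classifier is
cross-validated — this mirrors the protocol the analysis reproduces and
is optimistic; `crossvalidate_svm(refit_selection = TRUE)` provides the
leakage-free alternative.

## The phantom generator

`phantom_spec()` / `generate_cohort()` produce cohorts of 7-phase
studies (pre-contrast plus 60…360 s) with one ellipsoidal lesion per
study. Design choices, all of them configurable:

* **Kinetics**: each voxel follows a piecewise-linear template — rise to
  `1 + amplitude` at 60 s, then a linear course set by the late ratio.
  Only the two enhancement ratios matter to the classifier, so a
  pharmacokinetic model would add parameters without adding test power.
  Class defaults (amplitude 0.8; late ratio -0.2 / 0 / +0.25 / +0.05)
  keep every template at least 0.02 inside its defining inequalities.
* **Subregions**: a Gaussian random field smoothed at the coherence
  length (4 mm) is rank-thresholded to the target volume fractions
  (washout 0.35, plateau 0.30, persistent 0.20, remainder
  non-enhancing), giving exact fractions with spatially contiguous
  regions. No quantitative subregion proportions are published for real
  cohorts, so these defaults are explicitly arbitrary.
* **Noise**: additive Gaussian on every phase (default SD 2 on a
  baseline of 200, i.e. 1%). Baselines sit far above the noise floor,
  where a Rician channel is indistinguishable from Gaussian.
* **Label effect**: lesions labeled "high" have (i) the correlation
  length of the intensity-texture field multiplied by 2 (driving
  co-occurrence homogeneity/complexity features) and (ii) the
  left-right semi-axis multiplied by 1.25 (driving the coronal-plane
  maximum diameter). With both factors at 1 the generator is exactly
  exchangeable between labels, which is the null used for calibration
  tests. The effect sizes are generator configuration, not claims about
  any clinical effect; they were chosen to be clearly separable at
  cohort scale.

What the phantom does *not* emulate: motion, B1 inhomogeneity,
inter-phase misregistration, multi-focal disease, irregular lesion
margins, and realistic background parenchymal enhancement. Passing the
synthetic-recovery tests therefore shows that the pipeline's stages are
correct and connected, not that the clinical effect sizes would be
attainable on patient data.

## Problem sizes and numerical choices

The test suite exercises cohorts of 81 high / 38 low subjects on a
28 × 28 × 20 voxel grid with 8 × 6 × 6 mm lesions — the full cohort
size with a compact field of view, chosen so the whole suite runs
comfortably on a laptop; the acceptance script runs one cohort at the
full default 64 × 64 × 48 grid. Seeds fan out deterministically
(master seed → per-study seeds via one `sample.int` draw; stage seeds
are offsets of the master), so every cohort, fold assignment and SVM
calibration is bit-reproducible. Degenerate inputs are handled
explicitly rather than propagating NaN: zero-variance volumes refuse to
normalize, empty masks refuse to resample or mesh, constant features
screen to p = 1 with a warning and are dropped first in pruning, and
constant scores report AUC 0.5 with a degenerate-interval warning.

## Known limitations

* The 2D diameters assume the axis convention (x, y, z) = (left-right,
  anterior-posterior, inferior-superior); data in other orientations
  must be reoriented first, as the NIfTI orientation matrix is not
  consulted beyond voxel spacing.
* Phases are assumed co-registered; no motion correction is attempted.
* The default evaluation reproduces a select-then-cross-validate
  protocol, which overstates generalization; use the leakage-free mode
  for honest error bars.
* Mutual information at n ≈ 100 with 10 bins carries plug-in bias of
  order 0.04 nats; mRMR rankings between near-tied features are
  accordingly noisy.
```{r, eval = FALSE}
# end-to-end example on a small phantom cohort
spec <- phantom_spec(grid = c(28, 28, 20), lesion_semiaxes = c(8, 6, 6),
                     n_high = 20, n_low = 12)
pl <- run_ki67_pipeline(spec = spec, seed = 1, folds = 5)
print(pl)
autoplot(pl$screen)      # Manhattan plot
autoplot(pl$eval)        # ROC curve
```
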