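# habitex

Malignant-subregion texture analysis of breast DCE-MRI for predicting
Ki-67 expression status.

Dynamic contrast-enhanced MRI samples each voxel's signal before
contrast injection and at 60–360 s afterwards. Voxels inside a breast
lesion follow different kinetic patterns, and the washout/plateau
patterns track malignancy. `habitex` implements the full analysis chain
around that observation, for imaging researchers who want a tested,
reproducible reference implementation:

1. **Subregion segmentation** — per voxel, with
   ER<sub>first</sub> = (SI₆₀ − SI₀)/SI₀ and
   ER<sub>last</sub> = (SI₃₆₀ − SI₆₀)/SI₆₀:
   enhancing if ER<sub>first</sub> > 0.5; then persistent if
   ER<sub>last</sub> > 0.1, washout if ER<sub>last</sub> < −0.1, plateau
   otherwise. The **malignant subregion** is washout ∪ plateau.
2. **Texture extraction** on the first post-contrast phase restricted to
   the malignant mask: μ±3σ normalization, 1 mm³ resampling, bin-width-5
   discretization, then 14 shape + 18 first-order + 24 GLCM features on
   the original, Laplacian-of-Gaussian (σ ∈ {2, 4} mm) and 8
   undecimated-wavelet-subband images (476 features by default).
3. **Screening** — per feature, pooled t-test or Mann-Whitney U chosen
   by a Shapiro-Wilk normality gate; unadjusted p < 0.05, Manhattan-plot
   data included.
4. **Selection** — iterative |r| > 0.75 correlation pruning, then mRMR
   (mutual-information difference) ranking to a top-5 panel.
5. **Modeling** — RBF SVM with Platt probabilities; rank AUC with DeLong
   95% CI, Youden-index cutoff J = sens + spec − 1 with
   accuracy/sensitivity/specificity/PPV/NPV, per-feature AUCs, and
   stratified 10-fold cross-validation.

A synthetic phantom module (`phantom_spec()`, `generate_cohort()`)
produces 7-phase cohorts with known subregion structure and a
configurable label effect, so the entire pipeline is testable without
patient data. See the vignette
(`vignettes/malignant-subregion-texture.Rmd`) for the model details and
design decisions.

## Worked example

```r
library(habitex)
spec <- phantom_spec(grid = c(28, 28, 20), lesion_semiaxes = c(8, 6, 6),
                     n_high = 20, n_low = 12)
pl <- run_ki67_pipeline(spec = spec, seed = 1, folds = 5)
print(pl)
```

```
Ki-67 texture pipeline: 32 subjects, 476 features
  significant: 170 | pruned: 125 | panel: log_sigma_2_0_mm_3D_firstorder_Maximum,
  original_shape_SurfaceArea, log_sigma_4_0_mm_3D_glcm_Contrast,
  wavelet_HHL_firstorder_Mean, wavelet_LLL_firstorder_Range
Ki-67 SVM evaluation (32 subjects, 5-feature panel)
  AUC 1.000 [1.000, 1.000]
  Youden cutoff 0.896: acc 1.000 sens 1.000 spec 1.000 ppv 1.000 npv 1.000
  CV AUC 1.000 +/- 0.000 over 5 folds
```

Reading the output: of 476 extracted features, 170 differed between the
synthetic high and low Ki-67 cohorts at p < 0.05; pruning removed 125
correlated ones and mRMR kept a 5-feature panel. The phantom's default
label effect (longer texture correlation and coronal elongation in
"high" lesions) is deliberately strong, so the SVM separates the two
groups perfectly here — with effect factors set to 1 the same pipeline
sits at chance, which is exactly what the calibration tests check.
`autoplot(pl$screen)` draws the Manhattan plot, `autoplot(pl$eval)` the
ROC curve, and `generics::tidy(pl$eval)` / `glance(pl$eval)` return the
metrics as tibbles.

On clinical data, use `load_dce_series()` to read co-registered NIfTI
phases plus a lesion VOI, then the same stage functions
(`build_subregion_map()`, `malignant_mask()`, `extract_features()`,
`screen_features()`, `select_panel()`, `evaluate_panel()`).

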