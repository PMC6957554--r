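# mpus — multiparametric ultrasound localization of prostate cancer

`mpus` implements an automated per-pixel pipeline for localizing
prostate cancer from co-registered transrectal ultrasound: B-mode gray
levels, shear-wave elastography (SWE, Young's modulus in kPa), and a
2-minute dynamic contrast-enhanced ultrasound (DCE-US) cine loop
recorded after a microbubble bolus. It is aimed at ultrasound
quantification researchers who want a complete, reproducible reference
implementation of model-based contrast analysis plus machine-learning
combination — runnable end to end on a bundled synthetic data
generator, with ground truth, when no clinical data are at hand.

## What it computes

Per pixel of the prostate, from the motion-compensated loop, twelve
DCE-US parameters:

* a modified **local density random walk (LDRW)** bolus fit
  `C(t) = α √(κ / 2π(t−t₀)) · exp(−κ(t−t₀−μ)² / 2(t−t₀))`
  giving area under the curve α, dispersion-related rate κ (1/s) and
  mean transit time μ (s);
* heuristic bolus descriptors: appearance time AT (5% of peak), peak
  time PT, peak intensity PI, wash-in time WIT (10→90% rise);
* contrast-dispersion estimators over a 0.5–2 mm ring of neighbors:
  spatiotemporal correlation r, Welch spectral coherence ρ, and — by
  Tikhonov deconvolution of the center-to-neighbor impulse response
  followed by a joint fit of the convection–dispersion Green's function
  `g(t; d, v, D) = d/√(4πDt³) · exp(−(d−vt)²/4Dt)` — the convective
  velocity v (mm/s), dispersion D (mm²/s), and Péclet number
  Pe = v·L/D.

Together with Young's modulus E and gray level G, each of the 14 maps
expands into 6 radiomic features (value, value relative to the
per-image median, local entropy at ~1/2/3 mm, local variance at ~2 mm),
for 84 features per pixel. A zonally stratified random forest — one
1000-tree forest per prostate zone (PZ/TZ), each tree grown on a
1/1000th bootstrap after discarding six random training patients, with
cross-entropy splits, depth ≤ 50, calcified pixels omitted — produces
the multiparametric score `(malignant votes − benign votes)/trees`
∈ [−1, 1], median-filtered over ~2.5 mm. Evaluation is
leave-one-patient-out, with pooled pixel- and region-wise ROC-AUC,
Wilcoxon rank-sum comparisons, and a feature correlation matrix.

## Worked example

A complete synthetic study: simulate 12 patients (3 planes each, here
on a coarsened 0.5 mm/px grid), extract all features, and run the
leave-one-patient-out evaluation.

```r
library(mpus)

cfg    <- sim_config(n_patients = 12, grid = c(36, 48), pixel_spacing = 0.5)
rc     <- run_config(median_filter_radius_px = 5)   # ~2.5 mm at 0.5 mm/px
cohort <- simulate_cohort(cfg, seed = 11)
planes <- cohort_features(cohort, rc)
tab    <- build_feature_table(planes)               # 2088 labeled pixels
cv     <- lopo_crossval(tab, rc, seed = 21, planes = planes)

cv$auc$mp_pixel
#> [1] 0.9884785
cv$auc$mp_region
#> [1] 0.9968254
round(sort(cv$auc$feature_region, decreasing = TRUE), 3)
#> kappa    PI     E alpha     D   rho     v    Pe    AT     G    mu     r    PT   WIT
#> 0.752 0.718 0.677 0.582 0.493 0.489 0.471 0.451 0.394 0.277 0.146 0.142 0.138 0.118
```

Reading: pooling all held-out regions of interest, the multiparametric
score separates malignant from benign ROIs with AUC 0.997 at this seed,
while the best single parameter (kappa, 0.75; or wash-in time, 0.88
once its negative orientation is flipped via
`cv$auc$feature_region_oriented`) stays well below it — the combination
of perfusion, dispersion and elasticity channels is what localizes the
lesions, not any single map. Values near 0 in the raw table (e.g. `mu`,
`WIT`) are parameters that discriminate with the opposite sign: shorter
transit and wash-in in malignant tissue.

Single planes work the same way:

```r
pat <- simulate_patient(cfg, 123, "P01")
pf  <- extract_plane_features(pat$bundles$apex, rc)
sm  <- median_postfilter(
  score_map(train_zonal_forest(tab, rc, 17), pf$features,
            pat$bundles$apex$zone_mask), 5)
region_scores(sm, pat$bundles$apex$roi_labels)
```

A thin command-line front end (`inst/cli/mpus.R`) wraps the same
functions (`simulate`, `moco`, `extract`, `train`, `predict`,
`crossval`) for shell use.

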