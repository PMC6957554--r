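---
title: "Multiparametric ultrasound localization of prostate cancer: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiparametric ultrasound localization of prostate cancer: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mpus)
```

## The problem

Prostate cancer is multifocal and heterogeneous, and no single ultrasound
modality localizes it reliably. B-mode gray levels, shear-wave
elastography (SWE, Young's modulus in kPa) and dynamic contrast-enhanced
ultrasound (DCE-US, microbubble transit after a bolus injection) each
carry partial, complementary information: malignant tissue tends to be
stiffer than its host zone, to show faster contrast inflow (higher
convective velocity, shorter transit and wash-in times) and to disturb
the spatial coherence of contrast transport through its disorganized
microvasculature. `mpus` implements a per-pixel pipeline that extracts
model-based DCE-US parameters and multiscale radiomics from all three
modalities and combines them with a zonally stratified random forest
into a single multiparametric score per pixel, in `[-1, 1]`, positive
values indicating malignancy. Everything runs on a bundled synthetic
multiparametric-plane simulator, so the full pipeline — including
leave-one-patient-out (LOPO) evaluation — is exercisable without
clinical data.

## Pipeline

One *plane bundle* holds, on a common pixel grid: the DCE-US cine loop
(~2 min at 5 Hz, with timestamps and pixel spacing), the B-mode image,
the SWE map, a prostate mask, peripheral-zone/transition-zone (PZ/TZ)
labels, a calcification mask and histopathology-derived benign and
malignant regions of interest (ROIs). Segmentation and inter-modality
registration are upstream of this package: masks are inputs and are
assumed co-registered; a shape mismatch is an error, never silently
resampled.

### Motion compensation

The loop is rigidly stabilized against its wash-in reference frame (the
frame nearest 30 s). Transforms (translation within ±5 mm, rotation
within ±10°) are estimated at every 5th frame by maximizing normalized
cross-correlation — FFT correlation for the shift with parabolic
subpixel refinement, a coarse grid plus golden-section search for the
angle — and intermediate frames get componentwise linear interpolation
of `(tx, ty, θ)`. Design choices the problem left open: anchors extend
from the reference index in both directions and the last partial segment
reuses the nearest anchor; angles are interpolated linearly in degrees
(they are small); anchor estimates below the estimator noise floor
(0.05 px / 0.05°) snap to zero so a static loop passes through
bit-unchanged; frames without registrable structure (flat, or
correlation below 0.1 — e.g. before contrast arrival) keep the identity.

### Per-pixel bolus kinetics

Each in-prostate pixel's time-intensity curve (TIC) is
baseline-corrected (median of the first 10 s), clipped at zero and
low-pass filtered (zero-phase Butterworth magnitude, 0.5 Hz cut-off —
bolus kinetics live well below that). The modified local density random
walk (LDRW) bolus model

$$C(t) = \alpha\sqrt{\frac{\kappa}{2\pi(t-t_0)}}
  \exp\!\left(-\frac{\kappa\,(t-t_0-\mu)^2}{2(t-t_0)}\right),\quad t>t_0$$

is fit by bounded Levenberg-Marquardt, giving the area under the curve
α (a.u.·s), the dispersion-related rate κ (1/s) and the mean transit
time μ (s). Moment-based starts (t₀ one second before the appearance
time; μ the intensity-weighted mean of t−t₀; κ = μ/variance; α the
trapezoidal integral) make the noiseless fit exact to well below 1%.
t₀ is a free parameter bounded in `[0, AT]`; a fit that does not
converge or pins a parameter at a bound marks the pixel invalid — an
`NA`, never a silent zero, and invalid pixels are excluded from every
downstream median, histogram and training set. Heuristic bolus
descriptors use common DCE-US conventions (the problem statement fixes
none): appearance time AT at 5% of peak intensity, wash-in time WIT as
the 10→90% rise time on the rising limb, peak intensity PI and peak
time PT from the smoothed curve.

### Dispersion estimators

Around each pixel a ring kernel (default 0.5–2.0 mm, the microvascular
scale; decimated uniformly in angle to at most 24 members, beyond which
the estimators no longer change appreciably) selects neighbors.

* **Spatiotemporal correlation r** — mean Pearson correlation between
  the center TIC and each neighbor over the bolus window (5 s before
  the center's appearance time to 60 s after, clipped to the record).
  Zero-lag correlation is used. The window is computed on an
  offset-free copy of the curve so r is exactly invariant to affine
  intensity scaling.
* **Spectral coherence ρ** — Welch magnitude-squared coherence
  (32-sample segments, 50% overlap, per-segment demeaning, untapered),
  averaged over the 0–0.5 Hz band (DC excluded) and over neighbors.
  Coherence is delay-invariant, isolating dispersion from transit
  delay; segments are left untapered because tapering erodes exactly
  that delay invariance on transient bolus records, which is the
  property the estimator exists for.
* **Convection–dispersion identification (v, D, Pe)** — the impulse
  response from center to each neighbor is estimated by
  Tikhonov-regularized FFT deconvolution (λ = 0.05 of the mean input
  power), and the 1-D convection–dispersion Green's function
  $g(t; d, v, D) = \frac{d}{\sqrt{4\pi D t^3}}
  e^{-(d-vt)^2/(4Dt)}$ is fit jointly across neighbors over `(v, D)`
  with one profiled non-negative amplitude. A point that matters
  numerically: the regularized estimate equals the true response
  *convolved with the regularization filter*
  `B(f) = |X|²/(|X|² + λ·mean|X|²)`, so candidate models are blurred
  with the same filter before comparison (reconvolution-space
  fitting). Without this, the narrow Green's function is fit to a
  smeared response and v is biased low by a factor ~2; with it, the
  noiseless inversion is exact. The Péclet number is reported as
  `Pe = v·L/D` with L the mean member distance — an exact identity of
  the output, not a separate estimate. Per-pixel maps use a shared
  log-spaced `(v, D)` candidate library blurred with the plane-mean
  filter, followed by a local grid refinement; the one-off estimator
  refines by Nelder-Mead. Estimates pinned at the search bounds are
  invalid. Border pixels keep their estimate while at least 8 ring
  members remain.

### Radiomics and calcifications

Every base map (12 DCE-US parameters plus Young's modulus E and gray
level G) expands into six per-pixel features: the value; the value
minus the per-image in-mask median (`.rel` — a difference, not a
ratio, because several maps legitimately cross zero; this also removes
patient-level offsets, which is what lets the classifier survive
between-patient variability); local Shannon entropy in circular
kernels of ~1, ~2 and ~3 mm (32 histogram bins spanning the per-image
robust 1–99% range — per-image, not per-kernel, so entropies are
comparable across pixels; values outside the range clamp to the edge
bins; fewer than 10 valid members invalidates the pixel); and the
unbiased sample variance in a ~2-mm kernel. That is 14 × 6 = 84
features per pixel. Physical kernels convert to pixels by rounding the
radius to the nearest pixel, at least 1.

Calcifications are detected on the B-mode image with two Gaussian
matched filters (σ ≈ 0.6 and 1.8 mm, targeting spots of ~1.2 and
~3.6 mm diameter). Each response is thresholded 3 robust standard
deviations (median + 3·1.4826·MAD) above the in-mask center — robust
statistics so the calcifications themselves cannot inflate the
threshold — the union is gated by raw-image brightness at the same
robust level (the matched-filter response spills beyond a bright spot;
the gate removes that halo), and components under 3 px are discarded.
Detected pixels are carried as a flag: they are omitted from training,
but still scored at inference for display.

### Zonal random forest

Healthy TZ tissue is stiffer and perfuses differently than PZ tissue,
so pooling zones degrades every threshold the trees learn. The forced
first split on zonal location is therefore *realized* as two
independently grown per-zone forests with deterministic per-stratum
seeds — `zonal_equivalence_check()` verifies the construction is exactly
equivalent to retraining each stratum separately. Per stratum, 1000
trees are grown; before each tree, six training patients (drawn from
the full training cohort) are discarded entirely — a patient-level
decorrelation that promotes generalization across patients — and
⌈N/1000⌉ of the remaining rows (at least 100, to guard degenerate trees
on small synthetic cohorts) are bootstrapped with replacement. Trees
use cross-entropy (information) splits, depth at most 50, at least 5
samples per leaf, and ⌈√p⌉ features per split (standard forest
defaults where the recipe is silent; all config-exposed). The tree
grower is implemented in C++ (as the field's forest packages do) and
draws its feature subsets from R's RNG, so a training seed reproduces
the model bit-exactly. Leaf ties are broken by the label of the
lowest-index sample in the leaf, which keeps the ensemble score exactly
antisymmetric under a global label swap.

The multiparametric score of a pixel is the vote ratio
`(malignant − benign) / n_trees` of its zone's stratum — read of the
recipe's "ratio between malignant and benign classifications" that
actually spans `[-1, 1]` with the stated endpoints. Score maps are
post-filtered with a circular median (default radius 15 px ≈ 2.5 mm at
0.167 mm/px — interpreted as a radius, consistent with that physical
size, about half the radius of a clinically significant lesion),
intersected with the valid mask; invalid pixels stay invalid.

### Evaluation

`lopo_crossval()` trains one model per held-out patient (fold seeds
derive deterministically from the master seed), scores the held-out
planes, median-post-filters the maps, and pools all held-out pixels and
per-ROI mean scores before computing AUCs — pooled, matching a single
dataset-level figure, with per-patient values available for
diagnostics. `roc_auc()` is the midrank Mann–Whitney statistic (the
complement identity `AUC(s) + AUC(−s) = 1` holds exactly);
`wilcoxon_rank_sum()` enumerates all assignments exactly up to total
n = 12 (p doubled from the smaller tail) and otherwise uses the normal
approximation with tie and continuity corrections, flagged at 0.05 and
0.005; `feature_correlation_matrix()` gives the Pearson matrix with
t-distribution p-values and a mask of entries not significantly linear
(p > 0.05). Single-feature AUCs are reported both raw and oriented
(`max(AUC, 1−AUC)`), since parameters such as wash-in time
discriminate with a negative sign convention; both a raw-value mode
and (via training on a feature's six radiomic columns) a per-feature
classifier mode are available for single-parameter comparisons.

## The simulator

`simulate_cohort()` generates ground-truth-bearing patients: a prostate
ellipse with an anterior TZ ellipse; one labeled lesion per plane
(alternating host zone for cohort balance) plus an optional unlabeled
second lesion; per-pixel TICs drawn from the LDRW closed form with
tissue-dependent parameters (benign PZ μ = 25 s, κ = 0.5 1/s, α = 60;
benign TZ 28/0.4/80; lesions scale μ ×0.82, κ ×1.25, α ×1.22 at the
reference grade) and a flow-axis arrival-delay field `d(x)/v(x)` that
couples neighboring pixels through the local convective velocity
(benign 0.5–0.6 mm/s, lesions +0.3 mm/s); stiffness with TZ (35 kPa)
stiffer than PZ (22 kPa) and lesions +10 kPa over their host zone;
speckled B-mode with slightly hypoechoic lesions and bright
calcification disks (which also stiffen the SWE map, the false-positive
mechanism that motivates training-time omission); optional rigid drift.
Benign and malignant ROI disks share one radius and integer centers, so
class pixel counts balance exactly, and the malignant ROI's host zone
alternates across planes, balancing PZ/TZ provenance.

Heterogeneity is deliberate: independent patient-level log-normal
multipliers (SD 0.30) on kinetics, stiffness and flow, within-plane
smooth confound fields (relative SD 0.15), 8% TIC noise, and a
three-level lesion grade scaling the malignant offsets by 0.5/1.0/1.5.
These defaults were chosen so that no single raw parameter separates
the cohort well (oriented single-feature region AUCs ≈ 0.6–0.9) while
the combined classifier — which sees zone labels and
patient-offset-free `.rel` features — reaches region-wise AUCs in the
high 0.9s at the test problem size, the qualitative regime of
interest: multiparametric combination beating every single parameter
by a clear margin. `effect_scale = 0` gives a
null simulator (lesions indistinguishable) for calibration checks, and
`family = "gamma"` generates gamma-variate kinetics to probe model
mis-specification.

What the simulator does *not* emulate: acoustic wave propagation and
realistic speckle statistics, attenuation and shadowing with depth,
recirculation of contrast, elastic (non-rigid) tissue motion, and
histology-registration error in the ROI labels. A pass on synthetic
data therefore demonstrates the correctness and internal consistency of
the estimators and the classifier recipe, not clinical performance.

## Problem sizes and numerics

Analyses in the test-suite and the acceptance script run a 12-patient,
3-plane cohort on a 36 × 48 px grid at 0.5 mm/px — the package's chosen
analysis problem size; anatomy, kinetics and kernel sizes stay at their
physical scales, only the raster is coarser than the 192 × 144 px /
0.167 mm/px simulator default. At the coarser spacing the ~2.5 mm
median post-filter is 5 px. The null-simulator check averages the
held-out pixel AUC over five independent 10-patient, 2-plane null
cohorts: one small null cohort carries sampling spread of roughly
±0.1 around chance, so a banded assertion is only meaningful for the
replicate mean.

Numerical choices collected in one place: invalid estimates are `NA`
throughout and excluded from every statistic; LDRW fits stop at
relative RSS tolerance 1e-8 or 500 iterations; the deconvolution
regularization is fixed at λ = 0.05 and recorded with the resolved
configuration; `(v, D)` searches run in log space over
0.05–5 mm/s × 0.005–2 mm²/s, and bound-pinned estimates are invalid;
velocity estimates implying transport faster than one frame interval
over the nearest ring neighbor are unresolvable and marked invalid;
histogram entropies use fixed per-image bin edges so the FFT-free
counting path is exactly reproducible against a brute-force oracle;
rank-sum p-values use exact enumeration up to total n = 12, the exact
Wilcoxon null distribution for larger untied samples, and the tie- and
continuity-corrected normal approximation otherwise;
ties in the ROC statistic use midranks; exact rank-sum p-values double
the smaller tail and cap at 1; bundles persist to TIFF as rescaled
32-bit float (scale/offset in the YAML sidecar, ~1e-7 relative
fidelity) or to NIfTI as 64-bit float (exact round trip) — masks and
labels are 8-bit and exact in both.

## Known limitations

Registration is rigid and intra-loop only (SWE-to-DCE registration is
assumed done upstream). The dispersion identification inherits the
bandwidth of the bolus passage: at 20 dB SNR, velocity errors grow to
tens of percent (documented, not asserted). Calcified pixels are
scored at inference with a flag, a display decision the training-time
omission does not constrain. Region counts in the synthetic study are
small (72 ROIs), so region-wise AUCs carry wide confidence intervals;
conclusions drawn from them are directional, not clinical estimates.
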