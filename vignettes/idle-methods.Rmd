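---
title: "Integrated CT–histology risk evaluation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrated CT–histology risk evaluation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

After complete resection of a stage IA non-small-cell lung cancer, roughly a
fifth of patients progress (recurrence, metastasis or lung-cancer death), yet
TNM stage and tumor grade barely separate them. `idlelung` implements an
integrated deep learning evaluation (IDLE) of progression risk that combines
two non-overlapping views of the tumor: global morphology from the
preoperative low-dose CT (LDCT) scan and local micro-morphology from the
pathologist's readings of resected H&E sections. The package covers the full
chain — 3D CT feature extraction, tissue-feature encoding, the hybrid
network/forest risk model with leave-one-patient-out cross-validation
(LOOCV), time-dependent accuracy statistics under censoring, and decoding of
the fitted network — together with a synthetic cohort generator that makes
every step testable without access to restricted screening-trial data.

## CT feature extraction

Volumes are trilinearly resampled to a 0.5 mm isotropic grid. The lung is
segmented by thresholding air-like voxels (below −300 HU), keeping the
largest 26-connected component and closing with a 12 mm radius (large enough
to swallow the hole a ≤ 24 mm lesion leaves in the parenchyma); voxels at or
above +130 HU (bone/calcification) are never lung. A lesion is segmented
inside its gross cube (bounding box plus ≥ 1 cm margin): a 3×3×3 median
filter, Otsu's threshold restricted to lung voxels, morphological opening
and closing at one-voxel radius, then the largest component. Intensities are
normalized by subtracting the median of the adjacent normal lung and adding
300, so tumor and peritumor values are non-negative and energy-type features
are meaningful; every downstream feature is thereby invariant to constant
intensity offsets in the raw scan.

The registry emits exactly 173 named features per image:

* **Nested dispersion (9)** — the intensity-weighted center of all tumor
  voxels (linear weights) and of the top 50% / 20% by intensity; the
  dispersion `LocSd` about each center uses *squared*-intensity weights
  (the linear/quadratic asymmetry between the two stages is deliberate and
  kept exactly as defined); `LocSd/V` volume-normalized forms; and the
  Euclidean shifts `d50`, `d20` of the nested centers. Intensity ties at a
  selection cut are all retained, so a homogeneous lesion has coincident
  centers at every fraction.
* **First-order (15 × 3 VOIs)** — moments, type-7 quantiles, energy, RMS,
  and histogram entropy/uniformity on fixed 100 HU bins anchored at 0.
* **GLCM (22 × 3 VOIs)** — symmetric, normalized co-occurrence matrices at
  unit displacement along the 13 unique direction vectors obtained from
  0/45/90/135° angles in the three anatomical planes; 22 Haralick-family
  statistics averaged over directions. Sum variance is centered on the sum
  average; gray levels are the quantization bin indices.
* **GLRLM (11 × 3 VOIs)** — run-length matrices under a *strided-run*
  convention: for distance d, a run is a maximal chain of voxels visited
  every d-th step along a direction that share a quantized level. The
  classical run-length matrix has no distance parameter, so the stated
  distances 2–5 have to be given a meaning; striding is the reading that
  keeps "52 = 13 × 4 matrices" literally true. Eleven run statistics are
  averaged over all 52 matrices; run percentage divides by the VOI voxel
  count.
* **Intensity ratios (3)** — tumor/peritumor ratios of means and of the
  50th/90th percentiles.
* **Lung-level (17)** — per-lobe lesion count and any-solid /
  any-part-solid flags for the five lobes (solid: mean > −300 HU;
  part-solid: −600 to −300 HU), plus total lesion count and volume, from a
  lung-wide lesion table.

VOI geometry is a design choice the source material leaves open: the
peritumoral shell is the 0–5 mm Euclidean dilation of the tumor clipped to
lung, adjacent normal lung is the 10–15 mm shell, and the extra-tumor VOI is
lung minus tumor and peritumor restricted to the gross cube. Lesions are
eligible when noncalcified (≤ 10% of voxels above +130 HU) with equivalent
diameter ≥ 4 mm.

## Tissue features and model inputs

Per patient, ROI readings aggregate to five histologic subtype flags (union
over ROIs), the highest numeric grade (GX excluded from the maximum and
carried as a separate missing-grade flag; GX-only patients have an
undetermined grade, which grade-based comparisons exclude), the largest
invasive dimension, the ROI count and a pre-malignant flag. Model inputs add
demographics, surgery type, residual disease, lymphadenectomy, stage and
the LDCT-to-surgery interval; categoricals are one-hot encoded and
continuous columns standardized with training-fold statistics only, so no
test-fold information can leak into any fit.

## The risk model

Two hidden layers of logistic units are trained layer-wise with full-batch
gradient descent on the cross-entropy of the event-by-τ label (τ = 5 years;
patients censored before τ without an event are excluded from this stage but
kept for the forest — the loss itself cannot absorb censoring) with an L2
penalty (default 0.01; a supplied grid is resolved on an inner 70/30
validation split by unpenalized loss, because penalized training loss is
monotone in the penalty and cannot select it). Each unit draws a random
subspace of 40% of its layer's inputs: the per-unit problems are convex, so
units sharing all inputs would converge to one solution and the layer would
collapse to a single direction; subspacing keeps the units diverse and makes
the per-unit feature-selection counts informative. After training, weights
below the layer's 80th magnitude percentile — and, whenever pruning is
active, numerically negligible weights below 0.01 — are set exactly to
zero. A random survival forest (log-rank splitting, `mtry = √p`, 500 trees
by default) on the second-layer activations supplies the risk as the
ensemble cumulative hazard at τ, min–max normalized to [0, 1] by the
training-risk range and clipped for out-of-range test patients. Forest
training rows are canonically ordered, so predictions depend only on the
training multiset and duplicated patients score identically under LOOCV.
The selection trace counts, per input, the first-layer units in which it
survives pruning plus the second-layer units reachable through chained
nonzero paths.

LOOCV refits everything — standardization, grade imputation, layers, forest,
normalization — on each training fold of n − 1 patients.

## Evaluation statistics

Kaplan–Meier estimation and Cox models (Breslow ties, Wald intervals) come
from the `survival` package. The time-dependent AUC is the
cumulative-case/dynamic-control estimator with inverse-probability-of-
censoring weights from the reverse Kaplan–Meier censoring survival (cases
weighted at their event time's left limit, controls at the horizon); no
installed package provides it, so it is implemented here and checked
against brute-force pair counting in the censoring-free case, where it
reduces to the empirical AUC exactly. Its SD is the standard deviation over
500 patient-level bootstrap resamples. Time-dependent PPV/NPV follow Bayes'
rule — sensitivity × (1 − S(t)) / P(test positive), and symmetrically for
NPV — with cutoffs chosen as the highest score value whose weighted
sensitivity reaches each target; coarse scores (e.g. a three-level stage
variable) cannot reach high sensitivities and those grid points are
reported non-evaluable. Risk stratification scans cutoffs over the 10–90%
score quantiles at 1% steps with a ≥ 10-patients-per-group floor and keeps
the hazard-ratio-maximizing threshold (ties to the smaller cutoff); the scan
is rank-based. Cohort tables use Welch's t-test (the safer reading of a
"two-sample t-test") and Fisher's exact test, two-sided.

## Decoding

The network is refit on all patients; features are ranked by selection
count with ties broken by univariate logrank p then name. Top-ranked
variables are dichotomized at their HR-maximizing thresholds per endpoint
(progression, local recurrence, distant metastasis — the cause-specific
endpoints censor events of the other cause). Inputs and hidden activations
are screened by Welch t (continuous) or chi-square without continuity
correction (discrete; Fisher when an expected count drops below 5), the 25
smallest p-values are kept, and their z-score matrix uses the population SD
(rows standardize exactly to mean 0, SD 1). The synergy report compares the
integrated LOOCV scores with LDCT-only and tissue-only ablations (each
rebuilt by the identical procedure with the other platform's columns
removed; demographics and the screening-to-surgery interval stay in all
three) through time-dependent ROC at 5 and 10 years.

## The synthetic cohort

Each patient carries two independent standard-normal platform latents,
`z_ct` and `z_tis`. The linear predictor is
`η = β_ct z_ct + β_tis z_tis + β_int z_ct z_tis` (defaults 0.7 / 0.7 / 0.4);
the recorded latent risk adds N(0, 0.15²) measurement-level noise that does
not enter the hazard, so that with all effects zero the recorded risk is
pure noise and median splits separate nothing. Event times are Weibull
(shape 1.2) under proportional hazards on η, with the baseline rate
calibrated numerically so the expected observed-event fraction matches the
target (default 54/182 ≈ 0.30) under independent exponential censoring
(rate 0.03/year) capped administratively at 12 years. Observed events are
labelled local recurrence or distant metastasis with equal probability.
`z_ct` drives the planted lesion's solidity (logistic link), intensity
skewness, high-intensity cluster count and diameter (log-normal, 5–20 mm);
measured CT descriptors add small measurement noise. `z_tis` drives ROI
grades through a cumulative-logit model and invasive dimensions through a
log-normal link; patients have 2–3 slides and 1–10 ROIs (mean ≈ 5.9,
matching the real corpus ratio of ~1076 ROIs to 182 patients), and about
30% of non-AIS patients carry a second (AIS) histology. Phantom volumes are
96³ voxels at 0.5 mm: a soft-tissue shell, an ellipsoidal lung at −800 HU
with Gaussian noise (SD 20 HU), and an ellipsoidal lesion whose mean HU
rises with solidity, whose residuals are gamma-shaped when skewness is
positive, and in which compact ~2 mm blobs (capped at +120 HU so they stay
below the calcification rule) realize the cluster count.

What the generator does *not* emulate: real thoracic anatomy (airways,
vessels, lobar fissures), scanner/kernel effects, screening-round structure
and cause-of-death adjudication. Passing tests therefore demonstrate the
correctness and internal consistency of the pipeline under a known
generative model, not clinical performance on screening data.

A caveat the synthetic experiments surface explicitly: with a product
interaction on the log-hazard, each single platform retains real marginal
signal (the hazard conditional on one latent is convex in it, so its
magnitude predicts risk), which narrows the gap between the integrated
model and the ablations at small n. The cross-platform ordering is
therefore a noisy, qualitative property at desk scale.

## Problem sizes used by the test suite

The suite exercises the estimators at sizes chosen for a single-CPU run:
texture oracles on ≤ 4³ masks (30 random cases in unit tests, 100 in the
acceptance suite), segmentation phantoms at 64–96³, statistical calibration
at n = 400–2000, LOOCV behaviour at n = 12–150 with a reduced evaluation
configuration (16/8 units, 100–150 trees, capped depth), and the synergy
comparison on interaction-dominant cohorts of 120 patients over 5 seeds.
The model defaults (32/16 units, 500 unlimited-depth trees) remain the
recommended analysis settings; the vignette-stated evaluation configuration
is used wherever dozens of LOOCV refits are required.

## Known limitations

* The per-fold min–max normalization makes LOOCV scores only approximately
  comparable across folds; holding out an event slightly deflates that
  fold's hazards, a small conservative bias inherent to cross-validated
  risk scores.
* The hidden layers train on a fixed-horizon binary label; very late events
  contribute only through the forest.
* The GLRLM distance semantics and the VOI shell widths are explicit design
  choices where the method description is silent; both are parameterized.
* Competing risks are treated by censoring, matching the composite-endpoint
  design; no subdistribution hazards are modelled.
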