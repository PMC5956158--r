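---
title: "Methods: IVIM diffusion mapping, ROI histogram features, and tumor classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: IVIM diffusion mapping, ROI histogram features, and tumor classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivimcds)
```

This vignette documents the models, conventions, and design choices behind
`ivimcds`, in the order data flows through the pipeline: signal model and
map fitting, ROI histogram features, the feature repository, the
classifiers, and the synthetic data that stands in for patient scans.

## Signal model and map fitting

Diffusion-weighted MRI attenuates the signal of each voxel with the
diffusion weighting $b$ (s/mm²). The intravoxel incoherent motion (IVIM)
model separates true tissue diffusion from capillary pseudo-diffusion:

$$S(b) = S_0\left[(1-f)\,e^{-bD} + f\,e^{-b(D+D^*)}\right]$$

with tissue diffusivity $D$ (mm²/s), pseudo-diffusion $D^*$ (mm²/s,
typically an order of magnitude larger), and perfusion fraction
$f \in [0,1]$. The apparent diffusion coefficient collapses the decay
between two b-values into a single rate,
$\mathrm{ADC} = \ln(S(b_{low})/S(b_{high}))/(b_{high}-b_{low})$; for a
perfused voxel ADC exceeds $D$ because the perfusion term steepens the
low-b decay. Internally all diffusivities are mm²/s;
`map_in_reporting_units()` rescales to the clinical convention of
$10^{-6}$ mm²/s (so $1.098\times10^{-3}$ mm²/s prints as 1098).

**Feasibility.** Four unknowns need at least four distinct b-values, and a
segmented fit additionally needs both decay regimes sampled:
`check_ivim_feasibility()` requires ≥ 2 distinct b-values below and ≥ 2 at
or above the segmentation threshold. The default threshold of 200 s/mm² is
the conventional cut: with $D^* \gtrsim 5\times10^{-3}$ mm²/s the
perfusion term has decayed to $e^{-1}$ of its share by $b = 200$. The
reference 6-point protocol (0, 50, 100, 150, 600, 1000 s/mm²) splits into
a perfusion-sensitive segment {0, 50, 100, 150} and a pure-diffusion
segment {600, 1000}.

**Direction combination.** Protocols acquire each b-value along three
orthogonal gradient directions; `combine_directions()` reduces them to one
trace-weighted frame per b-value by the voxel-wise geometric mean, the
standard isotropic average (the arithmetic mean of log-signals). A zero in
any direction annihilates the product; such voxels are counted and
reported rather than patched.

**Iterated segmented fit.** The classic segmented fit — log-linear
regression over the high-b segment for $D$ and intercept $A$, then
$f = 1 - A/S(0)$, then bounded one-dimensional least squares for $D^*$ —
is only approximate: at $b = 600$ the perfusion term of a slow
$D^* = 5\times10^{-3}$ mm²/s voxel still contributes up to ~2% of the
signal, which biases the two-point high-b slope by up to ~15% at the low-D,
high-f corner of the physiological box. `fit_ivim_voxel()` therefore
iterates the three steps, each round subtracting the current perfusion
estimate from the high-b signals before refitting. The true parameter
vector is a fixed point of this iteration, so noise-free inputs converge to
machine precision (typically 3–30 iterations at a relative tolerance of
1e-10, capped at 50); the procedure stays segmented in structure, avoids a
simultaneous 4-parameter optimization, and is fully deterministic.

Numerical conventions: bounds $D \in [10^{-5}, 4\times10^{-3}]$,
$D^* \in [D, 0.5]$ mm²/s, $f \in [0,1]$ (physiological ranges); estimates
escaping a bound by more than rounding error are clipped and the voxel is
marked `nonconverged`, while sub-1e-9 excursions are clamped silently.
When $f < 10^{-4}$ the pseudo-diffusion term carries no signal and $D^*$
is pinned to $D$ (the identifiable limit) instead of being fitted.
Nonpositive signals make a voxel `degenerate`. Only `ok` voxels enter the
output maps; everything else is NaN — invalid voxels are never encoded as
sentinel numbers. The ADC pair defaults to (0, max b) and it is an error,
not a silent substitution, if either frame is missing.

## ROI histogram features

`compute_features()` produces the first-order feature set used for tumor
characterization: mean, median, ten centiles (2, 5, 10, 15, 25, 75, 85,
90, 95, 98), skewness, kurtosis, and entropy, plus voxel count and volume.
Conventions, each of which the literature leaves open and which are
therefore fixed and recorded here:

* **Centiles** are computed from the raw voxel values (not the histogram)
  with linear interpolation at rank $h = (n-1)p$ (`stats::quantile`
  type 7) — reproducible and the R default.
* **Moments** are population (biased) central moments; skewness
  $g_1 = m_3/m_2^{3/2}$, kurtosis $m_4/m_2^2$ in the Pearson (non-excess)
  convention, under which a Gaussian scores 3 and typical tumor ADC
  histograms score ≈ 2. A `sample_moments` flag switches to the unbiased
  estimators.
* **Entropy** is $-\sum_i p_i \log_2 p_i$ (bits) over the normalized
  counts of a 256-bin equal-width histogram spanning the ROI's [min, max];
  published tumor-cohort entropies of ≈ 6.8–7.1 bits require at least
  $2^8$ bins to be attainable, and 256 is recorded in every feature
  record. Entropy is invariant under value shifts (bins shift with the
  data) and ranges over $[0, \log_2 n_{bins}]$, attaining the maximum iff
  all bins are equally filled.
* **Degenerate input** (constant values) yields skewness = kurtosis =
  entropy = 0 with a flag, rather than NaN propagation.

NaN voxels inside the ROI (invalid fits) are dropped and counted. Whole
ROIs including cystic/necrotic regions are the caller's responsibility; no
automatic exclusion is applied. Morphology (`roi_morphology()`) reports
volume = voxel count × voxel volume, axis-aligned bounding lengths, the
center of mass in 0-based voxel coordinates, and the 6-connectivity
surface voxel count.

## Repository and case comparison

The repository is a JSON-lines file, one feature record per line
(`case_id`, group, map kind, features, bin count, schema version):
append-only self-archiving with clean diffs and no server dependency.
`group_summary()` uses the population SD (divide by $n$), mirroring the
moment convention above; a flag switches to $n-1$. `compare_case()`
reports, per feature and group, the index case's z-score and whether it
lies within the group mean ± 1 SD — the quantitative content of a
case-vs-cohort display. Zero-SD features report `NA` rather than an
infinite z-score.

## Classification

**Feature selection.** Features are compared between groups with the
Mann-Whitney U test ($U = \sum_{ij} [a_i > b_j] + \tfrac12[a_i = b_j]$);
the P value is exact (enumeration) for group sizes ≤ 8 without ties,
otherwise the tie- and continuity-corrected normal approximation.
Bonferroni correction uses the number of features tested. The default
selects on raw P < .05 — matching the apparent practice of clinical
reports that mark P = .03 significant among 15 comparisons, which strict
Bonferroni would not — and warns when the corrected criterion would
differ; `use_correction = TRUE` makes the strict choice. Clusters of
mutually correlated features (pairwise |Spearman ρ| above a threshold) can
be pruned to their lowest-P member, since neighbouring ADC centiles are
near-duplicates. A `preset = "reference"` returns the fixed clinical set
{mean, median, kurtosis, skewness, entropy, c15, c75}.

**2-step threshold rule.** Step 1 assigns a case to a tumor group when its
feature value lies within that group's mean ± 1 SD and not the other's.
Step 2 handles both remaining configurations — inside both bands *and*
inside neither — by nearest group mean in absolute distance, flagged
ambiguous. The "inside neither" case is underdetermined in the clinical
description this rule formalizes; treating it symmetrically with "inside
both" keeps every case classifiable. Distance ties go to malignant, the
conservative call in cancer triage. The rule is equivariant under positive
affine rescaling of the feature, so unit choices cannot change a call.
`loocv_threshold()` evaluates it by leave-one-out cross-validation,
recomputing both groups' statistics with the held-out case excluded —
the training set never sees the validation case.

**KNN / SVM.** `model_cv()` runs stratified k-fold cross-validation
(default 10-fold). Within each training fold — and only there, to avoid
leakage into the held-out cases — features are z-scored by the
training-fold statistics and SMOTE oversamples the minority class to
parity. SMOTE synthesizes $x_i + u\,(x_{nn} - x_i)$, $u \sim U(0,1)$, with
$x_{nn}$ among the $k=5$ nearest minority neighbours, so synthetic points
stay in the minority convex hull. Classifiers: KNN with $k = 5$ on the
z-scored features (probability = malignant fraction of the votes) and a
radial-basis SVM with $C = 1$ and Platt-calibrated probabilities; both are
defaults recorded in the call, since the clinical literature typically
leaves them unstated. A case with winning probability in (0.5, 0.8] is
flagged ambiguous — at most moderate confidence. All stochastic steps
(fold assignment, SMOTE, SVM calibration) run under one explicit seed and
are bit-for-bit reproducible.

**Metrics.** Malignant is the positive class. Sensitivity, specificity,
overall accuracy, and balanced accuracy are all reported: published
single-feature "accuracy" figures are not always arithmetically consistent
with any one definition, so both standard ones are emitted. ROC curves
sweep the unique scores and integrate by trapezoid, which makes
AUC = $U/(n_1 n_2)$ exactly — verified in the tests against the package's
own Mann-Whitney statistic and against an independent ROC implementation.
Net reclassification improvement sums, over the two truth classes, the net
fraction of cases a new method reclassifies correctly versus an old one;
for binary labels it equals ΔSensitivity + ΔSpecificity, is antisymmetric,
and is zero for a method against itself.

## Synthetic data: what it emulates and what it does not

**DWI phantom.** `generate_phantom()` builds the noise-free biexponential
signal per voxel and acquisition on a 32×32×8 grid with
1.56 × 1.56 × 5 mm voxels, the 6-b-value × 3-direction scheme above, and
ellipsoidal lesions in a soft-tissue background; the default tissue
parameters (background $D = 1.5\times10^{-3}$, malignant
$0.8\times10^{-3}$, benign $1.6\times10^{-3}$ mm²/s, with $f$ 0.12 / 0.08
/ 0.18) are plausible abdominal soft-tissue and tumor values, chosen once:
cellular malignant tissue restricts diffusion, benign lesions tend to be
looser and better perfused. Noise is Rician,
$S' = \sqrt{(S+n_1)^2 + n_2^2}$ with $n_i \sim N(0, \sigma)$ and
$\sigma$ = mean background $S_0$ / SNR, anchored at SNR 60 on the b = 0
images (the reported b1000 SNR of ~30 then follows from signal decay).
The phantom emulates signal decay, magnitude noise, and lesion geometry;
it does not emulate anatomy, motion, eddy currents, partial volume, or
inter-scan SNR variation (one σ per run).

**Feature cohort.** `generate_feature_cohort()` draws per-case features
from group Gaussians parameterized, by default, by published malignant /
benign ADC-histogram statistics of a 48-case pediatric cohort
(37 malignant, 11 benign; `reference_group_stats()`). Features are drawn
independently unless an equicorrelation is requested (used to exercise
correlation pruning); centile order is enforced by sorting within each
record. This surrogate honours marginal locations and spreads but not the
dependence structure of real histogram features — so classifier metrics on
it characterize the *procedures*, not expected clinical performance, and
tests passing on it do not certify behaviour on patient data.

## Problem sizes and runtime choices

The test-suite and acceptance-script workloads are sized for interactive
runs: 50 noise-free parameter sets across the bounds box, a 512-voxel
single-tissue noisy phantom (SNR 60), 100 random ROIs for the feature
oracle, the 48-case reference cohort for LOOCV/KNN/SVM, and a 16-case
end-to-end phantom cohort (one lesion each, ADC features, LOOCV). Larger
grids and cohorts scale linearly and are exercised the same way through
the same functions.

## Known limitations

* DICOM support is a minimal, hand-rolled Explicit-VR-little-endian
  reader/writer sufficient for multi-frame MR series with standard
  (0018,9087) or Siemens private (0019,100C) b-value tags; it is validated
  against an independent DICOM implementation in the tests but is not a
  general-purpose DICOM stack. NIfTI + JSON sidecar is the primary
  interchange format.
* Mask resampling is nearest-neighbour only, by design (binary labels);
  no registration is performed.
* The segmented fit assumes the high-b segment is perfusion-dominated
  noise-free; at very low SNR individual voxels can fail the positivity
  guard during perfusion correction and are then reported from the last
  consistent iterate or flagged rather than extrapolated.
* Single-feature threshold classification inherits the overlap of the
  group distributions; on strongly overlapping cohorts most cases are
  resolved by the (ambiguous) nearest-mean step, which is reported so the
  ambiguity rate is visible.
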