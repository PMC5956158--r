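# ivimcds

Quantitative diffusion-weighted MRI (DWI) decision support for tumor
characterization: parametric map computation, region-of-interest (ROI)
histogram analysis, a self-archiving feature repository, and
benign-vs-malignant classification.

Solid masses — in children especially — are a diagnostic dilemma: neoplastic
and non-neoplastic lesions can look alike on conventional MRI, and the
quantitative diffusion parameters that could help are not available in
routine scanner software. `ivimcds` implements the computational core of
such a decision-support pipeline so every stage can be run, audited, and
tested from code, without patient data: a synthetic phantom generator stands
in for the scanner.

## What it computes

**Parametric maps.** From a multi-b-value DWI series the package computes
the apparent diffusion coefficient between two b-values,

    ADC = ln( S(b_low) / S(b_high) ) / (b_high − b_low)        [mm²/s]

and the intravoxel incoherent motion (IVIM) parameters of the biexponential
signal model

    S(b) = S0 · [ (1 − f) · e^(−b·D)  +  f · e^(−b·(D + D*)) ]

where *D* is the tissue diffusion coefficient, *D\** the pseudo-diffusion
coefficient of capillary perfusion, and *f* the perfusion fraction. Fitting
is segmented — log-linear over the high-b segment for *D*, intercept for
*f*, bounded 1-D least squares for *D\** — and iterated with perfusion
correction of the high-b signals, which makes the noise-free fit exact. A
feasibility check requires at least 4 distinct b-values with 2 on each side
of the 200 s/mm² segmentation threshold before an IVIM fit is attempted.

**ROI features.** First-order histogram features of a masked map: mean,
median, the 2nd–98th centiles, skewness (g1 = m₃/m₂^1.5), kurtosis
(Pearson, m₄/m₂²), and histogram entropy H = −Σ pᵢ log₂ pᵢ over 256
equal-width bins, plus ROI morphology (volume, bounding lengths, center of
mass).

**Repository & decision support.** Features are archived as JSON lines, one
case per row. `group_summary()` gives per-feature group means and SDs;
`compare_case()` reports z-scores and mean ± 1 SD membership of an index
case against the malignant and benign cohorts.

**Classification.**
* a 2-step threshold rule on a single feature (assign by mean ± 1 SD
  interval membership; resolve "inside both / inside neither" by nearest
  group mean, flagged ambiguous), evaluated by leave-one-out
  cross-validation (LOOCV);
* SMOTE-balanced k-nearest-neighbor and radial-basis SVM classifiers under
  stratified 10-fold cross-validation with probability-based ambiguity
  flags (winning probability in (0.5, 0.8]);
* Mann-Whitney U feature selection with Bonferroni correction and optional
  correlation pruning; ROC/AUC; net reclassification improvement (NRI).

## Worked example

```r
library(ivimcds)

# digital phantom: 32x32x8 grid, 6 b-values x 3 directions, SNR 60 at b0,
# one "malignant" lesion (restricted diffusion) in soft-tissue background
ph  <- generate_phantom(phantom_spec(), seed = 1)
roi <- ph$rois$lesion1_malignant
adc <- map_in_reporting_units(compute_adc_map(ph$dwi))  # 1e-6 mm^2/s

vals <- extract_roi_values(adc, roi)
fv   <- compute_features(vals, voxel_volume_mm3 = prod(adc$spacing))
round(unlist(fv[c("mean", "median", "c15", "c75", "kurtosis", "entropy")]), 3)
#>     mean   median      c15      c75 kurtosis  entropy
#>  882.500  881.684  858.126  899.490    2.584    7.359
```

The lesion's ADC mean of ~883 ×10⁻⁶ mm²/s reflects its restricted
diffusion (tissue D = 0.8 ×10⁻³ mm²/s plus a perfusion contribution).
Comparing this index case against a synthetic 48-case reference cohort
(37 malignant / 11 benign, drawn from published group statistics):

```r
repo <- feature_repository(generate_feature_cohort(seed = 2))
compare_case(repo, fv, "ADC", features = c("mean", "kurtosis", "entropy"))
#>    feature     group  n    mean       sd  value      z within_1sd
#> 1     mean malignant 37 1030.45 300.8359 882.50 -0.492       TRUE
#> 4     mean    benign 11 1698.17 463.5932 882.50 -1.759      FALSE
#> ...
```

The case sits inside the malignant mean ± 1 SD band for ADC mean and
entropy but outside both benign bands — the pattern the threshold
classifier formalizes. Cross-validated over the whole cohort:

```r
loocv_threshold(query_records(repo, map_kind = "ADC"), "entropy")
#> <cv_metrics LOOCV> n=48  sens=0.730  spec=0.455  acc=0.667  bal.acc=0.592  ambiguous=39

model_cv(query_records(repo, map_kind = "ADC"), "KNN", folds = 10, seed = 11)
#> <cv_metrics 10-fold> n=48  sens=1.000  spec=0.909  acc=0.979  bal.acc=0.955  AUC=0.955  ambiguous=1
```

Single-feature thresholds on this overlapping synthetic cohort are modest,
while the multivariate KNN with SMOTE balancing separates it almost
perfectly; `ambiguous` counts the cases the respective rule could not call
confidently.

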