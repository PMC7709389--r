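---
title: "Methods: PLS calibration of an NMR extended lipid panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PLS calibration of an NMR extended lipid panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmrelp)
```

## The measurement problem

A serum proton NMR spectrum contains, between about 0.5 and 1.6 ppm, the
overlapping methyl (CH₃) and methylene (CH₂) resonances of every lipid
carried by every lipoprotein particle in the sample. No single peak
corresponds to "cholesterol" or "triglyceride": the analyte information is
distributed across the whole envelope, modulated by particle size and lipid
composition. The package therefore treats the fixed 1600-point window from
1.592 down to 0.494 ppm as a multivariate predictor and calibrates each
analyte — total cholesterol (TC), triglycerides (TG), HDL cholesterol
(HDL-C) and apolipoprotein B (apoB) — by partial least squares regression
with a single response (PLS1) against reference concentrations.

The canonical grid is fully determined by its endpoints and point count:
both endpoints inclusive, spacing (1.592 − 0.494)/1599 ppm, stored in
descending ppm (the NMR display convention; ascending input files are
reversed on read). Off-grid spectra are resampled by linear interpolation
only — no apodization, phasing, baseline correction or intensity
normalization is applied, because the assay assumes a fixed, standardized
acquisition upstream and any per-spectrum rescaling would destroy the
concentration information the regression relies on.

## The calibration model

For a training set of n spectra (rows of X, 1600 columns) and reference
concentrations y, the model is mean-centered NIPALS PLS1. Variables are not
autoscaled: all 1600 predictors share one intensity unit, and per-variable
scaling would inflate baseline noise regions. Each latent variable is the
direction of maximal covariance with the current response residual
(`w = X'y/|X'y|`, non-iterative for a single response); scores are
re-orthogonalized against earlier components, a numerical no-op that keeps
high component counts faithful. The regression form
`b = W (P'W)⁻¹ q` reproduces the fitted values of the nested model, and a
prediction is `ȳ + (x − x̄)·b`, so the training-mean spectrum predicts the
training-mean concentration exactly.

### Choosing the number of latent variables

The component count A is the global minimizer of the leave-one-out
cross-validation error

RMSE_CV(A) = sqrt( (1/n) Σᵢ (eᵢ − pᵢ(A))² ),

where pᵢ(A) is the prediction of sample i by the A-component model trained
without it. Ties break toward fewer components; a minimum sitting at the
search bound triggers a warning that the bound (default A_max = 40,
spec-scale runs here use 15–20) may be too small. One decomposition per
fold serves every A, because NIPALS components are nested; the default
implementation additionally advances all n folds together in sample
(Gram-matrix) space using response-only deflation and the weight recursion
r_a = w_a − Σⱼ (pⱼ'w_a) rⱼ, which leaves the Gram matrix fixed so each
component costs two n×n matrix products for all folds at once. This is
algebra, not approximation: the test suite pins the batched path to the
per-fold NIPALS path and to brute-force per-component refitting at 1e-10.

### Outlier screening

Reference values come from independent chemical analysis and occasionally
carry gross errors that would bias the calibration. After the first LOOCV
selection, each training sample is scored by DFFITS in latent-variable
space: with the scores T of the full fit (plus intercept) as the design,
leverage hᵢᵢ = 1/n + tᵢ(T'T)⁻¹tᵢ', deleted residual scale s₍ᵢ₎, and

dffits_i = (ŷᵢ − ŷ₍ᵢ₎,ᵢ) / (s₍ᵢ₎ √hᵢᵢ).

Samples beyond the conventional cutoff 2√((A+1)/n) are removed in a single
pass — no iterative re-screening — and LOOCV selection and the final fit
are re-run on the reduced set. The cutoff is deliberately conventional and
configurable; on noisy data it flags a few percent of benign samples
(the price of catching genuine reference errors), on noiseless data none.
Whether component selection should be repeated after removal is a genuinely
open design point; this package re-runs it and records both selections in
the model diagnostics.

## Assay logic

A deployed panel bundles five models. HDL-C gets two: sera with high TG
carry cholesterol-poor HDL particles whose spectral signature differs
enough that a single calibration underperforms at low HDL-C. The bundle
routes each sample by its own PLS-predicted TG — model 1 below 250 mg/dL,
model 2 at or above (the ≥ boundary follows the subset definition of the
high-TG training stratum). Routing always uses the uncensored TG
prediction. The hard switch creates a potential discontinuity for samples
near 250 mg/dL; `routing_audit()` logs both models' predictions in a ±2
mg/dL band as a diagnostic, without imposing a requirement.

Derived quantities: non-HDL-C = TC − HDL-C, and LDL-C by the NIH (Sampson)
equation with constants 0.948, 0.971, 8.56, 2140, 16100, 9.44. Both are
computed from unrounded predictions; displays round to one decimal, half
away from zero. Reportable ranges censor TC outside 66–868, TG 35–950,
HDL-C 14–152 and apoB 35–366 mg/dL to `"<low"`/`">high"` strings (negative
predictions count as below-range). LDL-C and non-HDL-C have no published
bounds, so they are reported uncensored but suppressed whenever an input
analyte is censored — fabricating bounds would be worse than suppression.
The Sampson equation's own validation ceiling for TG is not restated here;
TG above 800 mg/dL triggers a logged warning rather than a hard cutoff.

## The synthetic population generator

Because no spectra are distributed with the package, a generator stands in
for the patient population. It is deliberately structural, not physical:

- **Nine subclasses** (V1–V3, L1–L3, H1–H3; large→small VLDL, LDL, HDL),
  each with cholesterol/triglyceride/apoB composition coefficients (mg/dL
  per concentration unit; apoB zero for HDL) and a CH₃/CH₂ Lorentzian line
  pair whose centers grade with particle size. Nine components is the
  minimal structure that makes HDL-C separable from TC and apoB separable
  from total lipid — fewer would make the inverse problem trivial.
- **Ground truth by construction**: TC, TG, HDL-C and apoB are exact linear
  functionals of the subclass concentrations, so every generated sample
  carries recomputable truths (a conservation property the tests enforce
  bitwise).
- **Population model**: correlated log-normal concentrations (within-class
  correlation 0.70–0.75, VLDL–HDL correlation −0.40 so
  hypertriglyceridemia depletes HDL), plus an explicit 15% Bernoulli
  hypertriglyceridemic stratum whose VLDL log-means shift up and which is
  constrained by rejection to TG ≥ 250 mg/dL (non-members < 250). The
  stratum indicator therefore is the TG ≥ 250 event, and the generated
  fraction is exactly binomial around 0.15. Composition and distribution
  defaults were calibrated once so that a 5000-sample draw has analyte
  means within 15% of a clinical serum population (TC 181, TG 127, HDL-C
  54, apoB 94 mg/dL) and 1st–99th percentile spans inside the population
  ranges (TC 64–476, TG 24–886, HDL-C 14–167, apoB 35–305); they ship as
  config data, not code constants.
- **Rendering**: Lorentzian lines only — their closed-form areas
  (height·π·γ, truncated by arctangents at the axis ends) give exact
  oracles for the renderer tests. Sharp nuisance doublets for lactate
  (1.33 ppm) and alanine (1.48 ppm) and a branched-chain amino-acid
  multiplet cluster (0.90–1.05 ppm) vary log-normally per sample and are
  uncorrelated with the analytes; a fixed quadratic baseline; Normal ppm
  jitter (SD 0.002 ppm) on every line center; Gaussian noise at 0.5% of
  the sample's median line height. Spectra span 0.40–1.70 ppm at 4096
  points (≈2.2× canonical resolution). Each sample stores a render seed
  drawn under the population seed, so spectra are lazy but bitwise
  reproducible.

What the generator does **not** emulate: real lineshape physics (no
Gaussian/Voigt broadening, no field or temperature dependence), matrix
differences between serum and plasma, chemical-shift prediction, or the
continuous size distribution of real lipoproteins. Passing tests therefore
demonstrate that the pipeline recovers analytes from spectra whose
information content is genuinely distributed and nuisance-contaminated —
not that the calibration would transfer to a different spectrometer or
population. The noise and jitter defaults make recovery non-trivial but
leave held-out correlations around 0.999 at n = 800; real patient sera,
with biological composition variability the generator cannot represent,
yield the 0.98–0.997 range reported for assays of this design.

## Numerical choices and degenerate inputs

- Rank exhaustion in NIPALS is detected at 1e-24 relative scale — loose
  enough that genuine tiny components near full rank are kept (full-rank
  PLS then matches least squares to 1e-8), tight enough that exactly
  collinear data stops cleanly; LOO predictions carry the last valid
  component forward past the rank.
- Constant response or constant predictors raise degenerate-model errors;
  deletion diagnostics require n > A + 2; outlier removal that leaves
  fewer than A + 3 samples aborts training.
- A perfectly interpolating fit reports all-zero DFFITS (no influence
  signal exists) rather than 0/0.
- Deming regression (λ = 1 closed form) refuses zero-variance comparators
  and uncorrelated data, where the orthogonal fit's slope sign is
  undefined.
- The LOQ rule — lowest dilution level with replicate CV ≤ 20% and mean ≥
  LOD — is an explicit package choice where the source convention is
  unstated; LOB/LOD use the one-sided 95% normal quantile 1.645.
- Interference flags strictly above 10% change; stability accepts up to
  and including ±10% — the two rules mirror the differing verb phrasing
  of their protocols ("elicited > 10% change" vs "falling within ±10%").
- Within-lab precision is the total SD over all replicates of a pool, not
  a variance-components decomposition: the reported quantity is mean/SD/CV
  per pool, and a components breakdown is out of scope.
- Training-set stratification for the two HDL-C models uses the chemical
  (reference) TG, while deployment routing uses the NMR-predicted TG; the
  asymmetry is intentional — reference TG is the better label at training
  time, but the deployed assay only has its own prediction.

## Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen as
the package's own defaults: 1000-sample populations (800 train / 200 test,
A_max = 20) for calibration recovery, 100-sample noiseless sets for
outlier-removal and parameter-recovery checks, n ≤ 25 instances for the
brute-force equivalence properties, and 5000 concentration-only draws for
population realism. A full calibration at n = 800 takes seconds with the
batched LOO path.

## Known limitations

Single-response PLS only (no PLS2, kernel or sparse variants); no
prediction uncertainty intervals; JCAMP-DX support covers plain AFFN
`(X++(Y..Y))` tables only; the DFFITS screen is single-pass by design and
will not catch masked outlier pairs; the generator's realism claims extend
only to the marginal analyte distributions it was calibrated against.
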