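---
title: "Methods: IVIM-based nuclear grading of renal tumors with venous thrombus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: IVIM-based nuclear grading of renal tumors with venous thrombus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivimgrade)
```

## The problem

Clear cell renal cell carcinoma (ccRCC) with venous tumor thrombus is
resected through a complex, morbidity-prone operation, and patients whose
tumors carry a high WHO/ISUP nuclear grade (3–4) have markedly worse
progression-free survival (PFS) than low-grade (1–2) patients. A
preoperative grade estimate from diffusion MRI plus routine laboratory
values can therefore inform the choice between immediate surgery and
neoadjuvant therapy. `ivimgrade` implements that analysis chain end to end
and, because no patient data accompany it, ships generators for digital
diffusion phantoms and synthetic cohorts that stand in for the clinical
inputs at every stage.

## Signal model and voxel-wise fitting

The intravoxel incoherent motion (IVIM) model decomposes the
diffusion-weighted signal of a voxel into a slowly decaying tissue
compartment and a fast pseudo-diffusion compartment fed by capillary
microcirculation:

$$S(b) = S(0)\left[f\,e^{-b D_p} + (1-f)\,e^{-b D_t}\right],$$

with $D_t$ the true (tissue) diffusion coefficient, $D_p \ge D_t$ the
pseudo-diffusion coefficient, and $f \in [0,1)$ the perfusion fraction at
$b = 0$. The acquisition protocol modeled throughout uses
$b = 0, 20, 50, 100, 150, 200, 400, 600, 800$ s/mm² with
NEX $= 1,2,2,2,2,2,4,4,4$ excitations per $b$.

Fitting is *segmented*, the standard two-step protocol for this model:

1. **$D_t$** from the exact two-point log-linear slope between $b = 400$
   and $b = 800$ s/mm², $D_t = \ln(S_{400}/S_{800})/400$, where the
   perfusion compartment has decayed to numerical irrelevance. Two points
   determine the line, so "linear least squares on two b-values" is this
   closed form.
2. **$(S_0, f, D_p)$** from a bounded Levenberg–Marquardt least-squares fit
   of the full bi-exponential over all nine $b$-values with $D_t$ held
   fixed.

The apparent diffusion coefficient (ADC) is estimated separately as the
log-linear least-squares slope over the entire $b$ range; perfusion
inflates it above $D_t$, which is exactly why the IVIM decomposition is
informative.

### Numerical choices

* **Bounds** (the fitted literature rarely states them; these are standard
  physiological boxes that keep the optimizer off the degenerate
  $D_p \approx D_t$ ridge): $D_t \in (10^{-6}, 3\times10^{-3}]$ mm²/s,
  $D_p \in [3\times10^{-3}, 0.5]$ mm²/s, $f \in [0, 1)$,
  $S_0 \in (0, 2\,S(0)_{\text{measured}}]$.
* **Initialization**: $S_0^{(0)} = S(0)_{\text{measured}}$;
  $f^{(0)} = \mathrm{clamp}\!\left(1 - e^{\text{high-b intercept}}/S(0),
  0.01, 0.5\right)$ from the $b$-0 deficit of the high-b line;
  $D_p^{(0)} = 10\,D_t$, clamped into bounds.
* **Non-convergence policy**: a voxel whose optimizer fails, or whose
  signals are non-positive, or whose two-point $D_t$ leaves $(0, 3\times
  10^{-3}]$, is marked *invalid* rather than clamped, and is excluded from
  all downstream statistics. Clamping would pile estimates on the bounds
  and bias ROI means.
* **Units**: diffusion coefficients are mm²/s internally; every tabular
  interface (`tidy()`, ROI features, thresholds) reports the conventional
  $\times 10^{-3}$ mm²/s.
* No spatial regularization or denoising is applied anywhere.

## The digital phantom

`phantom_spec()` defines a 64×64×10 grid at 1.484 mm in-plane (38 cm field
of view over a 256 matrix) and 5 mm slices, holding an ellipsoidal "tumor"
(default radii 10×10×3 voxels, about 1230 voxels) in a background
compartment. Defaults place tumor ground truth at $D_t = 1.0\times10^{-3}$
mm²/s, $D_p = 20\times10^{-3}$ mm²/s, $f = 0.30$, $S_0 = 1000$ — magnitudes
matching the renal-tumor ROI summaries the workflow ultimately feeds on —
and each parameter may instead be a range, drawn uniformly per voxel.

Noise is Rician, the physics of magnitude MRI: each excitation observes
$\left|S + \sigma(Z_1 + iZ_2)\right|$ with independent standard normal
$Z_1, Z_2$, and the recorded signal per $b$ is the mean of its NEX
magnitude draws. The acquisition protocol does not state an SNR, so the
default $\sigma = 20$ gives $b$-0 tumor SNR 50, a realistic abdominal
figure, and is configurable. At that SNR the magnitude average at $b = 0$
sits within 1% of $S_0$, and median voxel-wise recovery biases on the
default phantom are a fraction of a percent for ADC and $D_t$ and well
under 0.01 absolute for $f$ (the test suite and the acceptance script
recompute these).

The phantom does **not** emulate respiratory motion, eddy currents, coil
sensitivity profiles, partial-volume mixtures, or spatially correlated
noise. Passing recovery tests on it therefore certifies the estimator
chain — not robustness to the artifacts of free-breathing abdominal DWI.

## ROI protocols

Clinical readers drew regions manually; the package substitutes two
deterministic surrogates so results are reproducible:

* **ROI_largest**: the axial slice with the maximal in-mask voxel count
  (ties to the lower index) and its two neighbors; at a volume edge the
  available one or two slices are used with a warning. The feature is the
  unweighted mean of the per-slice means.
* **ROI_low**: three non-overlapping circles of fixed 50 mm² physical
  area, placed greedily — among all candidate centers whose circle lies
  fully in-mask and off already-used voxels, take the circle with minimal
  mean ADC; remove its voxels; repeat. Circles are two-dimensional and are
  searched over all slices, since the lowest-ADC focus may sit on any
  section. The feature is the unweighted mean of the three circle means.

A circle's voxel set is the $k = \mathrm{round}(50/\text{pixel area})$
in-plane offsets nearest its center in physical distance (deterministic
tie-break by distance, then offset). With 1.484 mm pixels this gives 23
voxels = 50.4 mm². A plain center-within-radius rule at
$r = \sqrt{50/\pi} \approx 3.99$ mm was rejected because voxelization then
yields 21 voxels = 46.0 mm², violating the fixed-area contract by nearly
two pixel areas; the nearest-$k$ rule keeps the realized area within one
pixel of nominal by construction.

The voxel sets selected on the ADC map are copied identically to the
$D_t$, $D_p$ and $f$ maps, and invalid voxels are excluded from means.
`average_readers()` averages two readers' feature vectors element-wise,
mirroring two-radiologist consensus practice.

## The synthetic cohort

`cohort_spec()` draws a cohort of (default) 105 patients with high-grade
prevalence 69/105. Each feature is generated from its grade-conditional
law in `default_feature_rules()`: the probability that the feature exceeds
its clinical threshold, conditional on grade, equals the corresponding
conditional proportion of the 36-low/69-high training population
(e.g. platelet count ≥ 178×10⁹/L: 21/36 in low grade, 60/69 in high
grade). Continuous features are drawn from grade-conditional log-normals —
positive-valued and right-skewed like real laboratory measurements — with
the location parameter solved so the threshold-exceedance probability is
exact: $\mu = \log(\text{thr}) - s\,\Phi^{-1}(1-p)$ at shape $s$. The
shapes are fixed, plausible coefficients of variation (0.10–0.40 by
measurement type) and only move values around the threshold, not the
exceedance probability itself.

PFS is exponential per grade with medians 33.9 (low) and 13.2 (high)
months; censoring times are independent exponentials with rate
$c/(1-c)$ times the event rate, so the expected censored fraction is
exactly $c$ (default 0.3, a typical 3-year-follow-up figure; the sources
of these defaults report medians only, not censoring).

Importantly, features are generated *independently given grade*. The
generator reproduces the marginal, grade-conditional structure of the
tables, not the unpublished patient-level correlations. Two consequences:

* cohort-level composite metrics (model AUC, calibration $\chi^2$,
  survival log-rank $p$ of predicted groups) are **not** expected to match
  the source population's values, and the package does not claim them;
* the published equation applied verbatim to this cohort performs poorly,
  because its platelet and lymphocyte coefficient signs oppose those
  features' marginal directions in the tables — an ambiguity of the
  source's variable coding that the package surfaces rather than repairs.
  The equation is kept verbatim; the coding is exposed through the model
  object for users who wish to flip it.

A global seed fans out to fixed per-stage child streams (grade labels,
each feature, survival, noise), so any stage can be regenerated
independently and whole runs are bit-reproducible.

## Feature screening and the grade model

* **Youden dichotomization** scans midpoints between consecutive sorted
  unique values plus $\pm\infty$, in both coding directions, and maximizes
  $J = \text{sensitivity} + \text{specificity} - 1$; ties break toward the
  smaller cut, then toward "≥ is positive". Midpoint placement and the tie
  rule are implementation choices (the criterion itself does not fix
  them); a constant feature returns $J = 0$ at the constant with a
  warning.
* **2×2 diagnostics** use the defining ratios with Clopper–Pearson exact
  95% intervals (the printed intervals' method is unstated; exact
  intervals are the conservative default), and the AUC of a binary
  predictor is $(\text{sens}+\text{spec})/2$ with a DeLong-type variance.
* **Group comparisons**: Shapiro–Wilk gates Student's $t$ (equal-variance)
  versus Mann–Whitney for continuous features; categorical tables use
  Pearson $\chi^2$ without continuity correction, switching to Fisher's
  exact test when any expected cell is below 5. The uncorrected $\chi^2$
  convention is what reproduces the platelet table's $p = 0.001$ from its
  counts.
* **Backward selection** refits by maximum likelihood and removes, at each
  step, the variable with the largest likelihood-ratio removal $p$ while
  that $p \ge 0.10$ — the conventional backward-LR default, since the
  method name alone does not fix the threshold.
* The **score cutoff 1.12** is interpreted on the linear predictor $Y$
  (it exceeds 1, so it cannot be a probability); classification is
  $Y \ge 1.12 \Rightarrow$ high grade.
* The **nomogram** gives the largest $|\beta|$ 100 points, scores each
  variable's least favorable level as 0 points, and maps total points back
  to probability through the logistic inverse; the round-trip is exact to
  machine precision over all 32 indicator combinations.
* Missing laboratory values are median-imputed, with per-column counts
  logged — appropriate at the sub-1% missingness the workflow assumes, and
  not a general-purpose imputation strategy.

## Survival and agreement

Kaplan–Meier estimation and the two-group log-rank test are delegated to
the `survival` package (the field standard), wrapped to return tidy curves
with Greenwood variances and the median as the smallest $t$ with
$S(t) \le 0.5$; hand product-limit computation serves as the independent
oracle in the tests, not as the implementation. Inter-reader agreement
uses ICC(2,1) — two-way random effects, absolute agreement, single
measure — because reader identity is best treated as a random sample of
raters and systematic reader offsets should count against agreement; a
consistency variant is available. Cohen's kappa is unweighted, with the
conventional interpretation bands (≤0.20 slight through >0.80 excellent);
the degenerate case of two identical constant raters is defined as
$\kappa = 1$ with a warning.

## Problem sizes used by the tests

The test suite and acceptance script run: the full 64×64×10 phantom
(≈1230 tumor voxels) at SNR 50 for map recovery; 50 random noiseless
voxels against a dense $(f, D_p)$ grid-search oracle with closed-form
$S_0$; 100 random instances ($n \le 30$) for Youden-vs-exhaustive
equivalence; 20 cohorts of $n = 2000$ for backward-selection recovery of
the five-variable generating model; 200 replicates of $n = 300$ per group
for log-rank power at the 33.9- versus 13.2-month medians; and $n = 10^5$
draws for law-of-large-numbers checks of the cohort generator. These sizes
make each stochastic check decisive (multiple-sigma margins) while keeping
a full run in the tens of seconds.

## Known limitations

* The ROI surrogates are deterministic stand-ins for manual segmentation;
  they reproduce the *protocol*, not reader variability.
* No tri-exponential, kurtosis or Bayesian IVIM variants; no motion
  correction; no DICOM ingestion; no Cox modelling or competing risks.
* The synthetic cohort's independence-given-grade structure bounds what
  any downstream multivariable result on it can say about real patients
  (see above).
* Median-survival confidence intervals are not produced; the source
  material mixes "95% CI" and "range" wording for those intervals, so
  curves and point medians are reported instead.
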