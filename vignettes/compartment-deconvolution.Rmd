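---
title: "Compartment deconvolution of HR-MAS NMR breast-tissue profiles: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compartment deconvolution of HR-MAS NMR breast-tissue profiles: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Specimens excised during breast-conserving surgery are histological
mixtures: cancer cells, intratumoral fibrotic stroma, extratumoral fibrous
connective tissue, fat, glandular tissue, immune infiltrate and necrosis.
A bulk ^1^H HR-MAS NMR spectrum of such a specimen therefore reports a
composition-weighted average of the compartments' metabolic profiles. This
package implements the analysis chain that turns per-specimen spectra plus
post-measurement histology into compartment-level inference:

1. **Quantitation** — chemical-shift calibration against the formate
   reference (8.44 ppm), baseline correction, integration of curated
   spectral regions, and nonlinear deconvolution of the crowded
   3.0–3.3 ppm choline region.
2. **Multivariate modelling** — PCA for structure discovery and sample
   splitting; OPLS-DA for malignant-vs-normal classification with external
   validation; OPLS regression of the cancer-cell fraction on the profile
   (R²X, R²Y, sevenfold Q², CV-ANOVA, VIP, pcorr(1)).
3. **Purity deconvolution** — per-metabolite ordinary least squares against
   the cancer-cell percentage in specimens composed almost entirely of
   cancer plus intratumoral fibrosis; the intercept (0% cancer) estimates
   the pure-stroma level and the value at 100% the pure-cancer level, each
   with mean-response confidence bands; verdicts against a fat-adjusted
   extratumoral connective-tissue reference follow a two-level
   confidence-interval overlap rule.

Because the underlying patient data are not publicly deposited, the package
ships a seeded synthetic-data generator whose outputs have the statistical
shape the analysis assumes; every stage is exercised and tested against it.

## The synthetic cohort generator

`generate_cohort()` draws 140 specimens over five excision areas (38 tumor,
11 tumor border, 26/30/35 normal-appearing at <1 cm, =1 cm, >1 cm from the
border) for 39 patients. Design choices:

* **Compositions.** Each location has its own sampler calibrated so the
  marginal medians (and approximately the quartiles) of the seven tissue
  classes match the emulated cohort's composition statistics — e.g. tumor
  specimens have median 30% cancer cells (quartiles 10/40%) and median 70%
  fibrotic stroma, and specimens beyond 1 cm never contain cancer cells.
  Tumor-adjacent locations cannot be matched by any unimodal law (their
  marginal medians sum to far less than 100%), so they are mixtures of
  specimen *archetypes* (tumor-tissue, fatty, connective-dominant, mixed);
  the archetype weights were chosen to reproduce the marginal medians.
  Quantile laws are piecewise linear through (min, Q1, median, Q3, max);
  classes whose quartiles are all zero use a sparse power-tail law.
  Fractions are percentages summing to exactly 100 per specimen.
* **Weights** are Normal(13.8, 2.8) mg truncated at 5 mg by resampling.
* **Clinical covariates** (grade I/II/III/missing 11:21:6:1, subtype
  luminal A / luminal B HER2− / luminal B HER2+ / HER2 / TNBC
  22:11:3:1:2) are drawn per patient; specimens are assigned to patients
  independently of location because the per-patient sampling plan is not
  part of the emulated design.
* **Metabolite levels.** `mix_samples()` applies the linear two-(or more)
  compartment mixing model: `level = (Σ_c fraction_c · s_{c,m}) · exp(ε)`,
  with compartment signatures `s` (integral units per mg) from
  `default_signatures()`, grade II/III modifiers multiplying the
  cancer-compartment levels of lactate, taurine, phosphoethanolamine,
  glycine, glutamate and creatine, and multiplicative log-normal noise
  with `σ² = log(1 + cv²)`. The default `noise_cv = 0.2` was chosen once
  as realistic for intact-tissue region integrals: it yields
  purity-metabolite Pearson correlations of roughly 0.4–0.8 and a
  cross-validated predicted-vs-true purity correlation near 0.8 on the
  default cohort, the regime the analysis is designed for. The signature
  values themselves are editable defaults (cancer-enriched small
  metabolites, glucose depletion in cancer, lipid-dominated fat), not
  measured reference values.
* The log-normal noise choice matches the downstream log-transformation
  step; with `noise_cv = 0` mixing is an exact convex combination, which
  the identifiability tests exploit.

What the generator does **not** emulate: acquisition physics (relaxation,
diffusion editing, shimming artefacts), patient-level correlation between
specimens, peak-overlap structure outside the choline region, and
2D-spectrum information. Passing tests therefore demonstrate correctness of
the statistical machinery under the stated mixing model, not performance on
real spectra.

## Spectrum synthesis and quantitation

`synthesize_spectrum()` builds frequency-domain spectra as sums of
unit-area Lorentzians (`halfwidth` = HWHM, default 0.005 ppm) at
representative chemical shifts, one resonance per quantified variable, plus
the formate singlet and an optional polyethylene-glycol contaminant at
3.70 ppm. CPMG (small metabolites) and DIFF (lipid) channels are emulated
as two variable blocks, not pulse sequences. Axes are stored descending
(NMR convention); quadrature uses ascending copies.

* `calibrate_shift()` translates the axis so the tallest peak in the
  search window (default 8.24–8.64 ppm) lands on 8.44 ppm; a peak must
  exceed 5× the median absolute intensity of the window, otherwise the
  reference is declared missing. The operation is idempotent.
* `baseline_correct()` subtracts a piecewise-linear baseline through the
  medians of signal-free anchor regions, with constant extrapolation
  beyond the outermost anchors.
* `integrate_regions()` uses trapezoidal quadrature with linear
  interpolation at region boundaries. Default regions span ±2 halfwidths
  around each assigned shift — a deliberate relative-quantitation choice
  (capturing `(2/π)·atan(2) ≈ 70.5%` of an isolated Lorentzian's area)
  that keeps neighbouring resonances out; the region table is a plain
  data frame and fully overridable, since curated boundary tables differ
  between studies.
* `fit_choline_region()` resolves choline, phosphocholine and
  glycerophosphocholine by bounded Levenberg–Marquardt least squares
  (`minpack.lm`) on a sum of *power Lorentzians*
  `A·[γ²/(γ² + (x−c)²)]^m` with shape exponent `m ∈ [1, 2]` — our
  concrete reading of a "generalized Lorentzian line-shape", whose area
  has the closed form `A·γ·B(m−½, ½)`. Starting centers are the known
  shifts; up to five perturbed restarts are attempted and the best
  residual kept. An all-zero region short-circuits to zero areas.
* `log_and_uv_scale()` operationalizes "log-transform if required" as:
  log any variable whose sample skewness exceeds 1.0 (moment estimator),
  then mean-center and scale all columns to unit variance. The flags,
  centers and scales are stored so `apply_scaling()` projects held-out
  samples into the training model space exactly.

## The multivariate engine

`opls_fit()` implements orthogonal projections to latent structures with
one predictive component in the Trygg–Wold form: for each orthogonal
component, `w ∝ X'y`, `p = X't/t't`, `w_orth ∝ p − (w'p)w`, scores and
loadings of the orthogonal component are computed and the component removed
from X; the predictive component is refitted on the filtered matrix. Two
construction guarantees are tested: `t(1) ⟂ to(1)` (exact, because the
filtered matrix annihilates `to`) and `w_orth ⟂ w`. With zero orthogonal
components the fit reproduces one-component NIPALS PLS to 1e−8, which the
test suite checks against an independently coded oracle.

* **Cross-validation.** `cross_validate()` computes `Q² = 1 − PRESS/SSY`
  with seeded, class-stratified sevenfold assignment; centering and
  scaling are re-estimated inside every training fold by default (the
  alternative, reusing the full-data scaling, and the deterministic
  "every 7th sample" interleaved assignment are exposed as options, since
  commercial chemometrics software does not document a unique rule). A
  fold whose training part would lose a class is re-drawn, with a message.
* **CV-ANOVA.** `cv_anova()` uses
  `F = ((SSY − PRESS)/df1) / (PRESS/df2)` with `df1` = number of fitted
  latent components and `df2 = n − 1 − df1`, upper-tail F p value, and
  `p = 1` whenever PRESS ≥ SSY. Note the test is *conservative by
  construction*: under a true null the cross-validated PRESS exceeds SSY
  for the vast majority of fits, so the realized type-I error is far
  below the nominal level — the coverage suite measures approximately
  0.01 at n = 60 rather than 0.05. It should be read as a safeguard
  against over-interpreting weak models, not as a calibrated test.
* **VIP and pcorr.** With a single predictive component VIP reduces to
  `√K·|w_j|/‖w‖` (mean VIP² = 1 exactly) and ranks variables identically
  to |w|; `pcorr()` reports the Pearson correlation between t(1) and each
  scaled variable.
* **Classification.** `oplsda_fit()` centers a class dummy, orients the
  positive class to positive t(1), and thresholds predicted scores at the
  midpoint of the class-mean scores; a score exactly on the threshold is
  assigned to the positive (cancer) class — the conservative choice for
  margin screening.
* **Score-plane splitting.** `split_by_score_plane()` tiles the
  t(1)–t(2) plane into a 4×4 marginal-quantile grid and allocates a total
  test quota of `⌈fraction·n⌉` across occupied cells by largest-remainder
  rounding, stratified by group inside each cell. Allocating the *total*
  (rather than ceiling per cell) keeps the realized test fraction at its
  nominal value while still spreading the test set over the plane; a
  per-cell ceiling would inflate a 20% request to ≈ n/cells extra
  samples.

## Purity deconvolution

`fit_purity_regression()` is ordinary least squares of level on cancer-cell
percentage (purity is carried in percent throughout), with Pearson r and
its two-sided p, and `predict.lm` mean-response intervals at the probe
points 0/60/100%. Choices that were genuinely open:

* **Confidence vs prediction bands.** Mean-response (confidence) bands are
  the default — the quantity of interest is the *mean* level of the pure
  compartment, and figures of this analysis type conventionally show confidence
  bands — with prediction intervals available via the `interval` argument.
* **Outlier rule.** A point is dropped only when it is extreme on *both*
  diagnostics (|standardized residual| > 3 and Cook's distance > 1,
  configurable); requiring both mirrors the documented exclusion of a
  single point with diagnostics (4.5, 2.6) and avoids discarding
  high-leverage but well-fitting points. Removal refits and records the
  excluded ids with their diagnostics; removal is refused when fewer than
  5 points would remain.
* **Fat adjustment.** Extratumoral connective-tissue reference specimens
  carry non-zero fat; `adjust_for_fat()` fits level ~ fat% on the two
  distant normal locations and subtracts `slope · fat%` from each
  reference sample (projection to 0% fat). A calibration fat range under
  10 percentage points triggers an explicit extrapolation warning.
* **Verdicts.** `compare_compartments()` declares `significant` when the
  95% intervals (regression band at 0% vs t-interval on the adjusted
  reference mean) are disjoint and `trend` when only the 90% intervals
  are; `grade_contrast()` applies the same two-level rule to the
  mean-response intervals of two per-grade fits at 60% purity, returning
  `insufficient` below 5 samples per group. CI-overlap is known to be
  conservative relative to a two-sample test at the same level; it is
  used here because it is the rule the analysis design prescribes.
* **Subtype slopes.** `homogeneity_of_slopes()` is the standard
  interaction F test (separate-slopes vs common-slope linear models);
  its type-I error is nominal (checked at 0.05 ± 0.03 over 500 null
  replicates).
* **Contamination.** Samples whose PEG-region integral exceeds 5× the
  cohort median are excluded from the succinate and glutamate regressions,
  with logging.
* Extrapolation to 0%/100% is out-of-support for most datasets; every
  regression row carries the observed purity range so reports can show
  extrapolated values in context.

A property worth knowing when simulating: under multiplicative
(level-proportional) noise the residual spread grows with purity, so the
homoscedastic mean-response interval at the 0% extrapolation point is
conservative — the coverage suite measures ≈ 97–98% empirical coverage for
a nominal 95% interval at noise cv = 0.05. The interval never undercovers
under the mixing model; the package reports it as specified rather than
reweighting, because the real analysis has no access to the noise law.

## Numerical and degenerate-input conventions

Zero-variance responses, single-class labels, constant purity, empty
anchors, regions outside the axis, missing compartment signatures and
missing variables at prediction all raise errors naming the offending
object. Flat spectra fail calibration with "reference peak not found".
Ties at the class threshold go to the positive class. All seeds are
explicit function arguments; identical seeds give bit-identical cohorts,
spectra, fold assignments and pipeline output files.

## Problem sizes used by the test suite

The suite exercises the stages at deliberately modest sizes chosen to make
the statistical assertions sharp but cheap: 1000 replicate cohorts for
generator fidelity, 1000 replicates of n = 39 for interval coverage, 500
null replicates each for the CV-ANOVA and homogeneity-of-slopes
calibration checks, 200 label permutations for the Q² null, and the
140-specimen default cohort for the end-to-end run. The full suite runs in
well under a minute on one CPU.

## Known limitations

* One predictive component only, binary discriminant contrasts only.
* The generator's compartment signatures are plausible defaults, not
  estimates; absolute levels in its output have no physical units beyond
  "integral per mg".
* No multiple-testing correction is applied across metabolites in the
  univariate stage — deliberately, to mirror the emulated analysis; treat
  per-metabolite p values accordingly.
* CV-ANOVA conservativeness (above) means its p values are not comparable
  across models with different n.
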