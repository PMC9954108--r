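# stromanmr

Compartment deconvolution of ^1^H HR-MAS NMR breast-tissue metabolomics.

## What problem this solves

Tissue specimens taken from breast tumors and their surroundings are
histological mixtures — cancer cells, intratumoral fibrotic stroma,
extratumoral fibrous connective tissue, fat, glandular tissue. A bulk
HR-MAS NMR spectrum of an intact specimen therefore measures a
composition-weighted blend of compartment metabolomes, and naive
case–control comparisons confound "more cancer" with "different
metabolism". `stromanmr` is for spectroscopists and computational
metabolomics researchers who have per-specimen spectra (or region
integrals) together with post-measurement histology percentages and want:

* malignant-vs-normal classification models with honest external
  validation (OPLS-DA, predicted scores, sensitivity/specificity),
* a purity model: how much of each metabolite signal is explained by the
  cancer-cell fraction, and
* compartment-level estimates: the metabolic profile of *pure*
  intratumoral fibrosis and *pure* cancer tissue obtained without ever
  physically separating them.

## The model

Quantified levels are assumed to mix linearly with composition. For
metabolite *m* in specimen *i* with tissue fractions *f<sub>ic</sub>*:

```
x_im = Σ_c f_ic · s_cm · ε_im ,   ε log-normal
```

Restricting to specimens that are essentially two-compartment
(cancer + intratumoral fibrosis > 80%) and writing purity
*p* = %cancer, the expectation is linear in *p*:

```
E[x_m | p] = s_IF,m + (s_C,m − s_IF,m) · p/100
```

so an ordinary least-squares fit of level against purity estimates the
pure-fibrosis level as its intercept (p = 0) and the pure-cancer level at
p = 100, each with a mean-response confidence band. Stroma estimates are
compared against fat-adjusted extratumoral connective tissue by a
two-level rule: disjoint 95% intervals ⇒ significant, disjoint 90%
intervals only ⇒ trend. Grade I vs II/III tumors are contrasted at
p = 60%, and luminal A vs B slopes by a homogeneity-of-slopes F test.

The multivariate layer is classical chemometrics: PCA, and OPLS/OPLS-DA
(Trygg–Wold orthogonal filtering, one predictive component) with sevenfold
cross-validated Q², CV-ANOVA significance, VIP and correlation-scaled
loadings pcorr(1).

Because the cohort this design emulates is not publicly deposited, the
package includes a calibrated synthetic generator (`generate_cohort()`,
`mix_samples()`, `synthesize_spectrum()`) so that the entire pipeline is
runnable and testable from a seed.

## Worked example

```r
library(stromanmr)

res <- run_pipeline(run_config(seed = 1), out_dir = "run1")

res$oplsda1          # cancer vs distant-normal discriminant model
#> OPLS-DA model: 1 predictive + 1 orthogonal component(s)
#>   n = 73, K = 19
#>   R2X = 87.2%, R2Y = 87.4%, Q2 = 83.2%
#>   CV-ANOVA p = 7.23e-28

res$eval1            # external validation on the held-out locations
#> TP 16  FP 3  TN 45  FN 3
#> sensitivity 84.2%  specificity 93.8%  accuracy 91.0%

res$opls_purity      # OPLS regression of cancer-cell % on the profile
#> OPLS model: 1 predictive + 1 orthogonal component(s)
#>   n = 45, K = 19
#>   R2X = 72.1%, R2Y = 76.3%, Q2 = 68.0%
#>   CV-ANOVA p = 4.12e-11

head(res$deconvolution$regressions[, c("metabolite", "slope", "intercept",
                                       "pearson_r")], 4)
#>              metabolite     slope intercept pearson_r
#> glucose         glucose -0.000441    0.1797    -0.165
#> lactate         lactate  0.005208    0.2096     0.622
#> phosphoethanolamine ...  0.003833    0.1144     0.757
#> phosphocholine      ...  0.002708    0.1167     0.661
```

Reading the output: the discriminant model separates cancer-containing
from normal specimens almost completely in training (Q² 83%) and
classifies the external locations at 91% accuracy; the purity OPLS
explains two thirds of the cancer-fraction variance out of sample (the
cross-validated predicted-vs-true purity correlation on this cohort is
r = 0.82); and in the univariate stage most small metabolites rise with
purity (positive slopes, r ≈ 0.5–0.8) while glucose falls, so their
intercepts — the estimated pure-fibrosis levels — sit well above the
fat-adjusted extratumoral reference for lactate, glutamate, succinate and
the inositols (`res$deconvolution$comparisons` holds the verdicts).

A command-line wrapper is installed at
`system.file("scripts", "run_pipeline.R", package = "stromanmr")`.

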