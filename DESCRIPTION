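Package: stromanmr
Title: Compartment Deconvolution of HR-MAS NMR Breast Tissue Metabolomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing 1H HR-MAS NMR metabolic profiles of breast
    tumor and peritumoral tissue specimens with heterogeneous histological
    composition. Provides spectral-region quantitation (chemical-shift
    calibration to the formate reference, baseline correction, region
    integration and generalized-Lorentzian deconvolution of the crowded
    choline region), multivariate modelling (PCA, OPLS and OPLS-DA with
    sevenfold cross-validation, Q2, CV-ANOVA, VIP and correlation-scaled
    loadings), and the two-compartment purity-regression deconvolution that
    extrapolates per-metabolite linear fits against cancer-cell fraction to
    0% and 100% purity to estimate metabolite levels of pure intratumoral
    fibrotic stroma and pure cancer tissue, with confidence-interval overlap
    verdicts against fat-adjusted extratumoral connective tissue. A seeded
    synthetic-data generator emulates the histological composition,
    clinical covariates and compartment-mixed metabolite levels of such a
    cohort so the whole pipeline can be exercised without access to patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
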