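Package: nmrmetab
Title: Serum 1H NMR Metabolomics Workflow with PLS-DA and Monte Carlo
    Cross-Validation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for two-cohort serum 1H NMR metabolite profiling
    studies: a synthetic spectrum generator with known ground truth
    (Lorentzian multiplets, lipid background, residual-water artifact),
    spectral preprocessing (water-region exclusion, fixed-width binning,
    internal-standard normalization, targeted peak integration with
    local baseline correction), latent-variable chemometrics (NIPALS
    PLS/PLS-DA, orthogonal signal correction, PCA, ROC/AUC), univariate
    biomarker screening (Student's t-test with signed fold changes),
    and Monte-Carlo cross-validation with a permutation null that
    aggregates internal- and external-prediction confusion matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    mixOmics,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
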