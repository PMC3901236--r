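# nmrmetab

Serum ¹H NMR metabolomics in R: a tested implementation of the classic
two-cohort biomarker workflow — spectral preprocessing, PLS-DA
chemometrics, univariate marker screening and Monte-Carlo
cross-validation — together with a synthetic CPMG-like spectrum generator
with exact ground truth, so the whole chain is verifiable without access
to patient data.

The motivating application is discriminating hepatocellular carcinoma
(HCC) from hepatitis C (HCV) patients using serum spectra (cohorts of 40
vs 22), where three metabolites — choline (3.20 ppm, s), valine (1.03 ppm,
d) and creatinine (3.03 ppm, s) — act as the biomarker panel, but every
component is generic two-class machinery.

## What's inside

| Stage | Functions |
|---|---|
| Synthetic cohorts | `default_metabolite_library()`, `render_spectrum()`, `simulate_cohorts()` |
| Preprocessing | `exclude_water()`, `bin_spectrum()`, `normalize_to_reference()`, `align_global()`, `integrate_region()`, `build_feature_table()`, `mean_center()`, `autoscale()` |
| Chemometrics | `fit_pca()`, `fit_pls()` (NIPALS), `fit_plsda()`, `osc_correct()`, `kfold_cv_predict()`, `roc_auc()` |
| Screening | `unpaired_ttest()`, `fold_change()`, `select_features()` |
| Validation | `mccv()`, `permutation_mccv()`, `sensitivity_specificity()`, `format_confusion_table()` |

The model core, in the field's standard notation: spectra are reduced to a
samples × features matrix **X** (4096 sum-aggregated 0.003 ppm buckets, or
19 baseline-corrected peak integrals, TSP-normalized); class labels are
coded **y** ∈ {+1, −1}; NIPALS extracts latent variables *t_a = X w_a*
with deflation, giving the regression vector *B = W(PᵀW)⁻¹q*; the PLS-DA
call for a sample is sign(ŷ − ȳ_train). Orthogonal signal correction
removes components of maximal X-variance whose scores are orthogonal to
**y** before full-spectrum modelling. Validation pools, over 200
iterations of stratified 60/40 splits, the 7-fold internal-CV calls on
each training set with the external calls on each hold-out set into one
confusion matrix (row totals n_class × 200 by construction), and repeats
the identical procedure with freshly permuted labels as the null.

## Worked example

The `analysis/` scripts run the full study on the default synthetic
cohort (each regenerates its inputs deterministically from the seeds in
`analysis/00_common.R`; tables land in `results/`):

```sh
Rscript analysis/01_simulate.R          # 62 spectra + ground truth
Rscript analysis/02_preprocess.R        # binning + 19-metabolite integrals
Rscript analysis/03_global_model.R      # full-spectrum OSC-PLS
Rscript analysis/04_feature_selection.R # t-test screen, signed fold changes
Rscript analysis/05_validation.R        # PLS-DA, MCCV + permutation null
```

`04_feature_selection.R` prints the marker screen (uncorrected p < 0.05):

```
4 of 19 metabolites pass p < 0.05:
  valine         p = 1.16e-05  fold change +1.49
  creatinine     p = 1.76e-05  fold change -1.42
  choline        p = 7.53e-04  fold change +1.34
  acetate        p = 1.18e-02  fold change -1.21
```

The three seeded markers are recovered with fold changes near their true
factors (+1.53, −1.28, +1.32); `acetate` is a type-I hit of the
deliberately uncorrected screen. `05_validation.R` then reports

```
[model3] 7-fold cross-validated AUC: 0.924
[model3] MCCV (200 iter): sens 0.76 spec 0.94 | permuted: sens 0.50 spec 0.49
```

and writes the aggregated confusion matrix in the publication layout
(permutation counts in parentheses; row totals 8000/4400 are forced by
40/22 samples × 200 iterations):

```
True class Total       HCC         HCV
       HCC 8000 (8000) 6110 (4025) 1890 (3975)
       HCV 4400 (4400) 277 (2243)  4123 (2157)
```

The informative model sits far from its permutation null, which is at
chance — the signature of a real class difference.

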