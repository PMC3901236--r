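---
title: "Discriminating two patient cohorts from serum 1H NMR spectra: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminating two patient cohorts from serum 1H NMR spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmrmetab)
```

# The problem

Serum metabolite profiling by one-dimensional ^1^H NMR is a standard route
to candidate diagnostic biomarkers: a CPMG (spin-echo) spectrum of a serum
sample shows sharp multiplets from dozens of small metabolites on top of a
broad lipid/protein background, and differences between patient cohorts —
here a hepatocellular-carcinoma (HCC) cohort against a hepatitis-C (HCV)
cohort, 40 vs 22 subjects — appear as modest, correlated shifts in many
peak intensities at once. The statistical workflow this package implements
is the field's classic one: fixed-width binning or targeted peak
integration, internal-standard normalization, latent-variable
classification (PLS-DA, optionally after orthogonal signal correction),
univariate screening with Student's *t*-test and signed fold changes, and
resampling-based validation (Monte-Carlo cross-validation with a
permutation null).

Because patient spectra from such studies are generally not deposited, the
package pairs the analysis chain with a synthetic-spectrum generator whose
ground truth is known exactly. Every stage can therefore be tested
end-to-end: the generator *defines* the study conditions, and the analysis
must recover what was seeded.

# The synthetic cohort generator

## Spectral model

A spectrum is a sum of metabolite signals, optional broad backgrounds and
noise on a descending ppm axis (default 10.288 to −2.0 ppm, 16,384 points
— a ~6,000 Hz window at 500 MHz, stored finer than the 4096-bucket
analysis grid so binning is a genuine 4:1 reduction):

* **Metabolite multiplets.** Each resonance is a Lorentzian line or
  multiplet (doublet 1:1, triplet 1:2:1, quartet 1:3:3:1; J converted from
  Hz to ppm through the spectrometer frequency; unresolved multiplets are
  rendered as a broadened singlet). Lorentzian shapes are the natural
  choice for the sharp small-molecule lines that survive a CPMG echo
  train. Lines are normalized so the analytic area of a metabolite's
  signal equals its concentration times its `rel_intensity` weights —
  areas, not heights, carry quantitative meaning in NMR.
* **Lipid background.** Broad Gaussians near 0.9, 1.3, 2.0 and 5.3 ppm
  (FWHM 60 Hz). Gaussian-vs-Lorentzian contrast deliberately mimics the
  broad/narrow distinction between macromolecule humps and metabolite
  lines.
* **Residual water.** A Gaussian at 4.95 ppm with FWHM 0.15 ppm, i.e.
  numerically confined to the 4.7–5.2 ppm exclusion window, so the water
  cut provably removes it.
* **Reference standard.** A TSP singlet at 0.0 ppm with fixed
  concentration 1 and no biological variation, giving the normalization
  stage a well-defined target.
* **Noise.** i.i.d. Gaussian per point (default sd 0.02, a few hundred-fold
  below the taller metabolite lines — a realistic high-field SNR).

## The default library

The default library holds 19 metabolites routinely quantified in CPMG
serum spectra (isoleucine, leucine, valine, 3-hydroxybutyrate, lactate,
alanine, acetate, acetone, glutamate, glutamine, citrate, asparagine,
creatinine, choline, glycine, glucose, creatine, histidine, formate) plus
TSP. The three study biomarkers carry their literature positions —
choline 3.20 s, valine 1.03 d, creatinine 3.03 s. Some multiplet patterns
are simplified (e.g. creatine is represented only by its 3.93 ppm singlet)
so that the 19 default integration windows stay pairwise disjoint; users
can supply their own library and window TSV files. Mean concentrations
span roughly two orders of magnitude (glucose 5.0 down to formate 0.02,
arbitrary units) to echo serum's dynamic range.

## Biological variation and cohort effects

Per-sample concentrations are drawn log-normally with median
`mean_conc × effect` and coefficient of variation `bio_cv`: concentrations
stay positive, and multiplicative group effects compose exactly, so a
seeded effect factor is recovered as a ratio of cohort medians (or means —
for a shared `bio_cv` the lognormal mean offset cancels in the ratio).

Two defaults matter:

* `bio_cv = 0.3`. Between-subject CVs of serum metabolites are typically
  20–40%; 0.3 also places the seeded effects at a significance comparable
  to the study's own screen (a ×1.53 valine effect at n = 40/22 gives
  *t*-test p-values of order 10^−5^).
* The default cohorts are 40 "HCC" vs 22 "HCV" samples with the positive
  cohort scaled by choline ×1.32, valine ×1.53 and creatinine ×1/1.28
  (creatinine is the marker elevated in the *negative* cohort, exercising
  the negative branch of the signed-fold-change convention).

Everything is driven by one seed; identical inputs reproduce spectra and
ground truth bit for bit.

## What the simulator does *not* emulate

No phase or baseline-roll errors, no peak-position drift between samples
(a global alignment operation exists, but default spectra are aligned), no
peak-shape distortion, no correlated metabolite physiology, and no
NOESY-style relaxation modelling. Passing tests therefore demonstrate the
*procedure's* correctness and calibration — not robustness to the
alignment/baseline pathologies of real instrument data.

# Preprocessing

The processing order is: water-region exclusion (4.7–5.2 ppm) → binning →
TSP normalization, with targeted integrals computed on the unbinned,
TSP-normalized spectrum. Choices worth stating:

* **Binning aggregates by SUM** (4096 buckets of 0.003 ppm by default),
  so total in-window intensity is conserved exactly and "area" language
  stays meaningful; a mean option exists but is non-default. Buckets are
  half-open, laid from the high-ppm end, with edge ties going to the
  higher-ppm bucket.
* **Normalization divides by the reference area** over −0.05..0.05 ppm
  (trapezoidal for raw spectra, bucket-sum for binned ones); the
  post-normalization reference area is exactly 1, the operation is
  idempotent, and any global dilution factor cancels. A non-positive
  reference area is a hard, sample-named error — it means the internal
  standard is missing or corrupted.
* **Targeted integration** is trapezoidal with *local baseline
  correction*: the straight line through the region's two endpoint
  intensities is subtracted. This removes any linear baseline exactly (to
  machine precision, a tested invariant) and most of a broad hump's
  contribution under a narrow window; its residual error is the hump's
  curvature, which for the default lipid widths is below 1% of the
  metabolite areas involved.
* **Global alignment** shifts the whole axis so the tallest point near a
  reference shift (default: alanine, 1.479 ppm) lands exactly on it —
  shift-only, no segment-wise warping.
* **Scaling bookkeeping.** Feature tables move from `raw` to
  `mean_centered` or `autoscaled` exactly once; the fitted centers/scales
  are stored and reapplied to new data, which is what makes the
  cross-validation below leakage-free. Full-spectrum (binned) models use
  mean-centering; targeted peak-integral models use autoscaling, so the
  weak markers (choline, creatinine) are not drowned by glucose and
  lactate.

# Latent-variable modelling

* **PLS / PLS-DA** is NIPALS PLS1 with deflation of both blocks; at
  `n_lv = rank(X)` it reproduces the least-squares fit, scores are
  mutually orthogonal, and the compact regression vector
  `B = W (PᵀW)⁻¹ q` equals sequential-deflation prediction — all tested,
  plus agreement with an independent NIPALS implementation to 10^−6^.
  Labels are coded +1 (positive class, HCC) / −1.
* **Decision rule.** The discriminant score is the *centered* prediction,
  `s(x) = ŷ(x) − ȳ_train`, classified at threshold 0. With balanced
  classes `ȳ_train = 0` and this is the plain sign rule; with unbalanced
  cohorts (40/22 coded ±1 gives ȳ ≈ +0.29) the raw sign rule would call
  nearly two-thirds of null predictions positive, and a permutation run
  would report sensitivity/specificity far from 50% purely through the
  intercept. Removing the offset keeps an uninformative model at chance —
  measured permutation runs sit at ~0.50/0.48 — which is the behaviour a
  permutation null is supposed to certify. This mirrors in the simplest
  possible form what commercial PLS-DA implementations achieve with
  data-derived (Bayesian) thresholds.
* **Number of latent variables** defaults to 2 for both the 19-feature
  and 3-feature models. The choice is deliberately small (the marker
  signal is essentially one direction plus correlated noise) and exposed
  as a parameter everywhere.
* **OSC** (orthogonal signal correction, Wold-style) iterates from the
  first principal-component score: orthogonalize the score against `y`,
  regress weights, rebuild the score, to a 10^−8^ relative tolerance with
  an iteration cap that errors with diagnostics rather than silently
  stopping. After convergence the score is orthogonalized once more, so
  the removed component is *exactly* y-orthogonal (a tested invariant).
  One component is removed by default. If the data carry nothing
  orthogonal to `y` the component degenerates and the matrix passes
  through unchanged. The stored weight/loading pairs make the filter
  applicable to new samples.
* **PCA** is SVD-based; explained-variance fractions are non-increasing
  and the loadings orthonormal.
* **ROC/AUC** uses the rank (Mann-Whitney) formulation with half-weight
  ties — identical to exhaustive concordant-pair counting, which the
  tests verify exhaustively up to n = 12.

# Validation

Monte-Carlo cross-validation repeats, 200 times by default: a stratified
60/40 split (per-class training size `round(0.6 n_class)`; for 40/22 this
is 24 + 13 = 37, matching `round(0.6 × 62)`); 7-fold internal
cross-validation *within* the training set (folds refit their own
scaling); external prediction of the 40% hold-out by the model fitted on
the full training set; and pooling of the 62 per-iteration class calls
into one aggregated confusion matrix. The row totals are therefore exactly
`n_pos × n_iter` and `n_neg × n_iter` (8000 and 4400 for 40/22 × 200) —
a structural identity the tests assert exactly.

Design choices: splits and folds are stratified by class (at n = 22 for
the minor class, unstratified 60/40 splits occasionally lose a class
entirely); fold assignment is keyed on sorted sample ids, so predictions
are invariant to row order; one master seed derives a per-iteration
sub-seed (any iteration is replayable in isolation); and the permutation
null redraws a fresh uniform permutation of the labels *each iteration*,
which approximates the null distribution better than a single fixed
permutation and keeps class counts intact.

# Univariate screening

The screen is the classic pooled-variance (equal-variance) Student's
*t*-test — not Welch's, matching the published table's degrees of freedom
convention — with two-sided p-values, uncorrected by default (Bonferroni
and Benjamini-Hochberg are available but off, mirroring the deliberately
permissive screening stance); fold changes are ratios of raw-scale group
means reported as `+r` / `−1/r` so the sign names the elevated cohort.
Ratios of means (not medians) are used: with a common CV the lognormal
mean/median offset cancels either way, and means match the *t*-test's
estimand. Degenerate features (zero variance, non-positive means) are
excluded with a warning, never silently.

# Problem sizes and numerical notes

The shipped analysis scripts and tests use the study-sized cohort
(62 spectra × 16,384 points, 4096 buckets, 19 integrals) and 200 MCCV
iterations — the full published geometry, which runs in seconds to a
couple of minutes per stage. Effect-recovery checks use 500 samples per
cohort with `bio_cv = 0.1`, where the sampling error of a fold-change
estimate is well under the 5% acceptance band. Numerical tolerances that
matter: OSC convergence 10^−8^ (relative, on the score), score
orthogonality asserted at 10^−6^ relative, autoscaling refuses
zero-variance columns by name, and binning requires the axis to span the
requested grid rather than inventing empty buckets.

# Known limitations

* The 19 default integration windows are tied to the simulator's library;
  real studies must supply their own window list (the supplementary
  window tables of published studies are rarely machine-readable).
* The simulator's clean axis means the alignment operation is exercised
  on injected shifts only.
* OSC-PLS on 4096 buckets removes a large orthogonal variance fraction
  dominated by the lipid humps; on real data the removed component also
  absorbs instrumental drift, which the simulator does not model.
* PLS-DA here is strictly two-class with a single response column.
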