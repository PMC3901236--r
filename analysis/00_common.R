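# Shared study conditions for the analysis scripts. Every script sources
# this file and regenerates the same synthetic cohort deterministically,
# so each step can be run (and re-run) in isolation.

library(nmrmetab)

STUDY_SEED <- 101          # master seed of the simulated study
MCCV_SEED <- 210           # master seed of the validation stage
N_ITER <- 200              # Monte-Carlo cross-validation iterations
N_LV <- 2                  # latent variables of the PLS-DA models

results_dir <- "results"
scratch_dir <- "scratch"
dir.create(results_dir, showWarnings = FALSE)
dir.create(scratch_dir, showWarnings = FALSE)

study_library <- default_metabolite_library()
study_regions <- default_regions()
study_config <- sim_config(seed = STUDY_SEED)

# 40 HCC (positive) vs 22 HCV samples, with the positive cohort carrying
# the published effects: choline x1.32, valine x1.53, creatinine x1/1.28
study_simulation <- function() {
  co <- default_cohorts()
  simulate_cohorts(co$positive, co$negative, study_library, study_config)
}

# TSP-normalized spectra (the scale on which everything downstream runs)
study_spectra <- function(sim = study_simulation()) {
  lapply(sim$spectra, normalize_to_reference)
}
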