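#' Simulation configuration for synthetic serum spectra
#'
#' Defaults emulate a 500 MHz CPMG-style acquisition: a 6,000 Hz (~12 ppm)
#' spectral window stored on a descending axis from 10.288 to -2.0 ppm with
#' 16,384 points, so that the default 4096 x 0.003 ppm analysis binning is a
#' genuine 4:1 reduction of the simulation grid.
#'
#' @param ppm_start,ppm_end Axis limits in ppm; `ppm_start > ppm_end`
#'   (the axis is stored descending).
#' @param n_points Number of points on the simulation grid.
#' @param spectrometer_freq Spectrometer frequency in MHz, used to convert
#'   J couplings and linewidths from Hz to ppm.
#' @param noise_sd Standard deviation of i.i.d. Gaussian point noise,
#'   in intensity units.
#' @param lipid_background Add broad Gaussian lipid humps (centres near
#'   0.9, 1.3, 2.0 and 5.3 ppm)?
#' @param water_artifact Add a broad residual-water hump confined to
#'   4.7-5.2 ppm?
#' @param seed Integer seed controlling every random draw of a simulation.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(ppm_start = 10.288, ppm_end = -2.0, n_points = 16384,
                       spectrometer_freq = 500, noise_sd = 0.02,
                       lipid_background = TRUE, water_artifact = TRUE,
                       seed = 1L) {
  if (ppm_start <= ppm_end) stop("ppm_start must exceed ppm_end (descending axis)")
  if (n_points < 2) stop("n_points must be >= 2")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (spectrometer_freq <= 0) stop("spectrometer_freq must be > 0")
  structure(
    list(ppm_start = ppm_start, ppm_end = ppm_end,
         n_points = as.integer(n_points),
         spectrometer_freq = spectrometer_freq, noise_sd = noise_sd,
         lipid_background = isTRUE(lipid_background),
         water_artifact = isTRUE(water_artifact), seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Cohort specification for two-group simulations
#'
#' @param label Cohort label (e.g. "HCC").
#' @param n_samples Number of samples to draw.
#' @param effects Named numeric vector of multiplicative concentration
#'   factors (> 0) applied to this cohort's metabolites; metabolites not
#'   named keep factor 1.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(label, n_samples, effects = numeric(0)) {
  if (n_samples < 1) stop("n_samples must be >= 1")
  effects <- unlist(effects)
  if (length(effects) && (is.null(names(effects)) || any(names(effects) == "")))
    stop("effects must be a named vector")
  if (any(effects <= 0)) stop("all effect factors must be > 0")
  structure(list(label = as.character(label),
                 n_samples = as.integer(n_samples),
                 effects = effects),
            class = "cohort_spec")
}

#' Default study cohorts
#'
#' Two cohorts sized 40 (positive, "HCC") and 22 (negative, "HCV"), with
#' the positive cohort's choline, valine and creatinine concentrations
#' scaled by the study effect sizes: choline x1.32, valine x1.53 and
#' creatinine x1/1.28 (creatinine is elevated in the negative cohort, hence
#' its negative signed fold change).
#'
#' @return A list with elements `positive` and `negative` ([cohort_spec()]).
#' @export
default_cohorts <- function() {
  list(
    positive = cohort_spec("HCC", 40,
                           c(choline = 1.32, valine = 1.53,
                             creatinine = 1 / 1.28)),
    negative = cohort_spec("HCV", 22)
  )
}

# expand one library row into individual multiplet lines:
# data.frame(center_ppm, weight) with weights summing to rel_intensity.
# J is converted Hz -> ppm through the spectrometer frequency; "m" is
# rendered as a single broadened line (handled via linewidth upstream).
.multiplet_lines <- function(center, multiplicity, J_hz, freq) {
  Jppm <- J_hz / freq
  switch(multiplicity,
    s = list(offsets = 0, w = 1),
    m = list(offsets = 0, w = 1),
    d = list(offsets = c(-0.5, 0.5) * Jppm, w = c(1, 1) / 2),
    t = list(offsets = c(-1, 0, 1) * Jppm, w = c(1, 2, 1) / 4),
    q = list(offsets = c(-1.5, -0.5, 0.5, 1.5) * Jppm, w = c(1, 3, 3, 1) / 8),
    stop("unknown multiplicity: ", multiplicity)
  )
}

# Lorentzian of unit area (in ppm units) centred at c0 with FWHM fwhm (ppm)
.lorentz <- function(ppm, c0, fwhm) {
  hw <- fwhm / 2
  (hw / pi) / ((ppm - c0)^2 + hw^2)
}

# Gaussian of unit area (ppm units)
.gauss <- function(ppm, c0, fwhm) {
  sd <- fwhm / (2 * sqrt(2 * log(2)))
  stats::dnorm(ppm, mean = c0, sd = sd)
}

#' Per-unit-concentration spectral profiles of a library
#'
#' Renders, once per (library, config) pair, the noise-free spectrum each
#' metabolite contributes at unit concentration: the sum of its Lorentzian
#' multiplet lines (binomial 1:1 / 1:2:1 / 1:3:3:1 intensities for d/t/q,
#' "m" as a broadened singlet), normalised so the analytic area of each
#' metabolite's lines equals its `rel_intensity` total.
#'
#' @param lib A metabolite library.
#' @param config A [sim_config()].
#' @return A list with the ppm `axis` and a `profiles` matrix
#'   (points x metabolites).
#' @export
unit_profiles <- function(lib, config) {
  lib <- validate_library(lib)
  axis <- seq(config$ppm_start, config$ppm_end, length.out = config$n_points)
  mets <- unique(lib$name)
  prof <- matrix(0, nrow = config$n_points, ncol = length(mets),
                 dimnames = list(NULL, mets))
  for (i in seq_len(nrow(lib))) {
    row <- lib[i, ]
    fwhm <- row$linewidth_hz / config$spectrometer_freq
    ml <- .multiplet_lines(row$center_ppm, row$multiplicity, row$J_hz,
                           config$spectrometer_freq)
    for (k in seq_along(ml$offsets)) {
      prof[, row$name] <- prof[, row$name] +
        row$rel_intensity * ml$w[k] *
        .lorentz(axis, row$center_ppm + ml$offsets[k], fwhm)
    }
  }
  list(axis = axis, profiles = prof)
}

# broad background components (intensity vectors on the axis)
.lipid_background <- function(axis, freq) {
  centers <- c(0.9, 1.3, 2.0, 5.3)
  areas <- c(0.5, 1.0, 0.3, 0.2)
  fwhm <- 60 / freq  # >= 50 Hz, broad by construction
  bg <- numeric(length(axis))
  for (k in seq_along(centers)) {
    bg <- bg + areas[k] * .gauss(axis, centers[k], fwhm)
  }
  bg
}

.water_artifact <- function(axis) {
  # centred mid-window with FWHM 0.15 ppm: +/-0.25 ppm is ~3.9 sd, so the
  # artifact is (numerically) fully inside the 4.7-5.2 ppm exclusion window
  5 * .gauss(axis, 4.95, 0.15)
}

#' Render one synthetic spectrum
#'
#' @param lib A metabolite library.
#' @param concentrations Named numeric vector of concentrations; names must
#'   exist in the library; omitted metabolites contribute nothing.
#' @param config A [sim_config()]. Noise is drawn from the current RNG
#'   stream (seed the caller, or use [simulate_cohorts()] which seeds
#'   everything from `config$seed`).
#' @param sample_id Sample identifier.
#' @param cache Optional precomputed [unit_profiles()] result.
#' @return A [raw_spectrum()].
#' @export
render_spectrum <- function(lib, concentrations, config,
                            sample_id = "sample", cache = NULL) {
  lib <- validate_library(lib)
  mets <- unique(lib$name)
  unknown <- setdiff(names(concentrations), mets)
  if (length(unknown)) {
    stop("unknown metabolite(s) in concentrations: ",
         paste(unknown, collapse = ", "))
  }
  up <- cache %||% unit_profiles(lib, config)
  conc <- stats::setNames(numeric(length(mets)), mets)
  conc[names(concentrations)] <- concentrations
  y <- as.numeric(up$profiles %*% conc)
  if (config$lipid_background) {
    y <- y + .lipid_background(up$axis, config$spectrometer_freq)
  }
  if (config$water_artifact) y <- y + .water_artifact(up$axis)
  if (config$noise_sd > 0) {
    y <- y + stats::rnorm(length(y), sd = config$noise_sd)
  }
  raw_spectrum(up$axis, y, sample_id)
}

#' Simulate two cohorts of serum-like spectra with known ground truth
#'
#' Per-sample concentrations are drawn log-normally with median
#' `mean_conc * effect` and coefficient of variation `bio_cv` (so effects
#' compose multiplicatively and concentrations stay positive). Everything
#' is seeded from `config$seed`: the same inputs reproduce the same spectra
#' bit for bit.
#'
#' @param spec_pos,spec_neg [cohort_spec()]s for the positive and negative
#'   cohorts (labels must differ).
#' @param lib A metabolite library.
#' @param config A [sim_config()].
#' @return A list with `spectra` (list of [raw_spectrum()]),
#'   `truth` (data.frame: sample_id, label, one column of true
#'   concentrations per metabolite) and `labels` (character vector).
#' @export
simulate_cohorts <- function(spec_pos, spec_neg, lib = default_metabolite_library(),
                             config = sim_config()) {
  stopifnot(inherits(spec_pos, "cohort_spec"), inherits(spec_neg, "cohort_spec"))
  if (spec_pos$label == spec_neg$label) stop("cohort labels must differ")
  lib <- validate_library(lib)
  mets <- unique(lib$name)
  for (sp in list(spec_pos, spec_neg)) {
    bad <- setdiff(names(sp$effects), mets)
    if (length(bad)) stop("effects name unknown metabolite(s): ",
                          paste(bad, collapse = ", "))
  }
  pars <- lib[!duplicated(lib$name), c("name", "mean_conc", "bio_cv")]
  up <- unit_profiles(lib, config)

  draw_cohort <- function(sp) {
    eff <- stats::setNames(rep(1, length(mets)), mets)
    eff[names(sp$effects)] <- sp$effects
    conc <- matrix(0, nrow = sp$n_samples, ncol = length(mets),
                   dimnames = list(NULL, mets))
    for (m in mets) {
      p <- pars[pars$name == m, ]
      sdlog <- sqrt(log(1 + p$bio_cv^2))
      conc[, m] <- stats::rlnorm(sp$n_samples,
                                 meanlog = log(p$mean_conc * eff[m]),
                                 sdlog = sdlog)
    }
    conc
  }

  with_seed(config$seed, {
    conc_pos <- draw_cohort(spec_pos)
    conc_neg <- draw_cohort(spec_neg)
    conc <- rbind(conc_pos, conc_neg)
    labels <- c(rep(spec_pos$label, spec_pos$n_samples),
                rep(spec_neg$label, spec_neg$n_samples))
    ids <- paste0(labels, "_", c(seq_len(spec_pos$n_samples),
                                 seq_len(spec_neg$n_samples)))
    clean <- up$profiles %*% t(conc)
    if (config$lipid_background) {
      clean <- clean + .lipid_background(up$axis, config$spectrometer_freq)
    }
    if (config$water_artifact) clean <- clean + .water_artifact(up$axis)
    if (config$noise_sd > 0) {
      clean <- clean + matrix(stats::rnorm(length(clean), sd = config$noise_sd),
                              nrow = nrow(clean))
    }
    spectra <- lapply(seq_along(ids), function(j) {
      raw_spectrum(up$axis, clean[, j], ids[j])
    })
    truth <- data.frame(sample_id = ids, label = labels,
                        conc, check.names = FALSE,
                        stringsAsFactors = FALSE)
    list(spectra = spectra, truth = truth, labels = labels)
  })
}

#' Write simulated spectra and ground truth to disk
#'
#' Emits one two-column CSV per spectrum, the ground-truth TSV and a JSON
#' manifest echoing the configuration and seed.
#'
#' @param sim Result of [simulate_cohorts()].
#' @param dir Output directory (created if absent).
#' @param config The [sim_config()] used (echoed into the manifest).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, config) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in sim$spectra) {
    write_spectrum_csv(s, file.path(dir, paste0(s$sample_id, ".csv")))
  }
  utils::write.table(sim$truth, file.path(dir, "ground_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(config = unclass(config),
                   n_samples = length(sim$spectra),
                   labels = as.list(table(sim$labels)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
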