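# Shared fixtures: small libraries and quick simulation settings so each
# test builds its data in code.

# three-metabolite library (plus TSP) covering s/d multiplets
tiny_library <- function(bio_cv = 0.1) {
  validate_library(data.frame(
    name = c("TSP", "valine", "creatinine", "choline"),
    center_ppm = c(0, 1.03, 3.03, 3.20),
    multiplicity = c("s", "d", "s", "s"),
    J_hz = c(0, 7, 0, 0),
    linewidth_hz = c(1.2, 1.2, 1.2, 1.2),
    rel_intensity = 1,
    mean_conc = c(1, 0.22, 0.07, 0.03),
    bio_cv = c(0, bio_cv, bio_cv, bio_cv),
    stringsAsFactors = FALSE
  ))
}

tiny_regions <- function() {
  data.frame(name = c("valine", "creatinine", "choline"),
             lo = c(1.005, 3.005, 3.175),
             hi = c(1.055, 3.055, 3.225),
             stringsAsFactors = FALSE)
}

# coarse but full-window config: binning/water/TSP geometry preserved
quick_config <- function(noise_sd = 0, seed = 1L, ...) {
  sim_config(n_points = 4096, noise_sd = noise_sd, seed = seed, ...)
}

# two Gaussian clouds separated by delta standard deviations
gauss_clouds <- function(n_pos, n_neg, delta, p = 5, seed = 1) {
  with_seed(seed, {
    X <- rbind(matrix(stats::rnorm(n_pos * p, mean = delta), n_pos, p),
               matrix(stats::rnorm(n_neg * p, mean = 0), n_neg, p))
    rownames(X) <- sprintf("s%03d", seq_len(n_pos + n_neg))
    colnames(X) <- paste0("f", seq_len(p))
    list(X = X, labels = c(rep("HCC", n_pos), rep("HCV", n_neg)))
  })
}

# exhaustive concordant-pair AUC (independent oracle for roc_auc)
auc_by_pairs <- function(scores, labels, positive) {
  pos <- which(labels == positive)
  neg <- which(labels != positive)
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  }
  tot / (length(pos) * length(neg))
}
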