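make_spec <- function(ppm, intensity, id = "s1") raw_spectrum(ppm, intensity, id)

test_that("water exclusion removes exactly the window and conserves the rest", {
  lib <- tiny_library()
  cfg <- quick_config(water_artifact = TRUE, lipid_background = FALSE)
  s <- render_spectrum(lib, c(valine = 0.2), cfg)
  out <- exclude_water(s)
  expect_false(any(out$ppm >= 4.7 & out$ppm <= 5.2))
  keep <- s$ppm < 4.7 | s$ppm > 5.2
  expect_identical(out$intensity, s$intensity[keep])
  expect_equal(sum(out$intensity), sum(s$intensity[keep]))

  # no points in the window: returned unchanged
  s2 <- make_spec(seq(3, 1, length.out = 50), runif(50))
  expect_identical(exclude_water(s2), s2)

  s3 <- make_spec(seq(5.1, 4.8, length.out = 20), runif(20))
  expect_error(exclude_water(s3), "entire spectrum")
})

test_that("binning follows the sum convention and conserves signal", {
  s <- make_spec(c(8.75, 8.0, 6.5, 6.0, 4.4, 4.0, 2.3, 0.75),
                 c(1, 1, 2, 2, 3, 3, 4, 4))
  b <- bin_spectrum(s, n_bins = 4, bin_width = 2)
  expect_equal(b$values, c(2, 4, 6, 8))
  expect_equal(sum(b$values), sum(s$intensity))

  # default geometry on a simulated spectrum: exactly 4096 buckets
  sim <- render_spectrum(tiny_library(), c(valine = 0.2), quick_config())
  bb <- bin_spectrum(exclude_water(sim))
  expect_length(bb$values, 4096)
  expect_equal(sum(bb$values), sum(exclude_water(sim)$intensity))

  expect_error(bin_spectrum(make_spec(c(2, 1), c(0, 0)), n_bins = 4096),
               "spans less")
})

test_that("reference normalization rescales to unit area and removes dilution", {
  lib <- tiny_library()
  cfg <- quick_config()
  s <- render_spectrum(lib, c(TSP = 2, valine = 0.2), cfg)
  n <- normalize_to_reference(s)
  expect_equal(integrate_region(n, -0.05, 0.05, local_baseline = FALSE), 1,
               tolerance = 1e-12)
  # intensities are scaled by 1/area (area ~ 2 up to window truncation)
  expect_equal(n$intensity * n$meta$ref_area, s$intensity)

  # global x3 dilution is erased
  s3 <- raw_spectrum(s$ppm, 3 * s$intensity, "diluted")
  n3 <- normalize_to_reference(s3)
  expect_equal(n3$intensity, n$intensity, tolerance = 1e-12)

  # binned variant: unit reference sum, idempotent
  b <- normalize_to_reference(bin_spectrum(s))
  sel <- b$centers >= -0.05 & b$centers <= 0.05
  expect_equal(sum(b$values[sel]), 1)
  b2 <- normalize_to_reference(b)
  expect_equal(b2$values, b$values)

  zero <- make_spec(seq(1, -1, length.out = 100), rep(0, 100))
  expect_error(normalize_to_reference(zero), "reference area")
})

test_that("global alignment recovers an injected shift", {
  lib <- tiny_library()
  cfg <- quick_config()
  s <- render_spectrum(lib, c(choline = 0.5), cfg)
  step <- abs(diff(s$ppm[1:2]))
  # alanine is absent from the tiny library; align on the choline singlet
  shifted <- raw_spectrum(s$ppm + 0.01, s$intensity, "shifted")
  al <- align_global(shifted, ref_ppm = 3.20, search = 0.05)
  expect_lt(abs(al$meta$alignment_shift + 0.01), step + 1e-12)

  al0 <- align_global(s, ref_ppm = 3.20, search = 0.05)
  expect_lt(abs(al0$meta$alignment_shift), step + 1e-12)

  flat <- make_spec(seq(2, 0, length.out = 200), rep(1, 200))
  expect_error(align_global(flat, ref_ppm = 1.0), "flat")
})

test_that("region integration matches the analytic Lorentzian area", {
  # unit-area Lorentzian, FWHM 0.01 ppm, region +/- 10 linewidths
  ppm <- seq(2, 0, length.out = 20000)
  hw <- 0.005
  y <- (hw / pi) / ((ppm - 1)^2 + hw^2)
  s <- make_spec(ppm, y)
  a <- integrate_region(s, 1 - 0.1, 1 + 0.1, local_baseline = FALSE)
  expect_equal(a, 1, tolerance = 0.05)

  # a constant offset changes nothing with local baseline, and adds
  # c * width without it
  s_off <- make_spec(ppm, y + 3)
  expect_equal(integrate_region(s_off, 0.9, 1.1, local_baseline = TRUE),
               integrate_region(s, 0.9, 1.1, local_baseline = TRUE),
               tolerance = 1e-10)
  # offset adds c x (spanned width) to the uncorrected integral
  inside <- ppm[ppm >= 0.9 & ppm <= 1.1]
  width <- max(inside) - min(inside)
  expect_equal(integrate_region(s_off, 0.9, 1.1, local_baseline = FALSE) -
                 integrate_region(s, 0.9, 1.1, local_baseline = FALSE),
               3 * width, tolerance = 1e-6)

  zeros <- make_spec(ppm, rep(0, length(ppm)))
  expect_equal(integrate_region(zeros, 0.5, 1.5), 0)
  expect_error(integrate_region(s, 5, 6), "fewer than 3 points")
})

test_that("local baseline correction is exactly invariant to any straight line", {
  ppm <- seq(3, 1, length.out = 501)
  y <- exp(-((ppm - 2) / 0.05)^2)
  s <- make_spec(ppm, y)
  a <- 0.7; b <- -2.3
  s_lin <- make_spec(ppm, y + a + b * ppm)
  expect_equal(integrate_region(s_lin, 1.5, 2.5, local_baseline = TRUE),
               integrate_region(s, 1.5, 2.5, local_baseline = TRUE),
               tolerance = 1e-12)
})

test_that("feature tables are built per sample and region, order-faithfully", {
  lib <- tiny_library()
  cfg <- quick_config(noise_sd = 0.001, seed = 7)
  sim <- simulate_cohorts(cohort_spec("HCC", 5), cohort_spec("HCV", 4),
                          lib, cfg)
  spectra <- lapply(sim$spectra, normalize_to_reference)
  ft <- build_feature_table(spectra, tiny_regions(), labels = sim$labels)
  expect_equal(dim(ft), c(9L, 3L))
  expect_equal(ft$scaling_state, "raw")

  one <- build_feature_table(spectra[1], tiny_regions()[1, , drop = FALSE])
  expect_equal(one$values[1, 1],
               integrate_region(spectra[[1]], tiny_regions()[1, , drop = FALSE]))

  perm <- c(3, 1, 2, 9, 5, 4, 8, 6, 7)
  ft2 <- build_feature_table(spectra[perm], tiny_regions())
  expect_equal(ft2$values, ft$values[perm, ])

  off_axis <- raw_spectrum(spectra[[1]]$ppm + 0.001, spectra[[1]]$intensity, "bad")
  expect_error(build_feature_table(c(spectra[1:2], list(off_axis)), tiny_regions()),
               "axis mismatch")
})

test_that("scaling transitions, parameters and reapplication", {
  set.seed(11)
  m <- matrix(rexp(60), 12, 5, dimnames = list(paste0("s", 1:12), paste0("f", 1:5)))
  ft <- feature_table(m)

  ctr <- mean_center(ft)
  expect_true(all(abs(colMeans(ctr$values)) < 1e-10))
  expect_error(mean_center(ctr), "already")

  au <- autoscale(ft)
  expect_true(all(abs(colMeans(au$values)) < 1e-10))
  expect_true(all(abs(apply(au$values, 2, sd) - 1) < 1e-10))
  expect_error(autoscale(au), "already")

  # stored parameters reproduce the autoscaled table bit for bit
  expect_identical(apply_scaling(au, m), au$values)

  m2 <- cbind(m, constant = 1)
  expect_error(autoscale(feature_table(m2)), "constant")
})
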