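test_that("ring profile is a saturating monotone curve anchored at the pith", {
  p <- list(pith = 1.95, asym = 4.0, rate = 0.15, midpoint = 6)
  prof <- ring_profile(1:40, p)
  expect_equal(prof[1], p$pith)
  expect_true(all(diff(prof) > 0))          # strictly increasing
  expect_equal(which.max(prof), 40)
  # rapid early rise, plateau late: average slope before ring 18 must
  # dominate the slope beyond ring 23
  expect_gt(mean(diff(prof[1:18])), 8 * mean(diff(prof[23:40])))
  expect_lt(prof[40], p$asym)
  expect_error(ring_profile(0, p), "ring")
})

test_that("ring number and simulated length correlate strongly", {
  r <- vapply(1:20, function(s) {
    co <- default_cohort(s)
    cor(co$metadata$ring, co$target)
  }, numeric(1))
  expect_gt(mean(r), 0.80)
  expect_gte(sum(r > 0.80), 19)
})

test_that("spectrum synthesis is deterministic at zero noise and band-linked", {
  cfg <- cohort_config(noise_sd = 0, drift_amplitude = 0, scatter_sd = 0,
                       band_jitter_sd = 0, nuisance_amp_sd = 0)
  s1 <- synthesize_spectrum(3.0, 10, cfg)
  s2 <- synthesize_spectrum(3.0, 10, cfg)
  expect_identical(s1, s2)
  expect_length(s1, 2048)
  expect_true(all(is.finite(s1)))
  # a target-linked band moves with the configured sign and proportionally
  wl <- nir_wavelengths()
  i1415 <- which(wl == 1415); i2315 <- which(wl == 2315)
  s3 <- synthesize_spectrum(4.0, 10, cfg)
  s4 <- synthesize_spectrum(5.0, 10, cfg)
  d13 <- s3[i1415] - s1[i1415]
  expect_gt(d13, 0)                                   # positive slope
  expect_lt(s3[i2315] - s1[i2315], 0)                 # negative slope
  expect_equal(s4[i1415] - s3[i1415], d13, tolerance = 1e-10)
  expect_error(synthesize_spectrum(-1, 10, cfg), "target")
})

test_that("the default cohort reproduces the printed design counts", {
  co <- default_cohort(1)
  expect_equal(length(co$target), 164)
  expect_equal(ncol(co$absorbance), 2048)
  expect_equal(as.numeric(table(co$set)), c(117, 47))
  expect_equal(nrow(co$metadata), 164)
  expect_true(all(co$target > 0))
  expect_true(all(is.finite(co$absorbance)))
  expect_lte(max(co$metadata$tree_id), 7)
  # sampling rule: rings above 20 appear only at odd numbers
  high <- co$metadata$ring[co$metadata$ring > 20]
  expect_true(all(high %% 2 == 1))
})

test_that("generation is bit-reproducible under a fixed seed", {
  a <- simulate_cohort(cohort_config(seed = 123))
  b <- simulate_cohort(cohort_config(seed = 123))
  expect_identical(a, b)
  c <- simulate_cohort(cohort_config(seed = 124))
  expect_false(identical(a$absorbance, c$absorbance))
})

test_that("more channel noise means larger deviation from the clean core", {
  msd <- vapply(c(0.002, 0.01, 0.03), function(nsd) {
    dev <- 0
    for (s in 1:5) {
      cfg <- cohort_config(noise_sd = nsd, drift_amplitude = 0,
                           scatter_sd = 0, band_jitter_sd = 0,
                           nuisance_amp_sd = 0)
      set.seed(s)
      tgt <- runif(1, 2, 4.5)
      clean <- clean_spectrum(tgt, 12, cfg)
      set.seed(s + 100)
      noisy <- synthesize_spectrum(tgt, 12, cfg)
      dev <- dev + mean((noisy - clean)^2)
    }
    dev / 5
  }, numeric(1))
  expect_true(all(diff(msd) > 0))
})

test_that("summary statistics follow the documented conventions", {
  s <- summarize_lengths(c(2, 2, 2, 2))
  expect_equal(s$mean, 2); expect_equal(s$sd, 0)
  s2 <- summarize_lengths(c(1, 2, 3))
  expect_equal(s2$mean, 2); expect_equal(s2$sd, 1)
  expect_equal(summarize_lengths(c(1, 2, 3, 4, 5))$skewness, 0)
  # excess kurtosis of a symmetric two-point sample is -2
  expect_equal(summarize_lengths(c(-1, 1, -1, 1))$kurtosis, -2)
  expect_error(summarize_lengths(3), "at least 2")
})

test_that("wide CSV round-trips a cohort", {
  co <- small_cohort(5)
  f <- withr::local_tempfile(fileext = ".csv")
  write_spectra_csv(co, f)
  back <- read_spectra_csv(f)
  expect_equal(back$wavelengths, co$wavelengths)
  expect_equal(back$target, co$target, tolerance = 1e-12)
  expect_equal(unname(back$absorbance), unname(co$absorbance),
               tolerance = 1e-12)
  expect_identical(as.character(back$set), as.character(co$set))
  expect_equal(back$metadata$ring, co$metadata$ring)
})

test_that("degenerate configurations are rejected", {
  expect_error(cohort_config(band_centers = c(300, 1965)), "350")
  expect_error(cohort_config(noise_sd = -1))
  expect_error(simulate_cohort(cohort_config(n_samples = 1000L)),
               "exceeds")
  expect_error(cohort_config(split_fraction = 1.2))
})
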