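test_that("diagnostics match hand-derived toy cases", {
  d <- prediction_diagnostics(c(1, 2, 3), c(1.1, 1.9, 3.2))
  expect_equal(d$r2, 0.97, tolerance = 1e-10)
  expect_equal(d$rmse, sqrt(0.06 / 3), tolerance = 1e-10)
  expect_equal(d$rmse, 0.14142, tolerance = 1e-4)
  expect_equal(d$mape, (10 + 5 + 20 / 3) / 3, tolerance = 1e-10)
  expect_equal(d$mape, 7.2222, tolerance = 1e-4)

  # bias-corrected standard error and RPD: residuals (0.1, -0.1), SD 0.667
  d2 <- prediction_diagnostics(c(1, 2), c(0.9, 2.1), sd_reference = 0.667)
  expect_equal(d2$sec, sqrt(0.02 / 1), tolerance = 1e-10)
  expect_equal(d2$rpd, 0.667 / sqrt(0.02), tolerance = 1e-10)
  expect_equal(d2$rpd, 4.717, tolerance = 1e-3)

  e <- suppressWarnings(prediction_diagnostics(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(e$r2, 1)
  expect_equal(e$rpd, Inf)
  expect_equal(e$rmse, 0)
  expect_equal(e$mape, 0)
  expect_warning(prediction_diagnostics(c(1, 2, 3), c(0.5, 1.5, 2.5)),
                 "Inf")
  expect_error(prediction_diagnostics(c(0, 1), c(0, 1)), "MAPE")
  expect_error(prediction_diagnostics(2, 2), "at least 2")
})

test_that("diagnostics invariances and inequalities hold", {
  set.seed(6)
  y <- runif(30, 2, 5); yh <- y + rnorm(30, 0.1, 0.2)
  a <- prediction_diagnostics(y, yh)
  b <- prediction_diagnostics(y + 10, yh + 10)
  expect_equal(a$r2, b$r2, tolerance = 1e-12)
  expect_equal(a$rmse, b$rmse, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(a$mape, b$mape)))  # MAPE is scale-bound
  n <- a$n
  expect_lte(a$sec, a$rmse * sqrt(n / (n - 1)) + 1e-12)
  # constant prediction at the sample mean has R2 = 0
  expect_equal(prediction_diagnostics(y, rep(mean(y), 30))$r2, 0,
               tolerance = 1e-12)
})

test_that("PLS matches least squares at full rank and fits one band exactly", {
  set.seed(13)
  X <- matrix(rnorm(40 * 6), 40)
  beta <- c(1, -2, 0.5, 0, 3, -1)
  y <- 2 + X %*% beta + rnorm(40, sd = 0.3)
  m <- fit_pls(X, y, n_components = 6)
  ols <- stats::lm.fit(cbind(1, X), as.numeric(y))
  expect_equal(predict(m, X),
               as.numeric(cbind(1, X) %*% ols$coefficients),
               tolerance = 1e-6)

  # response affine in a single band, no noise: one component is exact
  prof <- exp(-((1:64) - 30)^2 / 50)
  amp <- runif(25, 1, 4)
  Xb <- outer(amp, prof) + 0.2
  yb <- 5 + 2 * amp
  m1 <- fit_pls(Xb, yb, n_components = 1)
  expect_equal(predict(m1, Xb), yb, tolerance = 1e-8)
})

test_that("PLS prediction is affine and centered correctly", {
  set.seed(17)
  X <- matrix(rnorm(30 * 20), 30)
  y <- rnorm(30, 3, 0.4)
  m <- fit_pls(X, y, n_components = 4)
  # training mean spectrum predicts the training mean response
  expect_equal(predict(m, matrix(colMeans(X), 1)), mean(y),
               tolerance = 1e-8)
  expect_equal(predict(m, X), m$fitted, tolerance = 1e-12)
  x1 <- X[1, , drop = FALSE]; x2 <- X[2, , drop = FALSE]
  al <- 0.3
  expect_equal(predict(m, al * x1 + (1 - al) * x2),
               al * predict(m, x1) + (1 - al) * predict(m, x2),
               tolerance = 1e-8)
  expect_error(predict(m, X[, 1:10]), "grid mismatch")
  expect_error(fit_pls(X, rep(2, 30), 2), "zero-variance")
})

test_that("noiseless synthetic cohorts are recovered almost perfectly", {
  cfg <- cohort_config(noise_sd = 0, drift_amplitude = 0, scatter_sd = 0,
                       band_jitter_sd = 0, nuisance_amp_sd = 0,
                       n_samples = 60L, n_trees = 3L, seed = 2)
  co <- simulate_cohort(cfg)
  cal <- cohort_split(co, "calibration")
  m <- suppressWarnings(fit_pls(cal$X, cal$y, n_components = 3))
  expect_gte(prediction_diagnostics(cal$y, m$fitted)$r2, 0.999)
})

test_that("default cohorts land in the study's calibration regime", {
  r2 <- vapply(1:5, function(s) {
    cal <- cohort_split(default_cohort(s), "calibration")
    m <- fit_pls(cal$X, cal$y, n_components = 7)
    prediction_diagnostics(cal$y, m$fitted)$r2
  }, numeric(1))
  expect_true(all(r2 > 0.7))
  expect_true(all(r2 < 0.95))
})
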