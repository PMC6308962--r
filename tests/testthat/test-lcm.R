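test_that("level correlations match direct Pearson computation", {
  target <- c(2, 4, 5)
  M1 <- cbind(c(1, 2, 3), target, -target)        # col2 affine+, col3 affine-
  map <- level_correlations(list(M1), target)
  expect_equal(map$r_matrix[1, 2], 1)
  expect_equal(map$r_matrix[1, 3], -1)
  # hand-computed Pearson r for ([1,2,3], [2,4,5])
  expect_equal(map$r_matrix[1, 1], 0.9820, tolerance = 1e-4)
  expect_equal(map$r_matrix[1, 1], cor(c(1, 2, 3), target))
})

test_that("zero-variance columns yield r = 0 with a warning", {
  target <- c(1, 2, 3)
  M <- cbind(rep(5, 3), target)
  expect_warning(map <- level_correlations(list(M), target),
                 "zero-variance")
  expect_equal(map$r_matrix[1, ], c(0, 1))
})

test_that("level selection maximizes |r| with ties to the smaller level", {
  target <- c(1, 2, 3, 5)
  # build three levels where column correlations are controlled
  base <- cbind(c(1, 2, 3, 4), c(4, 3, 2, 1))
  lv1 <- base; lv2 <- base; lv3 <- base
  lv2[, 1] <- -target            # strongest |r| at level 2, column 1
  lv3[, 2] <- target             # strongest |r| at level 3, column 2
  map <- select_levels(level_correlations(list(lv1, lv2, lv3), target))
  expect_equal(map$chosen_level[1], 2)
  expect_equal(map$chosen_level[2], 3)
  # single level: everything selects level 1
  m1 <- select_levels(level_correlations(list(lv1), target))
  expect_true(all(m1$chosen_level == 1))
  # identical levels: all ties resolve to level 1
  mt <- select_levels(level_correlations(list(lv1, lv1, lv1), target))
  expect_true(all(mt$chosen_level == 1))
  # signed criterion picks the most positive r
  ms <- select_levels(level_correlations(list(lv1, lv2, lv3), target),
                      signed = TRUE)
  expect_equal(ms$chosen_level[1], 1)   # level 2 has r = -1
})

test_that("hybrid construction is a pure per-column selection", {
  A <- matrix(1:6, 2); B <- matrix(101:106, 2)
  H <- construct_hybrid(list(A, B), c(1, 2, 1))
  expect_equal(H[, 1], A[, 1])
  expect_equal(H[, 2], B[, 2])
  expect_equal(H[, 3], A[, 3])
  expect_equal(construct_hybrid(list(A, B), rep(2, 3)), B)
  expect_error(construct_hybrid(list(A, B), c(1, 3, 1)), "out of range")
  # every hybrid value exists verbatim in one of the inputs
  expect_true(all(H %in% c(A, B)))
})

test_that("hybrid |r| equals the columnwise max of the level |r| matrix", {
  set.seed(21)
  target <- rnorm(12, 3, 0.5)
  levels <- lapply(1:3, function(j) {
    M <- matrix(rnorm(12 * 6), 12)
    M[, j] <- target * j + rnorm(12, sd = 0.2)  # plant signal per level
    M
  })
  map <- select_levels(level_correlations(levels, target))
  H <- construct_hybrid(levels, map)
  r_h <- abs(as.numeric(cor(H, target)))
  expect_equal(r_h, apply(abs(map$r_matrix), 2, max), tolerance = 1e-12)
  # brute force: no single fixed level beats the hybrid anywhere
  for (j in 1:3)
    expect_true(all(r_h >= abs(map$r_matrix[j, ]) - 1e-12))
})

test_that("the selection map is fitted on calibration data only", {
  set.seed(33)
  Xc <- matrix(rnorm(20 * 64), 20)
  yc <- rnorm(20, 3, 0.5)
  Xp <- matrix(rnorm(8 * 64), 8)
  a <- lcm_pretreat(Xc, yc, Xp, wavelet = "db2", k = 3)
  # a different prediction set must not change the fitted map or the
  # calibration hybrid (no leakage from held-out data)
  b <- lcm_pretreat(Xc, yc, matrix(rnorm(8 * 64), 8), wavelet = "db2",
                    k = 3)
  expect_identical(a$map$chosen_level, b$map$chosen_level)
  expect_identical(a$cal, b$cal)
  # prediction rows use the calibration-fitted selection verbatim
  pred_levels <- lapply(1:3, function(j)
    lwt_denoise_matrix(Xp, "db2", level = j, mode = "hard"))
  expect_equal(a$pred, construct_hybrid(pred_levels, a$map))
})
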