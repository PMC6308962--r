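test_that("filter banks satisfy orthonormality and QMF structure", {
  for (wn in c("db1", "db2", "db5", "db8", "sym5")) {
    w <- wavelet_filters(wn)
    expect_equal(sum(w$rec_lo^2), 1, tolerance = 1e-12)
    expect_equal(sum(w$rec_lo), sqrt(2), tolerance = 1e-12)
    # shifted-by-two self-orthogonality
    L <- length(w$rec_lo)
    for (s in seq_len(max(L %/% 2 - 1, 0)) * 2)
      expect_equal(sum(w$rec_lo[1:(L - s)] * w$rec_lo[(s + 1):L]), 0,
                   tolerance = 1e-10)
    expect_equal(w$dec_lo, rev(w$rec_lo))
  }
  # biorthogonal pair: unit DC gain on both sides, rbio = swapped bank
  w <- wavelet_filters("bior5.5")
  expect_false(w$orthogonal)
  expect_equal(sum(w$dec_lo), sqrt(2), tolerance = 1e-10)
  expect_equal(sum(w$rec_lo), sqrt(2), tolerance = 1e-10)
  wr <- wavelet_filters("rbio5.5")
  expect_equal(wr$dec_lo, rev(w$rec_lo))
  expect_equal(wr$rec_lo, rev(w$dec_lo))
  expect_error(wavelet_filters("db9"), "unsupported")
  expect_error(wavelet_filters("haar"), "unsupported")
})

test_that("zero and constant signals decompose as theory dictates", {
  z <- forward_lwt(rep(0, 64), "sym5", level = 3)
  expect_equal(z$approximation, rep(0, 8))
  expect_true(all(vapply(z$details, function(d) all(d == 0), TRUE)))

  cst <- forward_lwt(rep(2.5, 32), "db1", level = 1)
  expect_equal(cst$details[[1]], rep(0, 16))
  expect_equal(cst$approximation, rep(2.5 * sqrt(2), 16))

  # constants live entirely in the approximation: zeroing details of a
  # constant's decomposition reconstructs the constant exactly
  d <- forward_lwt(rep(1.7, 64), "db4", level = 4)
  d$details <- lapply(d$details, function(v) v * 0)
  expect_equal(inverse_lwt(d), rep(1.7, 64), tolerance = 1e-10)
})

test_that("round trip is exact for every wavelet, level and length", {
  set.seed(101)
  for (wn in supported_wavelets()) {
    tol <- if (wavelet_filters(wn)$orthogonal) 1e-8 else 1e-6
    for (n in c(64, 256, 2048)) {
      x <- rnorm(n)
      for (lev in 1:5) {
        for (p in c("lifting", "filterbank")) {
          d <- forward_lwt(x, wn, level = lev, path = p)
          expect_lt(max(abs(inverse_lwt(d) - x)), tol)
        }
      }
    }
  }
})

test_that("lifting path equals the convolution filter-bank oracle", {
  set.seed(7)
  for (wn in supported_wavelets()) {
    w <- wavelet_filters(wn)
    worst <- 0
    for (r in 1:100) {
      x <- rnorm(sample(c(64, 256), 1))
      a <- tracheidnir:::dwt_step(x, w)
      b <- tracheidnir:::lift_step(x, w)
      worst <- max(worst, abs(a$ca - b$ca), abs(a$cd - b$cd))
    }
    expect_lt(worst, 1e-8)
  }
})

test_that("transform is linear and orthogonal families preserve energy", {
  set.seed(11)
  x <- rnorm(256); y <- rnorm(256)
  for (wn in c("db2", "db7", "sym5", "bior5.5")) {
    dx <- forward_lwt(x, wn, 3); dy <- forward_lwt(y, wn, 3)
    dz <- forward_lwt(2 * x - 3 * y, wn, 3)
    expect_lt(max(abs(dz$approximation -
                        (2 * dx$approximation - 3 * dy$approximation))),
              1e-8)
    for (j in 1:3)
      expect_lt(max(abs(dz$details[[j]] -
                          (2 * dx$details[[j]] - 3 * dy$details[[j]]))),
                1e-8)
  }
  for (wn in c("db1", "db3", "db8", "sym5")) {
    d <- forward_lwt(x, wn, 5)
    e <- sum(d$approximation^2) + sum(unlist(d$details)^2)
    expect_equal(e, sum(x^2), tolerance = 1e-6)
  }
})

test_that("invalid depth and malformed coefficients are rejected", {
  expect_error(forward_lwt(rnorm(8), "db2", level = 4), "too deep")
  expect_error(forward_lwt(rnorm(63), "db2", level = 1), "too deep")
  d <- forward_lwt(rnorm(64), "db2", 2)
  d$details[[1]] <- d$details[[1]][-1]
  expect_error(inverse_lwt(d), "inconsistent")
  expect_equal(max_dwt_level(2048), 11)
  expect_equal(max_dwt_level(96), 5)
  expect_equal(max_dwt_level(7), 0)
})
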