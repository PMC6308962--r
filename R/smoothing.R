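# Baseline smoothers used as de-noising comparators. All four operate on
# a window of `segment_size` consecutive channels (the spectra live on an
# equally spaced 1 nm grid, so a fractional span and a point-count window
# are the same thing):
#   moving_average  centered mean, window truncated at the edges
#   savitzky_golay  local least-squares polynomial, uniform weights
#   loess           local quadratic regression, tricube weights
#   lowess          local linear regression, tricube weights
# Edge policy for the polynomial methods: fit on the truncated window and
# evaluate at the boundary point (no padding).

validate_smoother <- function(segment_size, poly_order) {
  if (segment_size %% 2 != 1 || segment_size < 3 || segment_size > 25)
    stop("segment_size must be odd and in [3, 25]")
  if (poly_order >= segment_size)
    stop("poly_order must be < segment_size")
  invisible(TRUE)
}

# tricube weights on integer offsets, normalized so the farthest point in
# the window keeps a small positive weight (keeps 3-point fits well-posed)
tricube_weights <- function(offsets) {
  dmax <- max(abs(offsets)) + 1
  (1 - (abs(offsets) / dmax)^3)^3
}

# equivalent-kernel row of a weighted polynomial fit evaluated at offset 0
local_poly_kernel <- function(offsets, degree, weights) {
  Xd <- outer(offsets, 0:degree, "^")
  WX <- Xd * weights
  H <- solve(crossprod(Xd, WX), t(WX))
  H[1, ]   # value of the fit at x = 0 (intercept row)
}

# local polynomial smoother with per-edge kernels precomputed
local_poly_smooth <- function(x, segment_size, degree, tricube) {
  n <- length(x)
  half <- (segment_size - 1L) %/% 2L
  wfun <- if (tricube) tricube_weights else function(off) rep(1, length(off))
  off <- (-half):half
  kern <- local_poly_kernel(off, degree, wfun(off))
  out <- numeric(n)
  idx <- (half + 1L):(n - half)
  # interior: one shared kernel, applied as a dot product over the window
  Xe <- stats::embed(x, segment_size)      # rows: x[i+half] ... x[i-half]
  out[idx] <- as.numeric(Xe %*% rev(kern))
  # edges: truncated window, its own kernel per offset
  for (i in seq_len(half)) {
    off_l <- (1L - i):half
    deg_l <- min(degree, length(off_l) - 1L)   # truncated window can be
    kl <- local_poly_kernel(off_l, deg_l, wfun(off_l))  # shorter than deg+1
    out[i] <- sum(kl * x[(i + off_l)])
    off_r <- (-half):(i - 1L)
    kr <- local_poly_kernel(off_r, deg_l, wfun(off_r))
    out[n - i + 1L] <- sum(kr * x[(n - i + 1L) + off_r])
  }
  out
}

#' Smooth a spectrum with one of the comparator methods
#'
#' @param x numeric spectrum (length > \code{segment_size}).
#' @param method one of \code{"moving_average"}, \code{"savitzky_golay"},
#'   \code{"loess"}, \code{"lowess"}.
#' @param segment_size odd window length in channels, 3..25.
#' @param poly_order polynomial order for Savitzky-Golay (default 2; loess
#'   and lowess are fixed at 2 and 1 by definition).
#' @return smoothed vector, same length as \code{x}.
#' @examples
#' smooth_spectrum(c(1, 2, 3, 4, 5), "moving_average", 3)
#' @export
smooth_spectrum <- function(x, method = c("moving_average",
                                          "savitzky_golay",
                                          "loess", "lowess"),
                            segment_size = 3L, poly_order = 2L) {
  method <- match.arg(method)
  validate_smoother(segment_size, poly_order)
  n <- length(x)
  if (n <= segment_size) stop("spectrum shorter than segment")
  half <- (segment_size - 1L) %/% 2L
  switch(method,
    moving_average = {
      # truncated centered mean via cumulative sums
      cs <- cumsum(c(0, x))
      lo <- pmax(seq_len(n) - half, 1L)
      hi <- pmin(seq_len(n) + half, n)
      (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
    },
    savitzky_golay = signal::sgolayfilt(x, p = poly_order,
                                        n = segment_size),
    loess = local_poly_smooth(x, segment_size, degree = 2L,
                              tricube = TRUE),
    lowess = local_poly_smooth(x, segment_size, degree = 1L,
                               tricube = TRUE)
  )
}

#' Smooth every spectrum in a matrix
#'
#' Row-wise \code{\link{smooth_spectrum}}.
#'
#' @param X samples x wavelengths matrix.
#' @inheritParams smooth_spectrum
#' @return matrix of the same shape and dimnames.
#' @export
smooth_matrix <- function(X, method, segment_size = 3L, poly_order = 2L) {
  stopifnot(is.matrix(X))
  out <- t(apply(X, 1L, smooth_spectrum, method = method,
                 segment_size = segment_size, poly_order = poly_order))
  dimnames(out) <- dimnames(X)
  out
}
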