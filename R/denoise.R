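#' Robust noise-level estimate from finest-scale detail coefficients
#'
#' \eqn{\hat\sigma = \mathrm{median}(|d|) / 0.6745}, the usual MAD-based
#' estimator: for white Gaussian noise the finest detail coefficients are
#' (nearly) pure noise and the median of absolute values is robust to the
#' sparse signal content.
#'
#' @param finest_details numeric vector of level-1 detail coefficients.
#' @return estimated noise standard deviation (>= 0).
#' @export
estimate_sigma <- function(finest_details) {
  if (length(finest_details) == 0) stop("empty detail vector")
  stats::median(abs(finest_details)) / 0.6745
}

#' Universal (global fixed) threshold
#'
#' Donoho--Johnstone universal rule \eqn{\lambda = \sigma \sqrt{2 \ln n}},
#' with \code{n} the signal length. One such threshold is shared by all
#' detail levels ("global fixed").
#'
#' @param sigma noise standard deviation, >= 0.
#' @param n signal length, >= 2.
#' @return threshold value.
#' @export
universal_threshold <- function(sigma, n) {
  stopifnot(sigma >= 0)
  if (n < 2) stop("n must be >= 2")
  sigma * sqrt(2 * log(n))
}

#' Hard or soft coefficient shrinkage
#'
#' Hard: coefficients with \eqn{|w| \le \lambda} are zeroed, the rest kept
#' (ties map to zero). Soft: \eqn{\mathrm{sign}(w)\max(|w|-\lambda, 0)}.
#'
#' @param coeffs numeric coefficient vector.
#' @param lambda threshold, >= 0.
#' @param mode \code{"hard"} (default) or \code{"soft"}.
#' @return shrunken coefficient vector.
#' @export
apply_threshold <- function(coeffs, lambda, mode = c("hard", "soft")) {
  mode <- match.arg(mode)
  if (lambda < 0) stop("lambda must be >= 0")
  if (mode == "hard") {
    ifelse(abs(coeffs) <= lambda, 0, coeffs)
  } else {
    sign(coeffs) * pmax(abs(coeffs) - lambda, 0)
  }
}

#' De-noise a signal by lifting wavelet shrinkage
#'
#' Decomposes the signal to depth \code{level}, estimates the noise sd
#' from the finest details (\code{\link{estimate_sigma}}), forms one
#' global threshold \code{\link{universal_threshold}} and applies it to
#' every detail level (the approximation is untouched), then reconstructs.
#'
#' @param x numeric signal, length divisible by \code{2^level}.
#' @param wavelet wavelet name or \code{wavelet_spec}.
#' @param level decomposition depth k, >= 1.
#' @param mode threshold mode, \code{"hard"} (default) or \code{"soft"}.
#' @param path transform path, \code{"lifting"} (default) or
#'   \code{"filterbank"}.
#' @param lambda optional fixed threshold overriding the universal rule.
#' @return de-noised signal, same length as \code{x}.
#' @examples
#' set.seed(1)
#' x <- sin(seq(0, 6 * pi, length.out = 256)) + rnorm(256, sd = 0.1)
#' y <- lwt_denoise(x, "db2", level = 4)
#' @export
lwt_denoise <- function(x, wavelet, level, mode = c("hard", "soft"),
                        path = c("lifting", "filterbank"), lambda = NULL) {
  mode <- match.arg(mode)
  path <- match.arg(path)
  d <- forward_lwt(x, wavelet, level = level, path = path)
  if (is.null(lambda)) {
    sigma <- estimate_sigma(d$details[[1L]])
    lambda <- universal_threshold(sigma, length(x))
  }
  d$details <- lapply(d$details, apply_threshold, lambda = lambda,
                      mode = mode)
  inverse_lwt(d)
}

#' De-noise every spectrum in a matrix
#'
#' Applies \code{\link{lwt_denoise}} row-wise (one row = one spectrum).
#'
#' @param X samples x wavelengths numeric matrix.
#' @inheritParams lwt_denoise
#' @return matrix of the same shape and dimnames.
#' @export
lwt_denoise_matrix <- function(X, wavelet, level, mode = c("hard", "soft"),
                               path = c("lifting", "filterbank")) {
  mode <- match.arg(mode)
  path <- match.arg(path)
  stopifnot(is.matrix(X))
  out <- t(apply(X, 1L, lwt_denoise, wavelet = wavelet, level = level,
                 mode = mode, path = path))
  dimnames(out) <- dimnames(X)
  out
}
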