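#' Construct a Daubechies orthonormal scaling filter
#'
#' Builds the minimum-phase (extremal-phase) Daubechies filter of order
#' \code{N} (filter length \code{2N}) by spectral factorization: the
#' half-band polynomial \eqn{P(y) = \sum_{k=0}^{N-1} \binom{N-1+k}{k} y^k}
#' is factored and the roots inside the unit circle are kept, which yields
#' the conventional dbN coefficients (db1 = Haar).
#'
#' @param N vanishing moments, integer in 1..8 (longer orders work but are
#'   not part of the supported set).
#' @return numeric vector of length \code{2N}: the synthesis (reconstruction)
#'   lowpass filter, normalized so its sum is \eqn{\sqrt 2}.
#' @keywords internal
daubechies_filter <- function(N) {
  stopifnot(N >= 1, N == round(N))
  if (N == 1) return(c(1, 1) / sqrt(2))
  # P(y) coefficients, ascending powers
  k <- 0:(N - 1)
  P <- choose(N - 1 + k, k)
  yroots <- polyroot(P)
  # map each root y -> z via y = (2 - z - 1/z)/4; keep |z| < 1
  zroots <- vapply(yroots, function(y) {
    b <- 2 - 4 * y               # z^2 - b z + 1 = 0
    disc <- sqrt(b^2 - 4 + 0i)
    z1 <- (b + disc) / 2
    z2 <- (b - disc) / 2
    if (Mod(z1) < 1) z1 else z2
  }, complex(1))
  # h(z) = c * (1 + z)^N * prod(z - z_i); build coefficients by convolution
  h <- 1 + 0i
  for (i in seq_len(N)) h <- convolve_poly(h, c(1, 1))
  for (z0 in zroots) h <- convolve_poly(h, c(-z0, 1))
  h <- Re(h)
  h <- h * sqrt(2) / sum(h)
  # extremal-phase convention: energy concentrated at the front
  if (which.max(abs(h)) > length(h) / 2) h <- rev(h)
  h
}

# plain polynomial product (ascending coefficient vectors)
convolve_poly <- function(a, b) {
  out <- rep(0 + 0i, length(a) + length(b) - 1)
  for (i in seq_along(a)) {
    idx <- i:(i + length(b) - 1)
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

# Published least-asymmetric (symlet) order-5 synthesis lowpass filter.
SYM5_REC_LO <- c(
  0.019538882735286728, -0.021101834024758855, -0.17532808990845047,
  0.01660210576452232, 0.6339789634582119, 0.7234076904024206,
  0.1993975339773936, -0.039134249302383094, 0.029519490925774643,
  0.027333068345077982
)

# Published bior5.5 filter pair (CDF-style biorthogonal, 5/5 vanishing
# moments): decomposition lowpass (analysis side, length 12 with alignment
# zeros) and reconstruction lowpass (synthesis side).
BIOR55_DEC_LO <- c(
  0, 0, 0.03968708834740544, 0.007948108637240322,
  -0.05446378846823691, 0.34560528195603346, 0.7366601814282105,
  0.34560528195603346, -0.05446378846823691, 0.007948108637240322,
  0.03968708834740544, 0
)
BIOR55_REC_LO <- c(
  0.013456709459118716, -0.002694966880111507, -0.13670658466432914,
  -0.09350469740093886, 0.47680326579848425, 0.8995061097486484,
  0.47680326579848425, -0.09350469740093886, -0.13670658466432914,
  -0.002694966880111507, 0.013456709459118716, 0
)

#' Filter bank for a supported mother wavelet
#'
#' Returns the four-filter analysis/synthesis bank of a wavelet, in the
#' quadrature-mirror convention used throughout the package:
#' \code{dec_lo = rev(rec_lo)}, \code{dec_hi[i] = (-1)^i rec_lo[i]} and
#' \code{rec_hi[i] = (-1)^{i-1} dec_lo[i]} (1-based \code{i}).
#'
#' Supported wavelets: \code{db1}..\code{db8}, \code{sym5}, \code{bior5.5}
#' and \code{rbio5.5} (the latter is \code{bior5.5} with analysis and
#' synthesis banks exchanged).
#'
#' @param wavelet character name, e.g. \code{"db2"}.
#' @return object of class \code{wavelet_spec}: a list with \code{name},
#'   \code{dec_lo}, \code{dec_hi}, \code{rec_lo}, \code{rec_hi} and the
#'   logical \code{orthogonal}.
#' @examples
#' w <- wavelet_filters("db2")
#' sum(w$rec_lo^2)  # orthonormal: 1
#' @export
wavelet_filters <- function(wavelet) {
  stopifnot(is.character(wavelet), length(wavelet) == 1)
  if (grepl("^db[1-8]$", wavelet)) {
    rec_lo <- daubechies_filter(as.integer(sub("db", "", wavelet)))
    dec_lo <- rev(rec_lo)
    orth <- TRUE
  } else if (wavelet == "sym5") {
    rec_lo <- SYM5_REC_LO
    dec_lo <- rev(rec_lo)
    orth <- TRUE
  } else if (wavelet == "bior5.5") {
    rec_lo <- BIOR55_REC_LO
    dec_lo <- BIOR55_DEC_LO
    orth <- FALSE
  } else if (wavelet == "rbio5.5") {
    rec_lo <- rev(BIOR55_DEC_LO)
    dec_lo <- rev(BIOR55_REC_LO)
    orth <- FALSE
  } else {
    stop("unsupported wavelet: ", wavelet)
  }
  n <- seq_along(rec_lo)
  dec_hi <- ifelse(n %% 2 == 0, 1, -1) * rec_lo   # (-1)^i, 1-based
  rec_hi <- ifelse(n %% 2 == 0, -1, 1) * dec_lo
  structure(
    list(name = wavelet, dec_lo = dec_lo, dec_hi = dec_hi,
         rec_lo = rec_lo, rec_hi = rec_hi, orthogonal = orth),
    class = "wavelet_spec"
  )
}

#' Names of the supported mother wavelets
#' @return character vector.
#' @export
supported_wavelets <- function() {
  c(paste0("db", 1:8), "sym5", "bior5.5", "rbio5.5")
}
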