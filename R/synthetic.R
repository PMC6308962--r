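#' Configuration for a synthetic larch-like cohort
#'
#' Defaults emulate the design of the study the package models: 7 trees
#' of final ring 40-43, spectra taken per ring (every ring up to 20, every
#' second ring from 21), 164 ring samples in total split 117/47 into
#' calibration and prediction sets, tracheid length rising with ring
#' number along a saturating (Gompertz) curve and plateauing past ring
#' ~23, and Vis-NIR-like absorbance spectra on the 350-2397 nm, 1 nm grid
#' (2048 channels) built from Gaussian absorption bands, two of which
#' (1415 and 2315 nm) are linked to tracheid length.
#'
#' @param n_trees number of trees.
#' @param ring_range integer range the per-tree final ring is drawn from.
#' @param n_samples cohort size after seeded subsampling of the pooled
#'   ring list (164 reproduces the study; NULL keeps every ring sample).
#' @param split_fraction calibration share; counts are fixed by
#'   \code{round(split_fraction * n)} (0.713 gives 117/47 at n = 164).
#' @param growth list of radial growth-curve parameters: \code{pith} and
#'   \code{asym} (mm), \code{rate} and \code{midpoint} (Gompertz shape),
#'   \code{asym_sd} (between-tree sd of the asymptote, mm) and
#'   \code{noise_sd} (within-ring observation sd, mm).
#' @param band_centers nm positions of the absorption bands; the first two
#'   are target-linked.
#' @param band_widths,band_amp0,band_amp_slope Gaussian band shape: width
#'   (nm), base amplitude and amplitude change per mm of tracheid length
#'   (zero slope = fixed band).
#' @param band_jitter_sd per-sample sd of the target-linked band
#'   amplitudes (irreducible spectral noise that bounds attainable R2).
#' @param nuisance_amp_sd per-sample sd of the amplitudes of the
#'   non-linked bands (compositional variability unrelated to the
#'   target).
#' @param noise_sd white-noise sd, absorbance units.
#' @param drift_amplitude sd of the random per-sample low-order polynomial
#'   baseline drift, absorbance units.
#' @param scatter_sd sd of the per-sample multiplicative scatter factor.
#' @param seed integer RNG seed; fixed seed means bit-identical cohorts.
#' @return object of class \code{cohort_config} (a validated list).
#' @export
cohort_config <- function(n_trees = 7L,
                          ring_range = c(40L, 43L),
                          n_samples = 164L,
                          split_fraction = 0.713,
                          growth = list(pith = 1.95, asym = 4.00,
                                        rate = 0.15, midpoint = 6,
                                        asym_sd = 0.20, noise_sd = 0.14),
                          band_centers = c(1415, 2315, 1965, 980, 1730,
                                           620, 1114, 1306, 1450, 2100),
                          band_widths = c(32, 45, 55, 28, 38,
                                          40, 30, 26, 34, 60),
                          band_amp0 = c(0.05, 0.32, 0.38, 0.10, 0.16,
                                        0.08, 0.12, 0.10, 0.22, 0.14),
                          band_amp_slope = c(0.030, -0.022, rep(0, 8)),
                          band_jitter_sd = 0.012,
                          nuisance_amp_sd = 0.010,
                          noise_sd = 2e-5,
                          drift_amplitude = 0.02,
                          scatter_sd = 0.012,
                          seed = 1L) {
  cfg <- list(n_trees = as.integer(n_trees),
              ring_range = as.integer(ring_range),
              n_samples = if (is.null(n_samples)) NULL
                          else as.integer(n_samples),
              split_fraction = split_fraction, growth = growth,
              band_centers = band_centers, band_widths = band_widths,
              band_amp0 = band_amp0, band_amp_slope = band_amp_slope,
              band_jitter_sd = band_jitter_sd,
              nuisance_amp_sd = nuisance_amp_sd, noise_sd = noise_sd,
              drift_amplitude = drift_amplitude, scatter_sd = scatter_sd,
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  stopifnot(cfg$n_trees >= 1L,
            cfg$noise_sd >= 0, cfg$drift_amplitude >= 0,
            cfg$scatter_sd >= 0, cfg$band_jitter_sd >= 0,
            cfg$nuisance_amp_sd >= 0,
            cfg$split_fraction > 0, cfg$split_fraction < 1,
            cfg$growth$noise_sd >= 0, cfg$growth$asym > cfg$growth$pith)
  if (any(cfg$band_centers < 350 | cfg$band_centers > 2397))
    stop("band centers must lie in [350, 2397] nm")
  stopifnot(length(cfg$band_widths) == length(cfg$band_centers),
            length(cfg$band_amp0) == length(cfg$band_centers),
            length(cfg$band_amp_slope) == length(cfg$band_centers))
  invisible(cfg)
}

#' Vis-NIR wavelength grid used throughout the package
#' @return integer vector 350..2397 (2048 channels, 1 nm step).
#' @export
nir_wavelengths <- function() 350:2397

#' Noise-free radial tracheid-length profile
#'
#' Gompertz-type saturating curve anchored at the pith:
#' \deqn{f(r) = pith + (asym - pith) \frac{G(r) - G(1)}{1 - G(1)},\quad
#'       G(r) = \exp(-\exp(-rate\,(r - midpoint)))}
#' so \eqn{f(1) = pith} exactly, \eqn{f} is strictly increasing in ring
#' and approaches \code{asym}; with the default shape it rises quickly
#' over the first ~18 rings and flattens past ring ~23.
#'
#' @param ring annual ring number(s), >= 1.
#' @param tree_params list with \code{pith}, \code{asym}, \code{rate},
#'   \code{midpoint}.
#' @return tracheid length in mm (vectorized over \code{ring}).
#' @export
ring_profile <- function(ring, tree_params) {
  if (any(ring < 1)) stop("ring must be >= 1")
  p <- tree_params
  G <- function(r) exp(-exp(-p$rate * (r - p$midpoint)))
  p$pith + (p$asym - p$pith) * (G(ring) - G(1)) / (1 - G(1))
}

# deterministic (noise-free) part of one spectrum
spectrum_clean <- function(target, ring, cfg, band_amps = NULL) {
  wl <- nir_wavelengths()
  u <- (wl - 350) / 2047
  baseline <- 0.45 + 0.22 * u + 0.06 * u^2 + 0.0004 * ring
  if (is.null(band_amps))
    band_amps <- cfg$band_amp0 + cfg$band_amp_slope * target
  bands <- rep(0, length(wl))
  for (b in seq_along(cfg$band_centers))
    bands <- bands + band_amps[b] *
      exp(-(wl - cfg$band_centers[b])^2 / (2 * cfg$band_widths[b]^2))
  baseline + bands
}

#' Synthesize one Vis-NIR-like absorbance spectrum
#'
#' Deterministic core (smooth baseline + Gaussian absorption bands whose
#' first two amplitudes are affine in the target) plus, when the
#' configured magnitudes are nonzero, per-sample band-amplitude jitter,
#' random quadratic baseline drift, a multiplicative scatter factor and
#' white noise. Randomness comes from the current RNG state, so callers
#' control reproducibility with \code{set.seed}.
#'
#' @param target tracheid length, mm (> 0).
#' @param ring annual ring number.
#' @param config a \code{cohort_config}.
#' @return absorbance vector of length 2048 (log(1/R) units).
#' @export
synthesize_spectrum <- function(target, ring, config) {
  stopifnot(target > 0)
  cfg <- config
  amps <- cfg$band_amp0 + cfg$band_amp_slope * target
  linked <- cfg$band_amp_slope != 0
  jit <- ifelse(linked, cfg$band_jitter_sd, cfg$nuisance_amp_sd)
  if (any(jit > 0))
    amps <- amps + stats::rnorm(length(amps), 0, jit)
  s <- spectrum_clean(target, ring, cfg, band_amps = amps)
  if (cfg$scatter_sd > 0)
    s <- s * (1 + stats::rnorm(1, 0, cfg$scatter_sd))
  if (cfg$drift_amplitude > 0) {
    u <- seq(-1, 1, length.out = length(s))
    d <- stats::rnorm(3, 0, cfg$drift_amplitude)
    s <- s + d[1] + d[2] * u + d[3] * u^2
  }
  if (cfg$noise_sd > 0)
    s <- s + stats::rnorm(length(s), 0, cfg$noise_sd)
  s
}

#' Simulate a full ring-resolved cohort
#'
#' Draws per-tree growth curves, walks the ring-sampling rule (every ring
#' up to 20, every second ring from 21 to the tree's final ring), pools
#' the ring samples, subsamples to \code{n_samples} if the pool is larger,
#' simulates tracheid lengths and spectra, and assigns the seeded random
#' calibration / prediction split. Everything is driven by
#' \code{config$seed}: the same seed reproduces the cohort bit for bit.
#'
#' @param config a \code{cohort_config}.
#' @return object of class \code{spectra_set}: list with
#'   \code{wavelengths} (2048 nm grid), \code{absorbance} (n x 2048
#'   matrix), \code{target} (mm), \code{metadata} (data.frame:
#'   \code{sample_id}, \code{tree_id}, \code{ring}) and \code{set}
#'   (factor, \code{"calibration"} / \code{"prediction"}).
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(cohort_config(seed = 7))
#' table(cohort$set)
#' }
#' @export
simulate_cohort <- function(config = cohort_config()) {
  cfg <- validate_cohort_config(config)
  set.seed(cfg$seed)
  final_ring <- sample(seq(cfg$ring_range[1], cfg$ring_range[2]),
                       cfg$n_trees, replace = TRUE)
  trees <- lapply(seq_len(cfg$n_trees), function(i) {
    g <- cfg$growth
    g$asym <- g$asym + stats::rnorm(1, 0, g$asym_sd)
    g
  })
  design <- do.call(rbind, lapply(seq_len(cfg$n_trees), function(i) {
    rings <- c(1:20, seq(21L, final_ring[i], by = 2L))
    data.frame(tree_id = i, ring = rings)
  }))
  if (!is.null(cfg$n_samples)) {
    if (cfg$n_samples > nrow(design))
      stop("n_samples exceeds the ", nrow(design),
           " ring samples available under the sampling rule")
    design <- design[sort(sample.int(nrow(design), cfg$n_samples)), ]
  }
  n <- nrow(design)
  if (n < 4) stop("cohort too small: need at least 4 samples")
  target <- vapply(seq_len(n), function(s) {
    mu <- ring_profile(design$ring[s], trees[[design$tree_id[s]]])
    max(mu + stats::rnorm(1, 0, cfg$growth$noise_sd), 0.2)
  }, numeric(1))
  absorbance <- t(vapply(seq_len(n), function(s)
    synthesize_spectrum(target[s], design$ring[s], cfg),
    numeric(length(nir_wavelengths()))))
  colnames(absorbance) <- paste0("A", nir_wavelengths())
  n_cal <- round(cfg$split_fraction * n)
  set <- rep("prediction", n)
  set[sample.int(n, n_cal)] <- "calibration"
  structure(
    list(wavelengths = nir_wavelengths(), absorbance = absorbance,
         target = target,
         metadata = data.frame(sample_id = seq_len(n),
                               tree_id = design$tree_id,
                               ring = design$ring),
         set = factor(set, levels = c("calibration", "prediction"))),
    class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat("Vis-NIR spectra set: ", nrow(x$absorbance), " samples x ",
      ncol(x$absorbance), " channels (",
      min(x$wavelengths), "-", max(x$wavelengths), " nm)\n", sep = "")
  print(table(x$set))
  invisible(x)
}

#' Subset a spectra_set by assigned set label
#' @param cohort a \code{spectra_set}.
#' @param which \code{"calibration"} or \code{"prediction"}.
#' @return list with \code{X} (matrix) and \code{y} (vector).
#' @export
cohort_split <- function(cohort, which = c("calibration", "prediction")) {
  which <- match.arg(which)
  keep <- cohort$set == which
  list(X = cohort$absorbance[keep, , drop = FALSE],
       y = cohort$target[keep])
}

#' Summary statistics of a tracheid-length sample
#'
#' Reports n, max, min, mean, sample sd, sample skewness
#' \eqn{g_1 = m_3 / m_2^{3/2}} and excess kurtosis
#' \eqn{g_2 = m_4 / m_2^2 - 3} (central-moment conventions; the excess
#' form matches the negative kurtosis typical of plateaued growth data).
#'
#' @param values numeric vector, length >= 2.
#' @return data.frame with one row: n, max, min, mean, sd, skewness,
#'   kurtosis.
#' @export
summarize_lengths <- function(values) {
  n <- length(values)
  if (n < 2) stop("need at least 2 values")
  m <- mean(values)
  cm <- function(k) mean((values - m)^k)
  m2 <- cm(2)
  data.frame(n = n, max = max(values), min = min(values), mean = m,
             sd = stats::sd(values),
             skewness = if (m2 > 0) cm(3) / m2^1.5 else 0,
             kurtosis = if (m2 > 0) cm(4) / m2^2 - 3 else 0)
}
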