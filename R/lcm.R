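#' Per-wavelength correlations between de-noised spectra and the target
#'
#' For each decomposition depth j the spectra are de-noised to level j;
#' this function computes, for every wavelength, the Pearson correlation
#' between the level-j absorbance column and the target, giving the
#' levels x wavelengths correlation matrix that drives the local
#' correlation maximization (LCM) selection.
#'
#' @param spectra_by_level list of samples x wavelengths matrices, element
#'   j = spectra de-noised at depth j (all same shape).
#' @param target numeric response vector, length = sample count (>= 3).
#' @return object of class \code{correlation_map}: list with
#'   \code{r_matrix} (levels x wavelengths), \code{k_max} and (after
#'   \code{\link{select_levels}}) \code{chosen_level}. Zero-variance
#'   columns get r = 0 with a warning.
#' @export
level_correlations <- function(spectra_by_level, target) {
  stopifnot(is.list(spectra_by_level), length(spectra_by_level) >= 1)
  dims <- lapply(spectra_by_level, dim)
  if (length(unique(dims)) != 1) stop("matrices differ in shape")
  n <- nrow(spectra_by_level[[1]])
  stopifnot(length(target) == n, n >= 3)
  k_max <- length(spectra_by_level)
  r_matrix <- matrix(NA_real_, k_max, ncol(spectra_by_level[[1]]))
  degenerate <- FALSE
  for (j in seq_len(k_max)) {
    M <- spectra_by_level[[j]]
    sds <- apply(M, 2L, stats::sd)
    r <- rep(0, ncol(M))
    ok <- sds > 0
    if (any(!ok)) degenerate <- TRUE
    if (any(ok))
      r[ok] <- as.numeric(stats::cor(M[, ok, drop = FALSE], target))
    r_matrix[j, ] <- r
  }
  if (degenerate)
    warning("zero-variance column(s); correlation recorded as 0")
  structure(list(r_matrix = r_matrix, k_max = k_max, chosen_level = NULL),
            class = "correlation_map")
}

#' Select the best decomposition level per wavelength
#'
#' For every wavelength, picks the level whose de-noised absorbance
#' correlates most strongly with the target. The default criterion is the
#' largest \emph{absolute} correlation (a strong negative correlation is
#' equally informative for a linear calibration); \code{signed = TRUE}
#' maximizes the signed r instead. Ties go to the smaller level, i.e. the
#' least-processed signal.
#'
#' @param map a \code{correlation_map}.
#' @param signed maximize signed r instead of |r|.
#' @return the \code{correlation_map} with \code{chosen_level} filled in
#'   (integer vector, one level per wavelength).
#' @export
select_levels <- function(map, signed = FALSE) {
  stopifnot(inherits(map, "correlation_map"))
  score <- if (signed) map$r_matrix else abs(map$r_matrix)
  map$chosen_level <- apply(score, 2L, which.max)  # which.max: first tie
  map
}

#' Assemble the LCM hybrid spectrum matrix
#'
#' Pure per-wavelength selection: column w of the output is column w of
#' \code{spectra_by_level[[chosen_level[w]]]}. A selection fitted on the
#' calibration set is applied unchanged to held-out samples.
#'
#' @param spectra_by_level list of samples x wavelengths matrices.
#' @param chosen_level integer vector (one entry per wavelength) or a
#'   \code{correlation_map} with \code{chosen_level} set.
#' @return samples x wavelengths matrix.
#' @export
construct_hybrid <- function(spectra_by_level, chosen_level) {
  if (inherits(chosen_level, "correlation_map"))
    chosen_level <- chosen_level$chosen_level
  chosen_level <- as.integer(chosen_level)
  nw <- ncol(spectra_by_level[[1]])
  stopifnot(length(chosen_level) == nw)
  if (any(chosen_level < 1L | chosen_level > length(spectra_by_level)))
    stop("chosen level out of range")
  out <- spectra_by_level[[1]]
  for (w in seq_len(nw))
    out[, w] <- spectra_by_level[[chosen_level[w]]][, w]
  out
}

#' Full LCM pretreatment of a calibration / prediction split
#'
#' De-noises both sets at every depth 1..k, fits the level selection on
#' the calibration set only (the held-out target is never read), and
#' returns the hybrid matrices plus the fitted map.
#'
#' @param X_cal,y_cal calibration spectra and target.
#' @param X_pred optional prediction-set spectra.
#' @param wavelet,k,mode de-noising parameters (see
#'   \code{\link{lwt_denoise}}); \code{k} is the deepest level considered.
#' @param signed passed to \code{\link{select_levels}}.
#' @return list with \code{cal}, \code{pred} (hybrid matrices; \code{pred}
#'   NULL if not supplied) and \code{map}.
#' @export
lcm_pretreat <- function(X_cal, y_cal, X_pred = NULL, wavelet = "db2",
                         k = 4L, mode = "hard", signed = FALSE) {
  cal_levels <- lapply(seq_len(k), function(j)
    lwt_denoise_matrix(X_cal, wavelet, level = j, mode = mode))
  map <- select_levels(level_correlations(cal_levels, y_cal),
                       signed = signed)
  pred <- NULL
  if (!is.null(X_pred)) {
    pred_levels <- lapply(seq_len(k), function(j)
      lwt_denoise_matrix(X_pred, wavelet, level = j, mode = mode))
    pred <- construct_hybrid(pred_levels, map)
  }
  list(cal = construct_hybrid(cal_levels, map), pred = pred, map = map)
}
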