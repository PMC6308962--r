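# Study orchestration: wavelet-family screen, dbN order sweep, level
# sweep, smoother sweep, final four-model comparison. Every sweep fits
# PLS on (pretreated) calibration spectra only and reports the
# calibration statistics used for parameter selection; the prediction
# set is only ever scored with fitted pretreatments, never refitted.

best_row_index <- function(tab) {
  # lexicographic: highest Rc2, then lowest RMSEC, then lowest MAPEc
  order(-tab$Rc2, tab$RMSEC, tab$MAPEc)[1]
}

sweep_result <- function(tab, params) {
  structure(list(table = tab, best = tab[best_row_index(tab), ],
                 params = params),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  print(x$table, digits = 4, row.names = FALSE)
  cat("best: ", x$best$label, "\n")
  invisible(x)
}

fit_denoised <- function(cohort, wavelet, level, mode = "hard",
                         n_components = 7L, path = "lifting",
                         label = wavelet) {
  cal <- cohort_split(cohort, "calibration")
  Xd <- lwt_denoise_matrix(cal$X, wavelet, level = level, mode = mode,
                           path = path)
  model_report(Xd, cal$y, n_components = n_components, label = label)
}

#' Screen candidate mother wavelets
#'
#' De-noises the calibration spectra with each candidate wavelet at a
#' common decomposition depth and hard universal threshold, fits a PLS
#' model per wavelet, and selects the family by calibration statistics
#' (highest Rc2; ties broken by RMSEC then MAPEc).
#'
#' @param cohort a \code{spectra_set}.
#' @param wavelets candidate wavelet names (default the order-5 members
#'   of the four families).
#' @param k decomposition depth used for the screen.
#' @param n_components PLS components.
#' @return a \code{sweep_result}: \code{table} (one row per wavelet),
#'   \code{best}, \code{params}.
#' @export
screen_wavelets <- function(cohort,
                            wavelets = c("sym5", "bior5.5", "rbio5.5",
                                         "db5"),
                            k = 5L, n_components = 7L) {
  reports <- lapply(wavelets, function(wv)
    fit_denoised(cohort, wv, level = k, label = wv,
                 n_components = n_components))
  sweep_result(report_table(reports),
               list(k = k, mode = "hard", n_components = n_components))
}

#' Sweep the Daubechies order
#'
#' As \code{\link{screen_wavelets}} but over db1..db8 at fixed depth.
#'
#' @inheritParams screen_wavelets
#' @param orders integer orders N of the dbN family.
#' @return a \code{sweep_result} with rows db1..db8.
#' @export
sweep_order <- function(cohort, orders = 1:8, k = 5L, n_components = 7L) {
  reports <- lapply(orders, function(N)
    fit_denoised(cohort, paste0("db", N), level = k,
                 label = paste0("db", N), n_components = n_components))
  sweep_result(report_table(reports),
               list(k = k, mode = "hard", n_components = n_components))
}

#' Sweep the decomposition depth
#'
#' @inheritParams screen_wavelets
#' @param wavelet wavelet held fixed while the depth varies.
#' @param levels depths to evaluate.
#' @return a \code{sweep_result} with one row per depth (label
#'   \code{"k=<level>"} and a \code{level} column).
#' @export
sweep_level <- function(cohort, wavelet = "db2", levels = 1:5,
                        n_components = 7L) {
  reports <- lapply(levels, function(k)
    fit_denoised(cohort, wavelet, level = k,
                 label = paste0("k=", k), n_components = n_components))
  tab <- report_table(reports)
  tab$level <- levels
  sweep_result(tab, list(wavelet = wavelet, mode = "hard",
                         n_components = n_components))
}

#' Sweep the comparator smoothers over segment sizes
#'
#' Grid of the four baseline smoothers times odd segment sizes, each
#' fitted and scored on the calibration set.
#'
#' @inheritParams screen_wavelets
#' @param methods smoother names (see \code{\link{smooth_spectrum}}).
#' @param segments odd window lengths.
#' @return a \code{sweep_result}; the table carries \code{method} and
#'   \code{segment} columns.
#' @export
sweep_smoothers <- function(cohort,
                            methods = c("moving_average", "loess",
                                        "savitzky_golay", "lowess"),
                            segments = seq(3L, 25L, by = 2L),
                            n_components = 7L) {
  cal <- cohort_split(cohort, "calibration")
  grid <- expand.grid(method = methods, segment = segments,
                      stringsAsFactors = FALSE)
  reports <- lapply(seq_len(nrow(grid)), function(i) {
    Xs <- smooth_matrix(cal$X, grid$method[i],
                        segment_size = grid$segment[i])
    model_report(Xs, cal$y, n_components = n_components,
                 label = paste0(grid$method[i], ":", grid$segment[i]))
  })
  tab <- report_table(reports)
  tab$method <- grid$method
  tab$segment <- grid$segment
  sweep_result(tab, list(n_components = n_components))
}

#' Wavelength-wise correlation of spectra with the target
#'
#' @param X samples x wavelengths matrix.
#' @param y target vector.
#' @return numeric vector, one Pearson r per wavelength (0 where a
#'   column has zero variance).
#' @export
correlation_curve <- function(X, y) {
  sds <- apply(X, 2L, stats::sd)
  r <- rep(0, ncol(X))
  ok <- sds > 0
  r[ok] <- as.numeric(stats::cor(X[, ok, drop = FALSE], y))
  r
}

#' Final four-model comparison
#'
#' Reproduces the closing analysis of the study design: PLS models on raw
#' spectra, LWT de-noised spectra (lifting path), the LWT-LCM hybrid and
#' WT de-noised spectra (convolution filter-bank path with identical
#' parameters), each fitted on the calibration set and scored on both
#' sets; plus the cross-prediction matrix (every model scored against
#' every pretreated prediction set) and the wavelength-wise correlation
#' curves of raw / LWT / LWT-LCM calibration spectra against the target.
#'
#' @param cohort a \code{spectra_set}.
#' @param wavelet,k optimal de-noising parameters (db2, depth 4 are the
#'   study's selection).
#' @param mode threshold mode.
#' @param n_components PLS components.
#' @return list with \code{table} (4 x 11 comparison data.frame),
#'   \code{reports}, \code{cross_matrix} (models x prediction-set
#'   pretreatments, Rp2), and \code{correlation_curves} (wavelengths x
#'   {raw, lwt, lwt_lcm} matrix).
#' @export
final_comparison <- function(cohort, wavelet = "db2", k = 4L,
                             mode = "hard", n_components = 7L) {
  cal <- cohort_split(cohort, "calibration")
  pred <- cohort_split(cohort, "prediction")
  pre <- list(
    raw = list(cal = cal$X, pred = pred$X),
    lwt = list(cal = lwt_denoise_matrix(cal$X, wavelet, k, mode,
                                        path = "lifting"),
               pred = lwt_denoise_matrix(pred$X, wavelet, k, mode,
                                         path = "lifting"))
  )
  lcm <- lcm_pretreat(cal$X, cal$y, pred$X, wavelet = wavelet, k = k,
                      mode = mode)
  pre$lwt_lcm <- list(cal = lcm$cal, pred = lcm$pred)
  pre$wt <- list(cal = lwt_denoise_matrix(cal$X, wavelet, k, mode,
                                          path = "filterbank"),
                 pred = lwt_denoise_matrix(pred$X, wavelet, k, mode,
                                           path = "filterbank"))
  labels <- c("raw", "lwt", "lwt_lcm", "wt")
  reports <- lapply(labels, function(l)
    model_report(pre[[l]]$cal, cal$y, pre[[l]]$pred, pred$y,
                 n_components = n_components, label = l))
  names(reports) <- labels
  # cross matrix: model row x prediction-set pretreatment column
  # inner sapply over models -> rows; outer over pretreatments -> columns
  cross <- sapply(labels, function(lp)
    sapply(labels, function(lm)
      prediction_diagnostics(
        pred$y, predict(reports[[lm]]$model, pre[[lp]]$pred))$r2))
  dimnames(cross) <- list(model = labels, prediction_set = labels)
  curves <- cbind(raw = correlation_curve(cal$X, cal$y),
                  lwt = correlation_curve(pre$lwt$cal, cal$y),
                  lwt_lcm = correlation_curve(pre$lwt_lcm$cal, cal$y))
  list(table = report_table(reports), reports = reports,
       cross_matrix = cross, correlation_curves = curves,
       lcm_map = lcm$map)
}
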