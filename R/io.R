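#' Write a spectra set as a wide CSV
#'
#' One row per sample: \code{sample_id, tree_id, ring, set, tracheid_mm}
#' followed by one absorbance column per wavelength (\code{A350} ...
#' \code{A2397}).
#'
#' @param cohort a \code{spectra_set}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_spectra_csv <- function(cohort, path) {
  df <- data.frame(sample_id = cohort$metadata$sample_id,
                   tree_id = cohort$metadata$tree_id,
                   ring = cohort$metadata$ring,
                   set = as.character(cohort$set),
                   tracheid_mm = cohort$target)
  df <- cbind(df, as.data.frame(cohort$absorbance))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a wide-format spectra CSV
#'
#' Inverse of \code{\link{write_spectra_csv}}; wavelengths are parsed
#' from the \code{A<nm>} column names, so any contiguous grid round-trips.
#'
#' @param path CSV file.
#' @return a \code{spectra_set}.
#' @export
read_spectra_csv <- function(path) {
  df <- utils::read.csv(path, check.names = TRUE)
  wl_cols <- grep("^A[0-9]+$", names(df), value = TRUE)
  if (length(wl_cols) == 0) stop("no wavelength columns (A<nm>) found")
  wl <- as.integer(sub("^A", "", wl_cols))
  o <- order(wl)
  absorbance <- as.matrix(df[, wl_cols[o], drop = FALSE])
  structure(
    list(wavelengths = wl[o], absorbance = absorbance,
         target = df$tracheid_mm,
         metadata = data.frame(sample_id = df$sample_id,
                               tree_id = df$tree_id, ring = df$ring),
         set = factor(df$set, levels = c("calibration", "prediction"))),
    class = "spectra_set")
}
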