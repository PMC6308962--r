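#' Fit a PLS1 calibration model by NIPALS
#'
#' Univariate-response partial least squares with mean-centering only (no
#' autoscaling: absorbance channels share units). Components are extracted
#' by the NIPALS recursion — weight vector \eqn{w = X'y / \|X'y\|}, scores
#' \eqn{t = Xw}, x-loading \eqn{p = X't/(t't)}, y-loading
#' \eqn{c = y't/(t't)} — with deflation of \code{X} and \code{y} after each
#' component. Predictions use the accumulated regression vector
#' \eqn{b = W (P'W)^{-1} c}.
#'
#' @param X samples x wavelengths numeric matrix.
#' @param y numeric response vector (tracheid length, mm).
#' @param n_components number of latent variables (PCs), 1 <=
#'   \code{n_components} <= min(n-1, p). Extraction stops early with a
#'   warning if a weight vector collapses (norm < 1e-12).
#' @param label optional pretreatment tag stored with the model.
#' @return object of class \code{pls_model}: list with \code{coefficients}
#'   (regression vector on centered data), \code{intercept}, \code{x_mean},
#'   \code{y_mean}, \code{n_components}, \code{fitted}, \code{label}.
#' @examples
#' X <- matrix(rnorm(40 * 12), 40)
#' y <- X[, 3] - 2 * X[, 7] + rnorm(40, sd = 0.05)
#' m <- fit_pls(X, y, n_components = 2)
#' cor(predict(m, X), y)
#' @export
fit_pls <- function(X, y, n_components = 7L, label = "raw") {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y))
  n <- nrow(X); p <- ncol(X)
  n_components <- as.integer(n_components)
  stopifnot(n_components >= 1L, n_components <= min(n - 1L, p))
  if (stats::sd(y) == 0) stop("zero-variance response")
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  Xc <- sweep(X, 2L, x_mean)
  yc <- y - y_mean
  W <- matrix(0, p, n_components)
  P <- matrix(0, p, n_components)
  cvec <- numeric(n_components)
  a_used <- 0L
  for (a in seq_len(n_components)) {
    w <- crossprod(Xc, yc)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {
      warning("weight norm collapsed; stopping at ", a - 1L, " components")
      break
    }
    w <- w / nw
    t_score <- Xc %*% w
    tt <- sum(t_score^2)
    p_load <- crossprod(Xc, t_score) / tt
    c_load <- sum(yc * t_score) / tt
    Xc <- Xc - t_score %*% t(p_load)
    yc <- yc - c_load * t_score
    W[, a] <- w; P[, a] <- p_load; cvec[a] <- c_load
    a_used <- a
  }
  W <- W[, seq_len(a_used), drop = FALSE]
  P <- P[, seq_len(a_used), drop = FALSE]
  cvec <- cvec[seq_len(a_used)]
  b <- W %*% solve(crossprod(P, W), cvec)
  model <- structure(
    list(coefficients = as.numeric(b),
         intercept = y_mean - sum(x_mean * b),
         x_mean = x_mean, y_mean = y_mean,
         n_components = a_used, label = label),
    class = "pls_model")
  model$fitted <- predict(model, X)
  model
}

#' Predict from a fitted PLS model
#'
#' @param object a \code{pls_model}.
#' @param newdata samples x wavelengths matrix on the training wavelength
#'   grid.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$coefficients))
    stop("wavelength grid mismatch: model has ",
         length(object$coefficients), " channels, newdata has ",
         ncol(newdata))
  as.numeric(newdata %*% object$coefficients + object$intercept)
}

#' @export
print.pls_model <- function(x, ...) {
  cat("PLS1 model (", x$label, "): ", x$n_components, " components, ",
      length(x$coefficients), " channels\n", sep = "")
  invisible(x)
}

#' Fit and score one pretreatment on a calibration / prediction split
#'
#' Fits PLS on the calibration rows and evaluates
#' \code{\link{prediction_diagnostics}} on both sets; one such report row
#' per pretreatment is what model-comparison tables are built from.
#'
#' @param X_cal,y_cal calibration spectra and responses.
#' @param X_pred,y_pred prediction-set spectra and responses (optional).
#' @param n_components PLS components.
#' @param label pretreatment tag.
#' @return object of class \code{model_report}: list with \code{label},
#'   \code{n_components}, \code{calibration} and (possibly NULL)
#'   \code{validation} diagnostics, and the fitted \code{model}.
#' @export
model_report <- function(X_cal, y_cal, X_pred = NULL, y_pred = NULL,
                         n_components = 7L, label = "raw") {
  model <- fit_pls(X_cal, y_cal, n_components = n_components, label = label)
  cal <- prediction_diagnostics(y_cal, model$fitted)
  val <- NULL
  if (!is.null(X_pred))
    val <- prediction_diagnostics(y_pred, predict(model, X_pred))
  structure(list(label = label, n_components = model$n_components,
                 calibration = cal, validation = val, model = model),
            class = "model_report")
}

#' Flatten model reports into a comparison table
#'
#' @param reports list of \code{model_report} objects.
#' @return data.frame with one row per report: label, PCs, Rc2, RMSEC,
#'   MAPEc, SEC, RPDc and, when a validation set was scored, Rp2, RMSEP,
#'   SEP, RPDp.
#' @export
report_table <- function(reports) {
  rows <- lapply(reports, function(r) {
    row <- data.frame(
      label = r$label, PCs = r$n_components,
      Rc2 = r$calibration$r2, RMSEC = r$calibration$rmse,
      MAPEc = r$calibration$mape, SEC = r$calibration$sec,
      RPDc = r$calibration$rpd, stringsAsFactors = FALSE)
    if (!is.null(r$validation)) {
      row$Rp2 <- r$validation$r2
      row$RMSEP <- r$validation$rmse
      row$SEP <- r$validation$sec
      row$RPDp <- r$validation$rpd
    }
    row
  })
  do.call(rbind, rows)
}
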