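#' Calibration / prediction diagnostics for a spectroscopic model
#'
#' Computes the usual chemometric figures of merit from measured and
#' predicted values:
#' \itemize{
#'   \item \code{r2}: \eqn{1 - \sum(y_i-\hat y_i)^2 / \sum(y_i-\bar y)^2}
#'   \item \code{rmse}: \eqn{\sqrt{\sum(y_i-\hat y_i)^2 / n}} (divisor n)
#'   \item \code{mape}: \eqn{100/n \sum |y_i-\hat y_i| / y_i} in percent
#'   \item \code{sec}: standard error — sd of the bias-corrected residuals
#'     with divisor \eqn{n-1}
#'   \item \code{rpd}: \code{sd_reference / sec}
#' }
#' On a calibration set these are reported as Rc2 / RMSEC / MAPEc / SEC /
#' RPDc, on a held-out prediction set as Rp2 / RMSEP / SEP / RPDp.
#'
#' @param y measured values (strictly positive; MAPE is undefined at 0).
#' @param y_hat predicted values, same length.
#' @param sd_reference reference standard deviation used in the RPD ratio;
#'   defaults to \code{sd(y)} of the set being scored.
#' @return object of class \code{prediction_diagnostics}: list with
#'   \code{r2}, \code{rmse}, \code{mape}, \code{sec}, \code{rpd}, \code{n},
#'   \code{sd_reference}.
#' @examples
#' prediction_diagnostics(c(1, 2, 3), c(1.1, 1.9, 3.2))
#' @export
prediction_diagnostics <- function(y, y_hat, sd_reference = stats::sd(y)) {
  stopifnot(length(y) == length(y_hat))
  n <- length(y)
  if (n < 2) stop("need at least 2 observations")
  if (any(y == 0)) stop("MAPE undefined: zero reference value")
  resid <- y - y_hat
  r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  rmse <- sqrt(sum(resid^2) / n)
  mape <- 100 * mean(abs(resid / y))
  sec <- sqrt(sum((resid - mean(resid))^2) / (n - 1))
  if (sec == 0) {
    warning("zero standard error; RPD reported as Inf")
    rpd <- Inf
  } else {
    rpd <- sd_reference / sec
  }
  structure(list(r2 = r2, rmse = rmse, mape = mape, sec = sec, rpd = rpd,
                 n = n, sd_reference = sd_reference),
            class = "prediction_diagnostics")
}

#' @export
print.prediction_diagnostics <- function(x, ...) {
  cat(sprintf(
    "n = %d:  R2 = %.3f  RMSE = %.3f  MAPE = %.3f%%  SE = %.3f  RPD = %.3f\n",
    x$n, x$r2, x$rmse, x$mape, x$sec, x$rpd))
  invisible(x)
}
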