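#' Goodness-of-fit metric suite
#'
#' Computes, for a pair of observed and predicted vectors, the standard
#' validation metrics of nonlinear food-process models:
#' sum of squared errors `SSE = sum((exp - pre)^2)`,
#' root-mean-square error `RMSE = sqrt(SSE / N)`,
#' reduced chi-square `chi2 = SSE / (N - n)` with `n` the model parameter
#' count, mean bias error `MBE = mean(pre - exp)`, mean percentage error
#' `MPE = (100/N) * sum((pre - exp)/exp)` (signed), average absolute
#' relative deviation `AARD = (100/N) * sum(|pre - exp| / |exp|)`, and the
#' coefficient of determination `r2 = 1 - SSE / SST`.
#'
#' `MPE` and `AARD` are undefined (returned as `NA` with a warning) when any
#' observation is exactly zero; the remaining metrics are still computed.
#'
#' @param y_exp Observed values.
#' @param y_pre Predicted values (same length).
#' @param n_params Model parameter count used in the reduced chi-square
#'   denominator; must satisfy `N > n_params >= 0`.
#' @return Named list: `N`, `n`, `SSE`, `RMSE`, `chi2`, `MBE`, `MPE`,
#'   `AARD`, `r2`.
#' @export
fit_metrics <- function(y_exp, y_pre, n_params = 0L) {
  y_exp <- as.numeric(y_exp); y_pre <- as.numeric(y_pre)
  N <- length(y_exp)
  if (length(y_pre) != N) stop("fit_metrics: length mismatch")
  if (n_params < 0) stop("fit_metrics: n_params must be >= 0")
  if (N <= n_params) stop("fit_metrics: need N > n_params for chi-square")
  e <- y_pre - y_exp
  SSE <- sum(e^2)
  RMSE <- sqrt(SSE / N)
  chi2 <- SSE / (N - n_params)
  MBE <- mean(e)
  if (any(y_exp == 0)) {
    warning("fit_metrics: zero observation(s); MPE and AARD undefined")
    MPE <- NA_real_; AARD <- NA_real_
  } else {
    MPE <- 100 * mean(e / y_exp)
    AARD <- 100 * mean(abs(e) / abs(y_exp))
  }
  SST <- sum((y_exp - mean(y_exp))^2)
  r2 <- 1 - SSE / SST
  list(N = N, n = as.integer(n_params), SSE = SSE, RMSE = RMSE, chi2 = chi2,
       MBE = MBE, MPE = MPE, AARD = AARD, r2 = r2)
}

#' Per-response goodness-of-fit table
#'
#' Applies [fit_metrics()] column-wise to observed and predicted response
#' matrices and assembles the standard report layout (one row per response;
#' columns chi2, RMSE, MBE, MPE, SSE, AARD, r2).
#'
#' @param y_exp Observed matrix (n x responses, named columns).
#' @param y_pre Predicted matrix of the same shape.
#' @param n_params Parameter count for the reduced chi-square (e.g. the
#'   trained network's free-parameter count).
#' @return data.frame, one row per response.
#' @export
metrics_table <- function(y_exp, y_pre, n_params = 0L) {
  y_exp <- as.matrix(y_exp); y_pre <- as.matrix(y_pre)
  stopifnot(identical(dim(y_exp), dim(y_pre)))
  cn <- colnames(y_exp)
  if (is.null(cn)) cn <- paste0("V", seq_len(ncol(y_exp)))
  rows <- lapply(seq_len(ncol(y_exp)), function(j) {
    m <- withCallingHandlers(
      fit_metrics(y_exp[, j], y_pre[, j], n_params),
      warning = function(w) invokeRestart("muffleWarning"))
    data.frame(response = cn[j], chi2 = m$chi2, RMSE = m$RMSE, MBE = m$MBE,
               MPE = m$MPE, SSE = m$SSE, AARD = m$AARD, r2 = m$r2,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @rdname metrics_table
#' @param tab A [metrics_table()] result.
#' @param path CSV file path.
#' @export
write_metrics_table <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Free parameters of a weight set
#'
#' Counts weights and biases; the default `n` used in the reduced
#' chi-square for a fitted network.
#'
#' @param weights A [weight_set()].
#' @return Integer count.
#' @export
n_parameters <- function(weights) {
  stopifnot(inherits(weights, "weight_set"))
  length(weights$W1) + length(weights$B1) + length(weights$W2) + length(weights$B2)
}
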