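#' Absolute relative error in percent
#'
#' `|actual - predicted| / |actual| * 100`; undefined for a zero actual.
#'
#' @param actual,predicted Values in the same units (vectorized).
#' @return Error percentage(s).
#' @export
error_percentage <- function(actual, predicted) {
  if (any(actual == 0)) stop("relative error undefined for actual = 0")
  abs(actual - predicted) / abs(actual) * 100
}

new_metrics_report <- function(fields) {
  structure(fields, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report> n =", x$n, "\n")
  for (nm in setdiff(names(x), "n")) {
    v <- x[[nm]]
    cat(sprintf("  %-14s %s\n", nm,
                if (is.null(v) || (length(v) == 1 && is.na(v))) "-"
                else format(v, digits = 6)))
  }
  invisible(x)
}

#' Summary of per-stride relative errors
#'
#' Mean, standard deviation, minimum and maximum of the per-stride
#' absolute relative errors, expressed as ratios (multiply by 100 for the
#' percentage form). The SD uses the sample (n-1) denominator by default.
#'
#' @param actuals,predictions Equal-length numeric vectors (m); actuals
#'   must be nonzero.
#' @param population_sd Use the population (n) denominator instead.
#' @return A `metrics_report` with `mean_error`, `sd_of_errors`,
#'   `min_error`, `max_error` (ratios) and `n`.
#' @export
error_summary <- function(actuals, predictions, population_sd = FALSE) {
  if (length(actuals) != length(predictions)) stop("length mismatch")
  if (!length(actuals)) stop("empty input")
  e <- error_percentage(actuals, predictions) / 100
  n <- length(e)
  sdv <- if (n > 1L) {
    s <- stats::sd(e)
    if (population_sd) s * sqrt((n - 1) / n) else s
  } else 0
  new_metrics_report(list(mean_error = mean(e), sd_of_errors = sdv,
                          min_error = min(e), max_error = max(e), n = n))
}

#' Regression agreement metrics
#'
#' MAE, MSE, RMSE = sqrt(MSE) and the coefficient of determination
#' `R^2 = 1 - SS_res / SS_tot` (SS_tot about the mean of the actuals).
#' With zero-variance actuals the R^2 is undefined and reported as absent
#' (`NULL`), not NaN.
#'
#' @param actuals,predictions Equal-length numeric vectors (m).
#' @return A `metrics_report` with `mae`, `mse`, `rmse`, `r_squared`, `n`.
#' @export
regression_metrics <- function(actuals, predictions) {
  if (length(actuals) != length(predictions)) stop("length mismatch")
  if (!length(actuals)) stop("empty input")
  err <- actuals - predictions
  mse <- mean(err^2)
  ss_tot <- sum((actuals - mean(actuals))^2)
  r2 <- if (ss_tot > 0) 1 - sum(err^2) / ss_tot else NULL
  new_metrics_report(list(mae = mean(abs(err)), mse = mse,
                          rmse = sqrt(mse), r_squared = r2,
                          n = length(actuals)))
}
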