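#' Absolute percentage error
#'
#' `|observed - predicted| / observed * 100`. Undefined at zero observed
#' counts: by default that is an error, because silently skipping zero days
#' materially changes the resulting MAPE; callers opt in to skipping via
#' `build_report(skip_zero_days = TRUE)`.
#'
#' @param observed,predicted Numeric vectors (recycled as usual).
#' @return APE in percent.
#' @examples
#' ape(206, 194.40)  # 5.6311
#' @export
ape <- function(observed, predicted) {
  observed <- as.numeric(observed); predicted <- as.numeric(predicted)
  if (any(observed == 0)) stop("APE undefined for observed value 0")
  abs(observed - predicted) / observed * 100
}

#' Mean absolute percentage error
#'
#' The mean of per-day APEs, in percent.
#'
#' @param observed,predicted Equal-length numeric vectors, `observed != 0`.
#' @return MAPE in percent.
#' @export
mape <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    stop("`observed` and `predicted` must have equal length")
  }
  mean(ape(observed, predicted))
}

#' Mean and sample standard deviation of forecast residuals
#'
#' Residual = observed - predicted; SD uses denominator n - 1.
#'
#' @param observed,predicted Equal-length numeric vectors, n >= 2.
#' @return Named numeric `c(mean, sd)`.
#' @export
residual_moments <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    stop("`observed` and `predicted` must have equal length")
  }
  if (length(observed) < 2L) stop("residual SD needs at least 2 observations")
  r <- as.numeric(observed) - as.numeric(predicted)
  c(mean = mean(r), sd = stats::sd(r))
}

#' Evaluation report over rolling-forecast records
#'
#' For each model (ARIMA arm, SES arm, combination) computes the overall
#' MAPE, the workday MAPE (weekdays 1-5), the weekend MAPE (weekdays 6-7),
#' the per-weekday APE sequences, and the residual mean and SD. The overall
#' MAPE is the mean of ALL per-day APEs, not the mean of the two sub-MAPEs.
#'
#' @param records A `forecast_records` data frame covering whole weeks.
#' @param skip_zero_days Drop days with observed count 0 from percentage
#'   errors (they remain in the residual moments)? Default `FALSE`: a zero
#'   observed count is an error.
#' @return An object of class `evaluation_report`: a list with one element
#'   per model (`arima`, `ses`, `combined`), each carrying `overall`,
#'   `workdays`, `weekends`, `ape_by_day`, `residual_mean`, `residual_sd`;
#'   plus `n_days` and `n_skipped`.
#' @export
build_report <- function(records, skip_zero_days = FALSE) {
  if (!inherits(records, "forecast_records")) {
    stop("`records` must be a forecast_records data frame")
  }
  if (nrow(records) == 0L) stop("no records to evaluate")
  if (nrow(records) %% 7L != 0L) stop("records must cover whole weeks")
  cols <- c(arima = "pred_arima", ses = "pred_ses", combined = "pred_combined")
  zero <- records$observed == 0
  if (any(zero) && !skip_zero_days) {
    stop(sprintf("observed count is 0 on %d day(s); MAPE undefined (set skip_zero_days = TRUE to drop them)",
                 sum(zero)))
  }
  keep <- !zero
  models <- lapply(cols, function(col) {
    obs <- records$observed[keep]
    pred <- records[[col]][keep]
    a <- ape(obs, pred)
    day <- records$day[keep]
    list(
      overall = mean(a),
      workdays = mean(a[day <= 5]),
      weekends = mean(a[day >= 6]),
      ape_by_day = split(a, factor(day, levels = 1:7)),
      residual_mean = mean(records$observed - records[[col]]),
      residual_sd = stats::sd(records$observed - records[[col]])
    )
  })
  structure(c(models, list(n_days = nrow(records), n_skipped = sum(zero))),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d forecast days (%d skipped as zero)\n",
              x$n_days, x$n_skipped))
  df <- as.data.frame(x)
  df[, -1] <- round(df[, -1], 4)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.evaluation_report <- function(x, ...) {
  rows <- lapply(c("arima", "ses", "combined"), function(m) {
    data.frame(model = m, overall_mape = x[[m]]$overall,
               workdays_mape = x[[m]]$workdays, weekends_mape = x[[m]]$weekends,
               residual_mean = x[[m]]$residual_mean,
               residual_sd = x[[m]]$residual_sd)
  })
  do.call(rbind, rows)
}

#' Write an evaluation report as CSV and a text summary
#'
#' @param report An `evaluation_report`.
#' @param csv_path,txt_path Output files (`NULL` to skip either).
#' @export
write_report <- function(report, csv_path = NULL, txt_path = NULL) {
  stopifnot(inherits(report, "evaluation_report"))
  df <- as.data.frame(report)
  if (!is.null(csv_path)) {
    utils::write.csv(df, csv_path, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(txt_path)) {
    lines <- c(
      sprintf("Forecast evaluation over %d days (%d zero days skipped)",
              report$n_days, report$n_skipped),
      sprintf("%-9s overall %6.2f%%  workdays %6.2f%%  weekends %6.2f%%  resid mean %8.4f sd %8.4f",
              df$model, df$overall_mape, df$workdays_mape, df$weekends_mape,
              df$residual_mean, df$residual_sd))
    writeLines(lines, txt_path)
  }
  invisible(df)
}
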