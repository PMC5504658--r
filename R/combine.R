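#' Residual energy of a forecast arm
#'
#' `E = sqrt(sum(e^2))` over an arm's one-step residuals; the accuracy
#' indicator that drives the combination weights — the smaller an arm's
#' energy, the larger its weight.
#'
#' @param residuals Non-empty numeric vector (no `NA`).
#' @return The residual energy (>= 0).
#' @export
residual_energy <- function(residuals) {
  residuals <- as.numeric(residuals)
  if (length(residuals) == 0L) stop("`residuals` must be non-empty")
  if (anyNA(residuals)) stop("`residuals` must not contain NA")
  sqrt(sum(residuals^2))
}

#' Inverse-energy combination weights for two arms
#'
#' `l_i = E_i^{-1} / (E_1^{-1} + E_2^{-1})`, so the weights are positive and
#' sum to one. If exactly one arm has zero energy (a perfect fit) it receives
#' all the weight; both zero is a degenerate error.
#'
#' @param E1,E2 Residual energies, non-negative, not both zero.
#' @return Numeric `c(l1, l2)`.
#' @export
combine_weights <- function(E1, E2) {
  if (!is.finite(E1) || !is.finite(E2) || E1 < 0 || E2 < 0) {
    stop("energies must be finite and non-negative")
  }
  if (E1 == 0 && E2 == 0) {
    stop("both residual energies are zero: weights undefined (perfect fits)")
  }
  if (E1 == 0) return(c(l1 = 1, l2 = 0))
  if (E2 == 0) return(c(l1 = 0, l2 = 1))
  inv <- c(1 / E1, 1 / E2)
  stats::setNames(inv / sum(inv), c("l1", "l2"))
}

#' Per-weekday combination weights from training residuals
#'
#' Computes each arm's residual energy per weekday and the corresponding
#' inverse-energy weights. Arm 1 is the daily seasonal-ARIMA model (its daily
#' residual sequence sliced at the positions of each weekday, warm-up
#' excluded); arm 2 the per-weekday smoother. In the fully degenerate case
#' where BOTH arms fit a weekday exactly (zero energy each) the weights fall
#' back to one half each: any convex combination of two exact forecasts is
#' exact.
#'
#' @param arm1_residuals_by_tau,arm2_residuals_by_tau Lists of length 7,
#'   each element the residual vector of that weekday (>= 1 value).
#' @return A data frame of class `combination_weights` with columns
#'   `day, E1, E2, l1, l2`.
#' @export
compute_weights_for_origin <- function(arm1_residuals_by_tau,
                                       arm2_residuals_by_tau) {
  if (length(arm1_residuals_by_tau) != 7L || length(arm2_residuals_by_tau) != 7L) {
    stop("residual lists must have one element per weekday (7)")
  }
  rows <- lapply(1:7, function(tau) {
    r1 <- arm1_residuals_by_tau[[tau]]
    r2 <- arm2_residuals_by_tau[[tau]]
    if (length(r1) == 0L || length(r2) == 0L) {
      stop(sprintf("no residuals available for weekday %d", tau))
    }
    E1 <- residual_energy(r1)
    E2 <- residual_energy(r2)
    l <- if (E1 == 0 && E2 == 0) c(0.5, 0.5) else combine_weights(E1, E2)
    data.frame(day = tau, E1 = E1, E2 = E2, l1 = l[1], l2 = l[2])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("combination_weights", "data.frame")
  out
}

#' Weighted combination of the two arms' weekly forecasts
#'
#' `x_hat(tau) = l1(tau) * pred1(tau) + l2(tau) * pred2(tau)` — a per-weekday
#' convex combination, so every combined value lies between the two arm
#' predictions.
#'
#' @param pred1,pred2 Length-7 forecasts (weekdays 1..7) from arms 1 and 2.
#' @param weights A `combination_weights` data frame.
#' @return Length-7 combined forecast.
#' @export
combined_forecast <- function(pred1, pred2, weights) {
  stopifnot(inherits(weights, "combination_weights"))
  pred1 <- as.numeric(pred1); pred2 <- as.numeric(pred2)
  if (length(pred1) != 7L || length(pred2) != 7L) {
    stop("arm forecasts must have length 7 (one value per weekday)")
  }
  weights <- weights[order(weights$day), ]
  weights$l1 * pred1 + weights$l2 * pred2
}

#' Configuration for the rolling one-week-ahead driver
#'
#' @param train_weeks Weeks in the initial training window.
#' @param test_weeks Number of rolling test weeks, or `NULL` for all
#'   remaining weeks.
#' @param week_start Weekday opening each panel week.
#' @param spec Differencing specification for the ARIMA arm.
#' @param p_max,q_max BIC order-search bounds at the first origin.
#' @param t_threshold Significance-pruning cutoff.
#' @param alpha_grid SES smoothing-constant grid.
#' @param preprocess Apply singularity replacement to each training window?
#' @param refit_alpha Re-optimize the SES alpha at every origin (otherwise
#'   frozen at the first origin's values)?
#' @param clip_zero Floor combined forecasts at zero?
#' @return A list of class `rolling_config`.
#' @export
rolling_config <- function(train_weeks = 43L, test_weeks = NULL,
                           week_start = "Monday", spec = diff_spec(),
                           p_max = 3L, q_max = 7L, t_threshold = 1.96,
                           alpha_grid = seq(0.01, 0.99, by = 0.01),
                           preprocess = TRUE, refit_alpha = TRUE,
                           clip_zero = FALSE) {
  cfg <- list(train_weeks = as.integer(train_weeks),
              test_weeks = if (is.null(test_weeks)) NULL else as.integer(test_weeks),
              week_start = match.arg(week_start, .weekday_names),
              spec = spec, p_max = as.integer(p_max), q_max = as.integer(q_max),
              t_threshold = t_threshold, alpha_grid = alpha_grid,
              preprocess = isTRUE(preprocess), refit_alpha = isTRUE(refit_alpha),
              clip_zero = isTRUE(clip_zero))
  for (f in c("train_weeks", "p_max", "q_max")) {
    if (is.na(cfg[[f]]) || cfg[[f]] < if (f == "train_weeks") 4L else 0L) {
      stop(sprintf("invalid config field `%s`", f))
    }
  }
  if (!inherits(cfg$spec, "diff_spec")) stop("invalid config field `spec`")
  class(cfg) <- "rolling_config"
  cfg
}

# residuals of the daily arm sliced by weekday position (1-based, col 1 = day 1)
slice_residuals_by_tau <- function(residuals) {
  lapply(1:7, function(tau) {
    idx <- seq(tau, length(residuals), by = 7L)
    r <- residuals[idx]
    r[!is.na(r)]
  })
}

#' Rolling one-week-ahead forecasts with both arms and their combination
#'
#' For each test week the driver (1) preprocesses the expanding training
#' window (singularity replacement on training data only — observed test
#' values are never modified), (2) refits both arms (ARIMA lag sets selected
#' by BIC + pruning at the first origin and frozen afterwards, coefficients
#' re-estimated every origin; the SES alpha re-optimized per origin by
#' default), (3) computes per-weekday inverse-energy weights from the
#' training one-step residuals, and (4) emits one record per test day with
#' the observed value and all three predictions.
#'
#' @param series A [daily_series()] covering the training weeks plus at least
#'   one test week.
#' @param config A [rolling_config()].
#' @return A data frame of class `forecast_records` with columns
#'   `origin_week, day, observed, pred_arima, pred_ses, pred_combined` (one
#'   row per test day; `origin_week` is the last training week of that
#'   origin). Attributes: `weights` (list of per-origin
#'   `combination_weights`), `ar_lags`, `ma_lags`, `config`.
#' @export
rolling_forecast <- function(series, config = rolling_config()) {
  stopifnot(inherits(series, "daily_series"), inherits(config, "rolling_config"))
  panel <- to_weekday_panel(series, week_start = config$week_start)
  if (config$train_weeks >= panel$weeks) {
    stop(sprintf("train_weeks = %d leaves no test week (panel has %d weeks)",
                 config$train_weeks, panel$weeks))
  }
  k <- panel$weeks - config$train_weeks
  if (!is.null(config$test_weeks)) k <- min(k, config$test_weeks)

  ar_lags <- NULL; ma_lags <- NULL
  alpha_fixed <- NULL
  weights_by_origin <- vector("list", k)
  records <- vector("list", k)

  for (o in seq_len(k)) {
    tw <- config$train_weeks + o - 1L
    origin_label <- tw
    res <- tryCatch({
      train <- weekday_panel(panel$values[seq_len(tw), , drop = FALSE],
                             week_start = panel$week_start,
                             start_date = panel$start_date,
                             label = panel$label)
      if (config$preprocess) train <- preprocess_panel(train)$panel
      x <- as.vector(t(train$values))
      w <- difference_series(x, config$spec)

      if (is.null(ar_lags)) {
        sel <- select_orders_bic(w, p_max = config$p_max, q_max = config$q_max)
        pruned <- prune_insignificant(
          fit_subset_arma(w, sel$ar_lags, sel$ma_lags),
          diff_series = w, t_threshold = config$t_threshold)
        ar_lags <- pruned$ar_lags
        ma_lags <- pruned$ma_lags
      }
      arima_fit <- fit_sarima(x, spec = config$spec,
                              ar_lags = ar_lags, ma_lags = ma_lags)
      pred_arima <- predict(arima_fit, n_ahead = 7L)

      grid <- config$alpha_grid
      ses <- if (config$refit_alpha || is.null(alpha_fixed)) {
        ses_forecast_week(train, grid = grid)
      } else {
        states <- lapply(1:7, function(tau)
          ses_run(train$values[, tau], alpha_fixed[tau], tau = tau))
        list(predictions = vapply(states, function(s)
          s$smoothed[length(s$smoothed)], 0), states = states)
      }
      if (is.null(alpha_fixed)) {
        alpha_fixed <- vapply(ses$states, `[[`, 0, "alpha")
      }

      res1 <- slice_residuals_by_tau(arima_fit$residuals)
      res2 <- lapply(ses$states, `[[`, "one_step_errors")
      wts <- compute_weights_for_origin(res1, res2)
      pred_comb <- combined_forecast(pred_arima, ses$predictions, wts)
      if (config$clip_zero) pred_comb <- pmax(pred_comb, 0)

      list(wts = wts,
           rec = data.frame(
             origin_week = tw, day = 1:7,
             observed = panel$values[tw + 1L, ],
             pred_arima = pred_arima, pred_ses = ses$predictions,
             pred_combined = pred_comb))
    }, error = function(e) {
      stop(sprintf("rolling forecast failed at origin week %d: %s",
                   origin_label, conditionMessage(e)), call. = FALSE)
    })
    weights_by_origin[[o]] <- res$wts
    records[[o]] <- res$rec
  }

  out <- do.call(rbind, records)
  rownames(out) <- NULL
  class(out) <- c("forecast_records", "data.frame")
  attr(out, "weights") <- weights_by_origin
  attr(out, "ar_lags") <- ar_lags
  attr(out, "ma_lags") <- ma_lags
  attr(out, "config") <- config
  out
}

#' Write rolling-forecast records / weights as CSV
#'
#' @param records A `forecast_records` data frame.
#' @param path Output file.
#' @export
write_forecast_records <- function(records, path) {
  stopifnot(inherits(records, "forecast_records"))
  df <- data.frame(origin_week = records$origin_week, day = records$day,
                   observed = records$observed,
                   arima = records$pred_arima, ses = records$pred_ses,
                   combined = records$pred_combined)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_forecast_records
#' @export
write_weights <- function(records, path) {
  stopifnot(inherits(records, "forecast_records"))
  wl <- attr(records, "weights")
  origins <- unique(records$origin_week)
  rows <- Map(function(w, o) cbind(origin_week = o, as.data.frame(w)), wl, origins)
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read forecast records written by [write_forecast_records()]
#'
#' @param path CSV path.
#' @return A `forecast_records` data frame (without fitting attributes).
#' @export
read_forecast_records <- function(path) {
  df <- utils::read.csv(path)
  need <- c("origin_week", "day", "observed", "arima", "ses", "combined")
  if (!all(need %in% names(df))) {
    stop("records CSV must have columns origin_week,day,observed,arima,ses,combined")
  }
  out <- data.frame(origin_week = df$origin_week, day = df$day,
                    observed = df$observed, pred_arima = df$arima,
                    pred_ses = df$ses, pred_combined = df$combined)
  class(out) <- c("forecast_records", "data.frame")
  out
}
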