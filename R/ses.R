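#' Initial level for single exponential smoothing
#'
#' The mean of the first three weekly observations of a weekday sub-series is
#' the initial smoothed value.
#'
#' @param x Numeric weekday series (one value per week), length >= 3.
#' @return The initial level.
#' @export
ses_init <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 3L) stop("SES initialization needs at least 3 weeks")
  mean(x[1:3])
}

#' Run single exponential smoothing on one weekday sub-series
#'
#' Applies the level recursion
#' `smoothed[t'+1] = alpha * x[t'] + (1 - alpha) * smoothed[t']`
#' from the 3-week-mean initial level; `smoothed[W+1]` is the next-week
#' prediction. One-step errors are scored from week 4 onwards so the
#' initialization window does not score itself; the state carries their MSE
#' and MAPE (MAPE over weeks with non-zero observations).
#'
#' @param x Numeric weekday series, length >= 3.
#' @param alpha Smoothing constant in `(0, 1]`.
#' @param tau Optional weekday index carried in the state.
#' @return An object of class `ses_state` with fields `tau`, `alpha`,
#'   `initial_level`, `smoothed` (length `W + 1`), `one_step_errors`
#'   (weeks `4..W`), `mse`, `mape`.
#' @export
ses_run <- function(x, alpha, tau = NA_integer_) {
  x <- as.numeric(x)
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha > 1) {
    stop("`alpha` must lie in (0, 1]")
  }
  n <- length(x)
  init <- ses_init(x)
  smoothed <- numeric(n + 1L)
  smoothed[1L] <- init
  for (t in seq_len(n)) {
    smoothed[t + 1L] <- alpha * x[t] + (1 - alpha) * smoothed[t]
  }
  if (n >= 4L) {
    idx <- 4:n
    err <- x[idx] - smoothed[idx]
    mse <- mean(err^2)
    nz <- x[idx] != 0
    mape <- if (any(nz)) mean(abs(err[nz]) / x[idx][nz]) * 100 else Inf
  } else {
    err <- numeric(); mse <- NA_real_; mape <- NA_real_
  }
  structure(
    list(tau = tau, alpha = alpha, initial_level = init, smoothed = smoothed,
         one_step_errors = err, mse = mse, mape = mape),
    class = "ses_state"
  )
}

#' @export
print.ses_state <- function(x, ...) {
  cat(sprintf("<ses_state> tau = %s, alpha = %.2f, level %.2f -> %.2f (MSE %.3g)\n",
              ifelse(is.na(x$tau), "?", x$tau), x$alpha, x$initial_level,
              x$smoothed[length(x$smoothed)], x$mse))
  invisible(x)
}

#' Choose the smoothing constant on a grid
#'
#' Evaluates [ses_run()] at every grid point and returns the state minimising
#' the one-step MSE; ties are broken by smaller MAPE, then smaller `alpha`.
#'
#' @param x Numeric weekday series, length >= 4.
#' @param grid Candidate `alpha` values in `(0, 1)`; default 0.01 to 0.99 in
#'   steps of 0.01.
#' @param tau Optional weekday index carried in the state.
#' @return The winning `ses_state`.
#' @export
ses_optimize_alpha <- function(x, grid = seq(0.01, 0.99, by = 0.01),
                               tau = NA_integer_) {
  x <- as.numeric(x)
  if (length(x) < 4L) stop("alpha optimization needs at least 4 weeks")
  grid <- as.numeric(grid)
  if (length(grid) == 0L || any(grid <= 0) || any(grid >= 1)) {
    stop("`grid` must be a non-empty subset of (0, 1)")
  }
  best <- NULL
  for (a in sort(grid)) {
    st <- ses_run(x, a, tau = tau)
    if (is.null(best) ||
        st$mse < best$mse ||
        (st$mse == best$mse && st$mape < best$mape)) {
      best <- st
    }
  }
  best
}

#' One-week-ahead SES forecasts for every weekday
#'
#' Optimizes the smoothing constant independently for each of the seven
#' weekday sub-series of a panel and returns the next-week predictions
#' `smoothed[W+1]`.
#'
#' @param panel A [weekday_panel()] with at least 4 weeks.
#' @param grid Alpha grid passed to [ses_optimize_alpha()].
#' @return A list with `predictions` (length 7, ordered by panel weekday),
#'   `states` (the seven `ses_state`s) and `summary`, a data frame
#'   `day, alpha, initial, mse, mape`.
#' @export
ses_forecast_week <- function(panel, grid = seq(0.01, 0.99, by = 0.01)) {
  stopifnot(inherits(panel, "weekday_panel"))
  if (panel$weeks < 4L) stop("SES forecasting needs at least 4 weeks")
  states <- lapply(1:7, function(tau) {
    ses_optimize_alpha(panel$values[, tau], grid = grid, tau = tau)
  })
  preds <- vapply(states, function(s) s$smoothed[length(s$smoothed)], 0)
  list(
    predictions = preds,
    states = states,
    summary = data.frame(
      day = 1:7,
      alpha = vapply(states, `[[`, 0, "alpha"),
      initial = vapply(states, `[[`, 0, "initial_level"),
      mse = vapply(states, `[[`, 0, "mse"),
      mape = vapply(states, `[[`, 0, "mape")
    )
  )
}
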