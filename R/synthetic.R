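#' Scenario configuration for the synthetic demand generator
#'
#' Describes a synthetic daily outpatient series with the structural features
#' the forecaster assumes: a weekly profile with weekend troughs, an optional
#' linear trend and mild annual cycle, AR(1) autocorrelated noise, and
#' holiday "singularities" that depress individual days.
#'
#' @param weeks Number of weeks (>= 5).
#' @param weekday_profile Seven positive mean visit counts (Monday..Sunday by
#'   default week convention).
#' @param trend_per_week Additive linear trend per week.
#' @param annual_amplitude Amplitude of a sine with period 365 days (>= 0).
#' @param ar_coefficient AR(1) coefficient of the noise, in (-1, 1).
#' @param noise_sd Innovation SD of the noise (>= 0).
#' @param holiday_weeks `NULL` or a data frame `week, day, depression` with
#'   depression factors in `[0, 1)`; the affected cell's mean is multiplied
#'   by `1 - depression`.
#' @param seed Integer RNG seed; generation is a pure function of the config.
#' @param label Series label.
#' @param start_date First calendar day (default a Monday so the series
#'   aligns with the default week convention).
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(weeks, weekday_profile, trend_per_week = 0,
                            annual_amplitude = 0, ar_coefficient = 0,
                            noise_sd = 0, holiday_weeks = NULL, seed = 1L,
                            label = "synthetic", start_date = "2014-01-06") {
  weeks <- as.integer(weeks)
  if (is.na(weeks) || weeks < 5L) stop("invalid config field `weeks` (need >= 5)")
  weekday_profile <- as.numeric(weekday_profile)
  if (length(weekday_profile) != 7L || any(!is.finite(weekday_profile)) ||
      any(weekday_profile <= 0)) {
    stop("invalid config field `weekday_profile` (need 7 positive values)")
  }
  if (!is.finite(trend_per_week)) stop("invalid config field `trend_per_week`")
  if (!is.finite(annual_amplitude) || annual_amplitude < 0) {
    stop("invalid config field `annual_amplitude`")
  }
  if (!is.finite(ar_coefficient) || abs(ar_coefficient) >= 1) {
    stop("invalid config field `ar_coefficient` (need |value| < 1)")
  }
  if (!is.finite(noise_sd) || noise_sd < 0) stop("invalid config field `noise_sd`")
  if (!is.null(holiday_weeks)) {
    holiday_weeks <- as.data.frame(holiday_weeks)
    need <- c("week", "day", "depression")
    if (!all(need %in% names(holiday_weeks)) ||
        any(holiday_weeks$week < 1) || any(holiday_weeks$week > weeks) ||
        any(holiday_weeks$day < 1) || any(holiday_weeks$day > 7) ||
        any(holiday_weeks$depression < 0) || any(holiday_weeks$depression >= 1)) {
      stop("invalid config field `holiday_weeks`")
    }
  }
  seed <- as.integer(seed)
  if (is.na(seed)) stop("invalid config field `seed`")
  structure(
    list(weeks = weeks, weekday_profile = weekday_profile,
         trend_per_week = trend_per_week, annual_amplitude = annual_amplitude,
         ar_coefficient = ar_coefficient, noise_sd = noise_sd,
         holiday_weeks = holiday_weeks, seed = seed, label = label,
         start_date = as.Date(start_date)),
    class = "scenario_config"
  )
}

#' Generate a synthetic daily visit series
#'
#' `x_t = round(max(0, mu_tau (1 - depression) + trend t' +
#' A sin(2 pi t / 365) + eta_t))` with AR(1) noise
#' `eta_t = phi eta_{t-1} + N(0, sd^2)`. Counts are rounded to integers
#' (visits are counts) and floored at zero. Deterministic given the config's
#' seed.
#'
#' @param config A [scenario_config()].
#' @return A [daily_series()] of `weeks * 7` days.
#' @export
generate_series <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  n <- config$weeks * 7L
  week <- rep(seq_len(config$weeks), each = 7L)
  tau <- rep(1:7, config$weeks)
  mu <- config$weekday_profile[tau]
  if (!is.null(config$holiday_weeks)) {
    h <- config$holiday_weeks
    for (i in seq_len(nrow(h))) {
      idx <- daily_index(h$week[i], h$day[i])
      mu[idx] <- mu[idx] * (1 - h$depression[i])
    }
  }
  t <- seq_len(n)
  eta <- as.numeric(stats::filter(stats::rnorm(n, 0, config$noise_sd),
                                  config$ar_coefficient,
                                  method = "recursive", init = 0))
  x <- round(pmax(0, mu + config$trend_per_week * week +
                    config$annual_amplitude * sin(2 * pi * t / 365) + eta))
  daily_series(x, config$start_date, label = config$label)
}

#' Generate ground-truth panels for SES parameter recovery
#'
#' Each weekday sub-series follows the local-level process whose optimal
#' one-step exponential smoother has exactly the requested constant:
#' `x_{t'} = level_{t'-1} + e_{t'}`, `level_{t'} = level_{t'-1} +
#' alpha_true * e_{t'}` with Gaussian `e`. Weekday series are independent.
#'
#' @param weeks Number of weeks.
#' @param tau_profile Seven starting levels.
#' @param alpha_true True smoothing constant in (0, 1).
#' @param noise_sd Innovation SD.
#' @param seed RNG seed.
#' @return A [weekday_panel()].
#' @export
generate_ses_truth <- function(weeks, tau_profile, alpha_true, noise_sd, seed) {
  if (!is.finite(alpha_true) || alpha_true <= 0 || alpha_true >= 1) {
    stop("`alpha_true` must lie in (0, 1)")
  }
  tau_profile <- as.numeric(tau_profile)
  stopifnot(length(tau_profile) == 7L)
  set.seed(as.integer(seed))
  v <- matrix(0, nrow = weeks, ncol = 7L)
  for (tau in 1:7) {
    level <- tau_profile[tau]
    e <- stats::rnorm(weeks, 0, noise_sd)
    for (t in seq_len(weeks)) {
      v[t, tau] <- level + e[t]
      level <- level + alpha_true * e[t]
    }
  }
  weekday_panel(v, label = sprintf("ses-truth alpha=%.2f", alpha_true))
}

#' Bundled week-45 worked example for two outpatient series
#'
#' Returns the reference worked example shipped with the package
#' (`inst/extdata/week45_example.csv`): for an endocrinology (EOV) and a
#' respiratory (ROV) outpatient series, the observed counts of one test week
#' alongside the two arms' published predictions and the ARIMA-arm weights
#' `l1` used in the combination. Used by format tests, the replication
#' command and the acceptance checks.
#'
#' @return A list with elements `eov` and `rov`, each a list
#'   `observed, arima, ses, l1, l2` of length-7 vectors (weekdays
#'   Monday..Sunday).
#' @export
worked_example_fixture <- function() {
  path <- system.file("extdata", "week45_example.csv", package = "visitcast")
  if (!nzchar(path)) stop("bundled worked example not found")
  df <- utils::read.csv(path)
  out <- lapply(split(df, df$series), function(d) {
    d <- d[order(d$day), ]
    list(observed = d$observed, arima = d$arima, ses = d$ses,
         l1 = d$l1, l2 = 1 - d$l1)
  })
  names(out) <- tolower(names(out))
  out[c("eov", "rov")]
}

#' Load a bundled scenario preset
#'
#' Presets are plain-text key-value files under
#' `inst/extdata/scenarios/` (`eov_like`, `rov_like`, `flat_control`).
#'
#' @param name Preset name or a path to a scenario file.
#' @return A [scenario_config()].
#' @export
scenario_preset <- function(name) {
  path <- if (file.exists(name)) name else
    system.file("extdata", "scenarios", paste0(name, ".dcf"),
                package = "visitcast")
  if (!nzchar(path) || !file.exists(path)) {
    stop(sprintf("unknown scenario preset: %s", name))
  }
  d <- as.data.frame(read.dcf(path), stringsAsFactors = FALSE)
  nums <- function(s) as.numeric(strsplit(trimws(s), "\\s+")[[1]])
  holidays <- NULL
  if (!is.null(d$holiday_weeks) && nzchar(trimws(d$holiday_weeks))) {
    trip <- strsplit(strsplit(trimws(d$holiday_weeks), ";")[[1]], ":")
    holidays <- do.call(rbind, lapply(trip, function(x)
      data.frame(week = as.integer(x[1]), day = as.integer(x[2]),
                 depression = as.numeric(x[3]))))
  }
  scenario_config(
    weeks = as.integer(d$weeks),
    weekday_profile = nums(d$weekday_profile),
    trend_per_week = as.numeric(d$trend_per_week %||% 0),
    annual_amplitude = as.numeric(d$annual_amplitude %||% 0),
    ar_coefficient = as.numeric(d$ar_coefficient %||% 0),
    noise_sd = as.numeric(d$noise_sd %||% 0),
    holiday_weeks = holidays,
    seed = as.integer(d$seed %||% 1L),
    label = as.character(d$label %||% name)
  )
}
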