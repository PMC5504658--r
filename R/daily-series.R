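#' @keywords internal
"_PACKAGE"

.weekday_names <- c("Monday", "Tuesday", "Wednesday", "Thursday", "Friday",
                    "Saturday", "Sunday")

#' Daily outpatient visit series
#'
#' A `daily_series` holds one count per consecutive calendar day: element `k`
#' of `values` is the observation for `start_date + (k - 1)` days. Counts are
#' integers on ingest but may become real-valued after singularity replacement.
#'
#' @param values Numeric vector of non-negative daily counts, one per day,
#'   no gaps.
#' @param start_date Date (or string coercible via [as.Date()]) of the first
#'   observation.
#' @param label Free-text label for the series (e.g. `"EOV"`, `"ROV"`).
#' @return An object of class `daily_series`.
#' @examples
#' x <- daily_series(c(120, 130, 125), "2014-01-06", label = "demo")
#' length(x$values)
#' @export
daily_series <- function(values, start_date, label = "") {
  if (length(values) == 0L) stop("`values` must be non-empty")
  values <- as.numeric(values)
  if (anyNA(values)) stop("`values` must not contain missing values")
  if (any(values < 0)) stop("all daily counts must be >= 0")
  start_date <- as.Date(start_date)
  if (length(start_date) != 1L || is.na(start_date)) {
    stop("`start_date` must be a single valid date")
  }
  structure(
    list(start_date = start_date, values = values, label = as.character(label)[1L]),
    class = "daily_series"
  )
}

#' @export
print.daily_series <- function(x, ...) {
  cat(sprintf("<daily_series> %s: %d days from %s (mean %.1f/day)\n",
              if (nzchar(x$label)) x$label else "unlabelled",
              length(x$values), format(x$start_date), mean(x$values)))
  invisible(x)
}

#' @export
length.daily_series <- function(x) length(x$values)

series_dates <- function(series) {
  series$start_date + seq_along(series$values) - 1L
}

# weekday position 1..7 of a date, with day 1 = `week_start`
weekday_position <- function(date, week_start = "Monday") {
  ws <- match(match.arg(week_start, .weekday_names), .weekday_names)
  iso <- as.integer(format(as.Date(date), "%u"))   # Monday = 1 .. Sunday = 7
  ((iso - ws) %% 7L) + 1L
}

#' Read or write a daily series as CSV
#'
#' The CSV dialect is fixed: comma-separated, header `date,visits`, ISO-8601
#' dates, UTF-8. Dates must be strictly consecutive days; a gap or duplicate
#' date is an error naming the offending date, as is any negative count.
#'
#' @param path File path.
#' @param label Label attached to the returned series.
#' @return `read_series()` returns a [daily_series()]; `write_series()`
#'   invisibly returns `path`. The two are mutually inverse on valid input.
#' @export
read_series <- function(path, label = "") {
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df)[1:2], c("date", "visits"))) {
    stop("CSV must have header `date,visits`")
  }
  if (nrow(df) == 0L) stop("CSV contains no observations")
  dates <- as.Date(df$date)
  if (anyNA(dates)) stop("unparseable date in CSV")
  step <- diff(as.integer(dates))
  if (any(step != 1L)) {
    bad <- which(step != 1L)[1L]
    if (step[bad] <= 0L) {
      stop(sprintf("duplicate or out-of-order date: %s", format(dates[bad + 1L])))
    }
    stop(sprintf("gap in dates after %s", format(dates[bad])))
  }
  visits <- suppressWarnings(as.numeric(df$visits))
  if (anyNA(visits)) stop("non-numeric visit count in CSV")
  if (any(visits < 0)) {
    stop(sprintf("negative count on %s", format(dates[which(visits < 0)[1L]])))
  }
  daily_series(visits, dates[1L], label = label)
}

#' @param series A [daily_series()].
#' @rdname read_series
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "daily_series"))
  df <- data.frame(date = format(series_dates(series)), visits = series$values)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Weekday panel: a daily series re-indexed by (week, weekday)
#'
#' The panel is a `weeks x 7` matrix whose cell `(t', tau)` is the count for
#' weekday `tau` of week `t'`; column 1 is the configured week-start day.
#' Construction requires whole weeks only, so a round trip with
#' [panel_to_series()] is lossless.
#'
#' @param values A numeric `weeks x 7` matrix (rows = weeks).
#' @param week_start Weekday name of column 1 (default `"Monday"`).
#' @param start_date Date of cell (1, 1), or `NULL` if unknown.
#' @param label Series label carried along.
#' @return An object of class `weekday_panel`.
#' @export
weekday_panel <- function(values, week_start = "Monday", start_date = NULL,
                          label = "") {
  values <- as.matrix(values)
  if (ncol(values) != 7L) stop("a weekday panel needs exactly 7 columns")
  if (nrow(values) < 1L) stop("a weekday panel needs at least 1 week")
  if (anyNA(values)) stop("all panel cells must be populated")
  week_start <- match.arg(week_start, .weekday_names)
  ws <- match(week_start, .weekday_names)
  colnames(values) <- .weekday_names[((ws - 1L + 0:6) %% 7L) + 1L]
  rownames(values) <- NULL
  structure(
    list(values = values, weeks = nrow(values), week_start = week_start,
         start_date = if (is.null(start_date)) NULL else as.Date(start_date),
         label = as.character(label)[1L]),
    class = "weekday_panel"
  )
}

#' @export
print.weekday_panel <- function(x, ...) {
  cat(sprintf("<weekday_panel> %s: %d weeks, week starts %s\n",
              if (nzchar(x$label)) x$label else "unlabelled",
              x$weeks, x$week_start))
  cat("weekday means:\n")
  print(round(colMeans(x$values), 1))
  invisible(x)
}

#' Fold a daily series into complete weeks
#'
#' Leading and trailing days that do not form a complete week (with respect to
#' `week_start`) are dropped, mirroring the usual trimming of incomplete
#' periods before cyclic modelling: a 365-day year starting mid-week keeps 51
#' complete weeks.
#'
#' @param series A [daily_series()].
#' @param week_start Weekday name that opens each panel week.
#' @return A [weekday_panel()] with attributes `dropped_leading` and
#'   `dropped_trailing` giving the number of trimmed days at each end.
#' @examples
#' s <- daily_series(rep(c(150, 140, 130, 120, 110, 60, 30), 4), "2014-01-06")
#' p <- to_weekday_panel(s)
#' p$weeks
#' @export
to_weekday_panel <- function(series, week_start = "Monday") {
  stopifnot(inherits(series, "daily_series"))
  week_start <- match.arg(week_start, .weekday_names)
  tau1 <- weekday_position(series$start_date, week_start)
  lead <- (8L - tau1) %% 7L
  n <- length(series$values)
  weeks <- (n - lead) %/% 7L
  if (weeks < 1L) stop("series does not contain one complete week")
  trail <- n - lead - weeks * 7L
  kept <- series$values[(lead + 1L):(lead + weeks * 7L)]
  p <- weekday_panel(matrix(kept, nrow = weeks, ncol = 7L, byrow = TRUE),
                     week_start = week_start,
                     start_date = series$start_date + lead,
                     label = series$label)
  attr(p, "dropped_leading") <- lead
  attr(p, "dropped_trailing") <- trail
  p
}

#' Flatten a weekday panel back to a daily series
#'
#' Cells are emitted in `(week, weekday)` order, exactly inverting
#' [to_weekday_panel()] on trimmed input.
#'
#' @param panel A [weekday_panel()].
#' @return A [daily_series()] (a synthetic Monday start date is used when the
#'   panel carries none).
#' @export
panel_to_series <- function(panel) {
  stopifnot(inherits(panel, "weekday_panel"))
  start <- panel$start_date
  if (is.null(start)) {
    # arbitrary anchor with the right weekday
    anchor <- as.Date("2001-01-01")  # a Monday
    start <- anchor + (match(panel$week_start, .weekday_names) - 1L)
  }
  daily_series(as.vector(t(panel$values)), start, label = panel$label)
}

#' Position of a (week, weekday) cell in the daily series
#'
#' Day `tau` of week `t'` sits at daily position `t = 7 (t' - 1) + tau`, a
#' bijection from `(1..W) x (1..7)` onto `1..7W`. This is the alignment used
#' to match the daily-model forecasts with the per-weekday smoother.
#'
#' @param week Week index `t' >= 1`.
#' @param day Weekday index `tau` in `1..7`.
#' @return Integer daily position.
#' @examples
#' daily_index(45, 7)  # 315
#' @export
daily_index <- function(week, day) {
  week <- as.integer(week); day <- as.integer(day)
  if (any(is.na(week)) || any(week < 1L)) stop("`week` must be >= 1")
  if (any(is.na(day)) || any(day < 1L) || any(day > 7L)) {
    stop("`day` must be in 1..7")
  }
  7L * (week - 1L) + day
}
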