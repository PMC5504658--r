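#' Detect holiday singularities in a weekday panel
#'
#' Public-holiday closures depress visit counts far below the typical level of
#' the same weekday; such days carry no information about routine demand.
#' For each weekday `tau` independently, a cell is flagged as a singularity
#' when it lies outside two sample standard deviations of that weekday's mean
#' (both statistics over all weeks of the panel, SD with denominator n-1).
#' A weekday with zero variance flags nothing.
#'
#' The report already carries the replacement value each flagged cell would
#' receive: the mean of the same weekday in the previous and following weeks
#' (the single existing neighbour at the panel edges). Neighbour values are
#' always the ORIGINAL observations, even if the neighbour is itself flagged —
#' detection and replacement are a single pass.
#'
#' @param panel A [weekday_panel()] with at least 3 weeks.
#' @return A data frame of class `singularity_report` with columns
#'   `week`, `day`, `original`, `replacement`, `mean`, `sd`.
#' @seealso [replace_singularities()]
#' @export
detect_singularities <- function(panel) {
  stopifnot(inherits(panel, "weekday_panel"))
  if (panel$weeks < 3L) stop("singularity detection needs at least 3 weeks")
  v <- panel$values
  out <- list()
  for (tau in 1:7) {
    col <- v[, tau]
    m <- mean(col)
    s <- stats::sd(col)
    if (!is.finite(s) || s == 0) next
    hit <- which(abs(col - m) > 2 * s)
    for (t in hit) {
      nb <- col[intersect(c(t - 1L, t + 1L), seq_len(panel$weeks))]
      out[[length(out) + 1L]] <- data.frame(
        week = t, day = tau, original = col[t], replacement = mean(nb),
        mean = m, sd = s
      )
    }
  }
  rep <- if (length(out)) do.call(rbind, out) else
    data.frame(week = integer(), day = integer(), original = numeric(),
               replacement = numeric(), mean = numeric(), sd = numeric())
  rep <- rep[order(rep$week, rep$day), , drop = FALSE]
  rownames(rep) <- NULL
  class(rep) <- c("singularity_report", "data.frame")
  rep
}

#' Replace flagged singularities by their neighbour-week mean
#'
#' Applies the replacements recorded by [detect_singularities()]; unflagged
#' cells are returned bit-exact.
#'
#' @param panel The [weekday_panel()] the report was computed from.
#' @param report A `singularity_report`.
#' @return A [weekday_panel()] with flagged cells replaced.
#' @export
replace_singularities <- function(panel, report) {
  stopifnot(inherits(panel, "weekday_panel"),
            inherits(report, "singularity_report"))
  if (nrow(report) == 0L) return(panel)
  if (any(report$week > panel$weeks)) {
    stop("report does not match panel: week index out of range")
  }
  v <- panel$values
  v[cbind(report$week, report$day)] <- report$replacement
  out <- weekday_panel(v, week_start = panel$week_start,
                       start_date = panel$start_date, label = panel$label)
  attr(out, "n_replaced") <- nrow(report)
  out
}

#' Detect and replace singularities in one call
#'
#' @inheritParams detect_singularities
#' @return A list with elements `panel` (cleaned) and `report`.
#' @export
preprocess_panel <- function(panel) {
  report <- detect_singularities(panel)
  list(panel = replace_singularities(panel, report), report = report)
}

#' Split a weekday panel into training and test weeks
#'
#' @param panel A [weekday_panel()].
#' @param train_weeks Number of leading weeks kept for fitting; must leave at
#'   least one test week. A 51-week panel with `train_weeks = 43` gives the
#'   301-day training / 56-day test split.
#' @return A list with `weekday_panel` elements `train` and `test`.
#' @export
split_train_test <- function(panel, train_weeks) {
  stopifnot(inherits(panel, "weekday_panel"))
  train_weeks <- as.integer(train_weeks)
  if (is.na(train_weeks) || train_weeks < 1L || train_weeks >= panel$weeks) {
    stop(sprintf("`train_weeks` must be in 1..%d (got %s)",
                 panel$weeks - 1L, train_weeks))
  }
  week_rows <- function(rows, shift_weeks) {
    sd <- if (is.null(panel$start_date)) NULL else
      panel$start_date + 7L * shift_weeks
    weekday_panel(panel$values[rows, , drop = FALSE],
                  week_start = panel$week_start, start_date = sd,
                  label = panel$label)
  }
  list(train = week_rows(seq_len(train_weeks), 0L),
       test = week_rows((train_weeks + 1L):panel$weeks, train_weeks))
}

#' Write a singularity report as CSV
#'
#' @param report A `singularity_report`.
#' @param path Output file.
#' @export
write_singularity_report <- function(report, path) {
  stopifnot(inherits(report, "singularity_report"))
  utils::write.csv(as.data.frame(report), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
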