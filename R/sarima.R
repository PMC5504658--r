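#' Differencing specification
#'
#' Describes the operator `(1 - B)^d (1 - B^L)^D` applied before ARMA
#' modelling: `d` regular differences for trend and `D_order` seasonal
#' differences at step length `D_lag` (7 for a weekly cycle). The default —
#' no regular difference, one lag-7 difference — is the single application of
#' `(1 - B^7)` used throughout the daily-visits model.
#'
#' @param d Non-negative integer order of regular differencing.
#' @param D_order Non-negative integer order of seasonal differencing.
#' @param D_lag Positive integer seasonal step length.
#' @return An object of class `diff_spec`.
#' @export
diff_spec <- function(d = 0L, D_order = 1L, D_lag = 7L) {
  d <- as.integer(d); D_order <- as.integer(D_order); D_lag <- as.integer(D_lag)
  if (is.na(d) || d < 0L) stop("`d` must be a non-negative integer")
  if (is.na(D_order) || D_order < 0L) stop("`D_order` must be a non-negative integer")
  if (is.na(D_lag) || D_lag < 1L) stop("`D_lag` must be a positive integer")
  structure(list(d = d, D_order = D_order, D_lag = D_lag), class = "diff_spec")
}

diff_offset <- function(spec) spec$d + spec$D_order * spec$D_lag

# polynomial coefficients of (1-B)^d (1-B^L)^D, constant term first
diff_poly <- function(spec) {
  mult <- function(a, b) {
    res <- numeric(length(a) + length(b) - 1L)
    for (i in seq_along(a)) {
      res[i:(i + length(b) - 1L)] <- res[i:(i + length(b) - 1L)] + a[i] * b
    }
    res
  }
  p <- 1
  for (i in seq_len(spec$d)) p <- mult(p, c(1, -1))
  seas <- c(1, rep(0, spec$D_lag - 1L), -1)
  for (i in seq_len(spec$D_order)) p <- mult(p, seas)
  p
}

#' Apply a differencing operator to a series
#'
#' @param x Numeric vector.
#' @param spec A [diff_spec()].
#' @return The differenced series; its length shrinks by
#'   `d + D_order * D_lag`.
#' @seealso [invert_difference()]
#' @export
difference_series <- function(x, spec = diff_spec()) {
  stopifnot(inherits(spec, "diff_spec"))
  x <- as.numeric(x)
  if (length(x) <= diff_offset(spec)) {
    stop(sprintf("series of length %d is too short for differencing offset %d",
                 length(x), diff_offset(spec)))
  }
  if (spec$d > 0L) x <- diff(x, lag = 1L, differences = spec$d)
  if (spec$D_order > 0L) x <- diff(x, lag = spec$D_lag, differences = spec$D_order)
  x
}

#' Undo differencing on a block of forecasts
#'
#' Given forecasts `w` on the differenced scale and the observed history on
#' the original scale, reconstructs original-scale values by the recursion
#' `x_t = w_t - sum_j c_j x_{t-j}` where `c_j` are the coefficients of the
#' differencing polynomial; already-inverted forecasts feed later steps.
#'
#' @param diff_forecasts Forecasts on the differenced scale.
#' @param history Observed original-scale series up to the forecast origin.
#' @param spec A [diff_spec()].
#' @return Original-scale forecasts, same length as `diff_forecasts`.
#' @export
invert_difference <- function(diff_forecasts, history, spec = diff_spec()) {
  stopifnot(inherits(spec, "diff_spec"))
  m <- diff_offset(spec)
  if (length(history) < m) {
    stop(sprintf("need at least %d historical values to invert, got %d",
                 m, length(history)))
  }
  if (m == 0L) return(as.numeric(diff_forecasts))
  cf <- diff_poly(spec)[-1L]          # c_1 .. c_m
  ext <- c(as.numeric(history), numeric(length(diff_forecasts)))
  n <- length(history)
  for (h in seq_along(diff_forecasts)) {
    ext[n + h] <- diff_forecasts[h] - sum(cf * ext[n + h - seq_len(m)])
  }
  ext[(n + 1L):(n + length(diff_forecasts))]
}

#' Sample autocorrelation and partial autocorrelation
#'
#' Thin wrappers around [stats::acf()]/[stats::pacf()] returning plain
#' vectors; a zero-variance input is an error rather than `NaN`s.
#'
#' @param x Numeric vector.
#' @param max_lag Largest lag, `< length(x)`.
#' @return `sample_acf()`: autocorrelations at lags `0..max_lag`
#'   (`r_0 = 1`); `sample_pacf()`: partial autocorrelations at `1..max_lag`.
#' @export
sample_acf <- function(x, max_lag) {
  x <- as.numeric(x)
  if (max_lag >= length(x)) stop("`max_lag` must be smaller than the series length")
  if (stats::sd(x) == 0) stop("zero-variance series has no autocorrelation")
  r <- stats::acf(x, lag.max = max_lag, plot = FALSE, demean = TRUE)$acf[, 1, 1]
  stats::setNames(r, 0:max_lag)
}

#' @rdname sample_acf
#' @export
sample_pacf <- function(x, max_lag) {
  x <- as.numeric(x)
  if (max_lag >= length(x)) stop("`max_lag` must be smaller than the series length")
  if (stats::sd(x) == 0) stop("zero-variance series has no autocorrelation")
  r <- stats::pacf(x, lag.max = max_lag, plot = FALSE)$acf[, 1, 1]
  stats::setNames(r, 1:max_lag)
}

# Conditional residual recursion for a subset ARMA model in the convention
#   (1 - sum phi_k B^k) w_t = (1 - sum theta_k B^k) eps_t,
# conditioning on the first p = max(ar_lags) observations with presample
# eps = 0. Returns eps aligned to w[(p+1):n].
css_residuals <- function(w, ar_lags, ar_coef, ma_lags, ma_coef) {
  n <- length(w)
  p <- if (length(ar_lags)) max(ar_lags) else 0L
  q <- if (length(ma_lags)) max(ma_lags) else 0L
  if (p > 0L) {
    phi <- numeric(p); phi[ar_lags] <- ar_coef
    a <- stats::filter(w, c(1, -phi), method = "convolution", sides = 1)
    a <- as.numeric(a)[(p + 1L):n]
  } else {
    a <- w
  }
  if (q > 0L) {
    theta <- numeric(q); theta[ma_lags] <- ma_coef
    as.numeric(stats::filter(a, theta, method = "recursive", init = numeric(q)))
  } else {
    a
  }
}

check_lags <- function(lags, what) {
  lags <- sort(unique(as.integer(lags)))
  if (any(is.na(lags)) || any(lags < 1L)) {
    stop(sprintf("%s lags must be positive integers", what))
  }
  lags
}

#' Fit a subset-lag ARMA model by conditional least squares
#'
#' Estimates an ARMA model on a (differenced, zero-mean) series in which only
#' the named AR and MA lags carry coefficients, in the sign convention
#' `phi(B) = 1 - sum phi_k B^k`, `Theta(B) = 1 - sum theta_k B^k`. The
#' conditional sum of squared innovations (presample errors zero,
#' conditioning on the first `max(ar_lags)` observations) is minimised by
#' BFGS from a zero start; standard errors come from the numerical Hessian of
#' the objective, `Var(b) = 2 sigma^2 H^{-1}`.
#'
#' @param w Numeric series on the differenced scale.
#' @param ar_lags,ma_lags Integer vectors of active lags (possibly empty).
#' @param control Passed to [stats::optim()] after the defaults.
#' @return An object of class `subset_arma`: coefficients with standard
#'   errors and t-values, `sigma2` (= RSS / effective n), diff-scale
#'   residuals, and fit diagnostics. An AR root on or inside the unit circle
#'   is recorded in `$warnings`.
#' @export
fit_subset_arma <- function(w, ar_lags = integer(), ma_lags = integer(),
                            control = list()) {
  w <- as.numeric(w)
  ar_lags <- check_lags(ar_lags, "AR")
  ma_lags <- check_lags(ma_lags, "MA")
  n <- length(w)
  p <- if (length(ar_lags)) max(ar_lags) else 0L
  k <- length(ar_lags) + length(ma_lags)
  if (n <= p + 1L) stop("series too short for the requested AR lags")
  n_eff <- n - p
  warnings <- character()

  split_par <- function(par) {
    list(ar = par[seq_along(ar_lags)],
         ma = par[length(ar_lags) + seq_along(ma_lags)])
  }
  objective <- function(par) {
    cf <- split_par(par)
    eps <- css_residuals(w, ar_lags, cf$ar, ma_lags, cf$ma)
    s <- sum(eps * eps)
    if (!is.finite(s)) s <- .Machine$double.xmax / 1e10
    s
  }

  if (k == 0L) {
    eps <- w
    rss <- sum(eps * eps)
    fit <- NULL
    ar_coef <- numeric(); ma_coef <- numeric()
    se <- numeric(); tval <- numeric()
  } else {
    ctrl <- utils::modifyList(list(maxit = 1000L, reltol = 1e-12), control)
    fit <- stats::optim(numeric(k), objective, method = "BFGS",
                        hessian = TRUE, control = ctrl)
    if (fit$convergence != 0L) {
      stop(sprintf(
        "subset ARMA estimation did not converge (optim code %d%s)",
        fit$convergence,
        if (!is.null(fit$message) && nzchar(fit$message %||% ""))
          paste0(": ", fit$message) else ""))
    }
    cf <- split_par(fit$par)
    ar_coef <- cf$ar; ma_coef <- cf$ma
    eps <- css_residuals(w, ar_lags, ar_coef, ma_lags, ma_coef)
    rss <- sum(eps * eps)
    sigma2 <- rss / n_eff
    vc <- tryCatch(2 * sigma2 * solve(fit$hessian), error = function(e) NULL)
    se <- if (is.null(vc)) rep(NA_real_, k) else sqrt(pmax(diag(vc), 0))
    tval <- c(ar_coef, ma_coef) / se
    if (p > 0L) {
      phi_full <- numeric(p); phi_full[ar_lags] <- ar_coef
      roots <- polyroot(c(1, -phi_full))
      if (any(Mod(roots) <= 1 + 1e-8)) {
        warnings <- c(warnings, "AR polynomial has a root on or inside the unit circle")
      }
    }
  }
  sigma2 <- rss / n_eff
  lag_names <- function(prefix, lags) {
    if (length(lags)) paste0(prefix, lags) else character()
  }
  names_all <- c(lag_names("ar", ar_lags), lag_names("ma", ma_lags))
  structure(
    list(ar_lags = ar_lags,
         ar_coef = stats::setNames(ar_coef, lag_names("ar", ar_lags)),
         ma_lags = ma_lags,
         ma_coef = stats::setNames(ma_coef, lag_names("ma", ma_lags)),
         se = stats::setNames(se, names_all), tvalues = stats::setNames(tval, names_all),
         sigma2 = sigma2, rss = rss, n = n, n_eff = n_eff,
         residuals_diff = eps, diff_series = w,
         objective_value = rss, warnings = warnings),
    class = "subset_arma"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.subset_arma <- function(x, ...) {
  cat(sprintf("<subset_arma> AR lags {%s}, MA lags {%s}, sigma^2 = %.4g\n",
              paste(x$ar_lags, collapse = ","),
              paste(x$ma_lags, collapse = ","), x$sigma2))
  if (length(x$tvalues)) {
    print(round(data.frame(coef = c(x$ar_coef, x$ma_coef), se = x$se,
                           t = x$tvalues), 4))
  }
  for (wrn in x$warnings) cat("warning:", wrn, "\n")
  invisible(x)
}

#' Select ARMA orders by BIC over a full contiguous-lag grid
#'
#' Fits ARMA(p, q) with contiguous lags `1..p`, `1..q` for every
#' `p <= p_max`, `q <= q_max` and returns the lag sets minimising
#' `BIC = n ln(RSS/n) + k ln(n)` with `k = p + q + 1` (the variance counts as
#' a parameter; constants common to all candidates are dropped). Ties go to
#' the smaller `p + q`, then the smaller `p`. Sparse subsets are produced
#' afterwards by [prune_insignificant()], not here.
#'
#' @param w Differenced series.
#' @param p_max,q_max Grid bounds (default 7, the weekly cycle length).
#' @return List with `ar_lags`, `ma_lags`, `bic`, and the full candidate
#'   `table`.
#' @export
select_orders_bic <- function(w, p_max = 7L, q_max = 7L) {
  w <- as.numeric(w)
  grid <- expand.grid(p = 0:p_max, q = 0:q_max)
  grid <- grid[order(grid$p + grid$q, grid$p), ]
  best <- NULL
  rows <- list()
  for (i in seq_len(nrow(grid))) {
    p <- grid$p[i]; q <- grid$q[i]
    fit <- tryCatch(
      fit_subset_arma(w, ar_lags = seq_len(p), ma_lags = seq_len(q)),
      error = function(e) NULL)
    if (is.null(fit)) next
    n <- fit$n_eff
    bic <- n * log(fit$rss / n) + (p + q + 1) * log(n)
    rows[[length(rows) + 1L]] <- data.frame(p = p, q = q, bic = bic)
    if (is.null(best) || bic < best$bic) {
      best <- list(ar_lags = seq_len(p), ma_lags = seq_len(q), bic = bic)
    }
  }
  if (is.null(best)) stop("no ARMA candidate could be fitted")
  best$table <- do.call(rbind, rows)
  best
}

#' Drop insignificant coefficients and refit
#'
#' Iteratively removes the coefficient with the smallest `|t|` below
#' `t_threshold` and refits, until every remaining coefficient is significant
#' or none remain. This is how sparse (subset) lag structures arise from the
#' contiguous BIC winner.
#'
#' @param model A `subset_arma` fit.
#' @param diff_series The series the model was fitted on (defaults to the one
#'   stored in the model).
#' @param t_threshold Absolute-t cutoff (default 1.96). Coefficients whose
#'   standard error is unavailable count as insignificant.
#' @return A `subset_arma` with (weakly) fewer terms.
#' @export
prune_insignificant <- function(model, diff_series = model$diff_series,
                                t_threshold = 1.96) {
  stopifnot(inherits(model, "subset_arma"))
  repeat {
    k <- length(model$ar_lags) + length(model$ma_lags)
    if (k == 0L) return(model)
    tv <- abs(model$tvalues)
    tv[is.na(tv)] <- 0
    if (all(tv >= t_threshold)) return(model)
    drop <- names(tv)[which.min(tv)]
    ar <- model$ar_lags; ma <- model$ma_lags
    if (grepl("^ar", drop)) {
      ar <- setdiff(ar, as.integer(sub("ar", "", drop)))
    } else {
      ma <- setdiff(ma, as.integer(sub("ma", "", drop)))
    }
    model <- fit_subset_arma(diff_series, ar_lags = ar, ma_lags = ma)
  }
}

#' Ljung-Box portmanteau test on residuals
#'
#' `Q(m) = n (n + 2) sum_{k=1..m} r_k^2 / (n - k)` referred to a chi-square
#' with `m - n_params` degrees of freedom, floored at 1. Residuals passing at
#' every tested lag (p > 0.05, say) support the white-noise hypothesis.
#'
#' @param residuals Numeric residual vector (no `NA`).
#' @param lags Integer vector of maximum lags `m` to test.
#' @param n_params Number of estimated ARMA coefficients.
#' @return A data frame of class `ljung_box` with columns `lag`, `statistic`,
#'   `df`, `p_value`.
#' @export
ljung_box <- function(residuals, lags = c(6L, 12L, 18L, 24L), n_params = 0L) {
  residuals <- as.numeric(residuals)
  n <- length(residuals)
  lags <- sort(unique(as.integer(lags)))
  if (any(lags < 1L)) stop("lags must be positive")
  if (max(lags) >= n) stop("largest lag must be smaller than the residual length")
  if (stats::sd(residuals) == 0) stop("zero-variance residuals: test degenerate")
  r <- sample_acf(residuals, max(lags))[-1L]
  terms <- r^2 / (n - seq_along(r))
  out <- data.frame(
    lag = lags,
    statistic = n * (n + 2) * vapply(lags, function(m) sum(terms[1:m]), 0),
    df = pmax(lags - n_params, 1L)
  )
  out$p_value <- stats::pchisq(out$statistic, out$df, lower.tail = FALSE)
  class(out) <- c("ljung_box", "data.frame")
  out
}

#' Fit the seasonal-ARIMA arm on an original-scale daily series
#'
#' Differences the series per `spec`, fits (or prunes down to) a subset ARMA
#' on the differenced scale, and maps innovations back: because the inversion
#' uses observed lags, the diff-scale innovation at day `t` equals the
#' original-scale one-step error, so `fitted = observed - residual` with an
#' `NA` warm-up prefix of length `offset + max(ar_lags)`.
#'
#' @param x Numeric daily series (original scale), or a [daily_series()].
#' @param spec A [diff_spec()].
#' @param ar_lags,ma_lags Active lag sets for the differenced-scale ARMA.
#' @return An object of class `sarima_fit`: the `subset_arma` in `$model`,
#'   plus original-scale `$fitted` and `$residuals` aligned to `x`.
#' @export
fit_sarima <- function(x, spec = diff_spec(), ar_lags = integer(),
                       ma_lags = integer()) {
  if (inherits(x, "daily_series")) x <- x$values
  x <- as.numeric(x)
  w <- difference_series(x, spec)
  model <- fit_subset_arma(w, ar_lags = ar_lags, ma_lags = ma_lags)
  off <- diff_offset(spec)
  p <- if (length(model$ar_lags)) max(model$ar_lags) else 0L
  res <- rep(NA_real_, length(x))
  res[(off + p + 1L):length(x)] <- model$residuals_diff
  structure(
    list(model = model, spec = spec, series = x,
         fitted = x - res, residuals = res),
    class = "sarima_fit"
  )
}

#' @export
print.sarima_fit <- function(x, ...) {
  cat(sprintf("<sarima_fit> n = %d, differencing (d=%d, D=%d at lag %d)\n",
              length(x$series), x$spec$d, x$spec$D_order, x$spec$D_lag))
  print(x$model)
  invisible(x)
}

#' Forecast from a fitted seasonal-ARIMA arm
#'
#' Standard ARMA recursion on the differenced scale — future innovations set
#' to zero, past innovations taken from the fit — then inversion of the
#' differencing against the observed history. Values are returned on the
#' original scale and are not clipped or rounded.
#'
#' @param object A `sarima_fit`.
#' @param n_ahead Forecast horizon in days (default one week).
#' @param ... Unused.
#' @return Numeric vector of `n_ahead` forecasts.
#' @export
predict.sarima_fit <- function(object, n_ahead = 7L, ...) {
  n_ahead <- as.integer(n_ahead)
  if (is.na(n_ahead) || n_ahead < 1L) stop("`n_ahead` must be >= 1")
  m <- object$model
  w <- m$diff_series
  nw <- length(w)
  p <- if (length(m$ar_lags)) max(m$ar_lags) else 0L
  q <- if (length(m$ma_lags)) max(m$ma_lags) else 0L
  phi <- numeric(p); phi[m$ar_lags] <- m$ar_coef
  theta <- numeric(q); theta[m$ma_lags] <- m$ma_coef
  wext <- c(w, numeric(n_ahead))
  epsext <- c(numeric(p), m$residuals_diff, numeric(n_ahead))
  for (h in seq_len(n_ahead)) {
    t <- nw + h
    arpart <- if (p > 0L) sum(phi * wext[t - seq_len(p)]) else 0
    mapart <- if (q > 0L) sum(theta * epsext[t - seq_len(q)]) else 0
    wext[t] <- arpart - mapart
  }
  invert_difference(wext[(nw + 1L):(nw + n_ahead)], object$series, object$spec)
}

#' Simulate from a subset ARMA process
#'
#' Generates `w_t = sum phi_k w_{t-k} + eps_t - sum theta_k eps_{t-k}` with
#' Gaussian innovations, discarding a burn-in prefix. Used for parameter
#' recovery experiments and self-consistency tests.
#'
#' @param n Output length.
#' @param ar_lags,ar_coef,ma_lags,ma_coef Subset lag structure.
#' @param sd Innovation standard deviation.
#' @param n_burn Burn-in length.
#' @return Numeric vector of length `n`.
#' @export
simulate_subset_arma <- function(n, ar_lags = integer(), ar_coef = numeric(),
                                 ma_lags = integer(), ma_coef = numeric(),
                                 sd = 1, n_burn = 200L) {
  stopifnot(length(ar_lags) == length(ar_coef),
            length(ma_lags) == length(ma_coef))
  p <- if (length(ar_lags)) max(ar_lags) else 0L
  q <- if (length(ma_lags)) max(ma_lags) else 0L
  ntot <- n + n_burn
  eps <- stats::rnorm(ntot, 0, sd)
  mpart <- eps
  if (q > 0L) {
    theta <- numeric(q); theta[ma_lags] <- ma_coef
    mpart <- as.numeric(stats::filter(eps, c(1, -theta),
                                      method = "convolution", sides = 1))
    mpart[seq_len(q)] <- eps[seq_len(q)]
  }
  w <- mpart
  if (p > 0L) {
    phi <- numeric(p); phi[ar_lags] <- ar_coef
    w <- as.numeric(stats::filter(mpart, phi, method = "recursive",
                                  init = numeric(p)))
  }
  w[(n_burn + 1L):ntot]
}

#' Serialize / restore a subset ARMA model as plain text
#'
#' Key-value document (Debian-control format) carrying the lag sets,
#' coefficients, innovation variance and differencing specification, so a
#' fitted arm can be reused by the command-line interface.
#'
#' @param fit A `sarima_fit`.
#' @param path File path.
#' @return `write_sarima()` invisibly returns `path`; `read_sarima_spec()`
#'   returns a list with `spec`, `ar_lags`, `ar_coef`, `ma_lags`, `ma_coef`,
#'   `sigma2`.
#' @export
write_sarima <- function(fit, path) {
  stopifnot(inherits(fit, "sarima_fit"))
  m <- fit$model
  num <- function(v) paste(format(v, digits = 17), collapse = " ")
  df <- data.frame(
    d = fit$spec$d, D_order = fit$spec$D_order, D_lag = fit$spec$D_lag,
    ar_lags = paste(m$ar_lags, collapse = " "),
    ar_coef = num(m$ar_coef),
    ma_lags = paste(m$ma_lags, collapse = " "),
    ma_coef = num(m$ma_coef),
    sigma2 = num(m$sigma2)
  )
  write.dcf(df, path)
  invisible(path)
}

#' @rdname write_sarima
#' @export
read_sarima_spec <- function(path) {
  d <- as.data.frame(read.dcf(path), stringsAsFactors = FALSE)
  nums <- function(s) if (is.na(s) || !nzchar(s)) numeric() else
    as.numeric(strsplit(trimws(s), "\\s+")[[1]])
  list(
    spec = diff_spec(as.integer(d$d), as.integer(d$D_order), as.integer(d$D_lag)),
    ar_lags = as.integer(nums(d$ar_lags)), ar_coef = nums(d$ar_coef),
    ma_lags = as.integer(nums(d$ma_lags)), ma_coef = nums(d$ma_coef),
    sigma2 = as.numeric(d$sigma2)
  )
}
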