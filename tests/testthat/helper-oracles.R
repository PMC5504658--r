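# Independent brute-force oracles, kept deliberately naive (explicit loops,
# no shared code with the package internals) so they can cross-check the
# vectorised implementations.

# conditional residuals of a subset ARMA in the convention
#   w_t = sum phi_k w_{t-k} + eps_t - sum theta_k eps_{t-k},
# conditioning on the first max(ar_lags) observations, presample eps = 0
oracle_css_residuals <- function(w, ar_lags, ar_coef, ma_lags, ma_coef) {
  n <- length(w)
  p <- if (length(ar_lags)) max(ar_lags) else 0
  eps <- numeric(n)
  for (t in seq_len(n)) {
    if (t <= p) { eps[t] <- 0; next }
    val <- w[t]
    for (i in seq_along(ar_lags)) {
      k <- ar_lags[i]
      val <- val - ar_coef[i] * w[t - k]
    }
    for (j in seq_along(ma_lags)) {
      k <- ma_lags[j]
      if (t - k >= 1) val <- val + ma_coef[j] * eps[t - k]
    }
    eps[t] <- val
  }
  eps[(p + 1):n]
}

# recursive h-step forecast on the differenced scale, then manual inversion
# for one seasonal difference at lag L
oracle_forecast_original <- function(x, spec_L, ar_lags, ar_coef,
                                     ma_lags, ma_coef, h) {
  w <- x[(spec_L + 1):length(x)] - x[1:(length(x) - spec_L)]
  n <- length(w)
  p <- if (length(ar_lags)) max(ar_lags) else 0
  eps <- c(numeric(p), oracle_css_residuals(w, ar_lags, ar_coef, ma_lags, ma_coef))
  wf <- numeric(h)
  for (s in seq_len(h)) {
    val <- 0
    for (i in seq_along(ar_lags)) {
      k <- ar_lags[i]
      idx <- n + s - k
      val <- val + ar_coef[i] * (if (idx <= n) w[idx] else wf[idx - n])
    }
    for (j in seq_along(ma_lags)) {
      k <- ma_lags[j]
      idx <- n + s - k
      if (idx >= 1 && idx <= n) val <- val - ma_coef[j] * eps[idx]
    }
    wf[s] <- val
  }
  xx <- c(x, numeric(h))
  for (s in seq_len(h)) {
    xx[length(x) + s] <- wf[s] + xx[length(x) + s - spec_L]
  }
  xx[(length(x) + 1):(length(x) + h)]
}

# a small deterministic weekly series for structural tests
weekly_series <- function(weeks, profile = c(150, 140, 130, 120, 110, 60, 30),
                          start = "2014-01-06") {
  daily_series(rep(profile, weeks), start, label = "toy")
}
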