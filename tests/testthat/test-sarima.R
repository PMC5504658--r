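test_that("differencing matches its definition and annihilates the cycle", {
  expect_equal(difference_series(c(1, 2, 3, 4), diff_spec(d = 1, D_order = 0)),
               c(1, 1, 1))
  s <- rep(c(5, 9, 2, 8, 1, 7, 3), 6)
  expect_equal(difference_series(s, diff_spec()), rep(0, 35))
  expect_error(difference_series(1:5, diff_spec()), "too short")
})

test_that("invert_difference is the inverse of difference_series on the retained support", {
  set.seed(101)
  for (spec in list(diff_spec(), diff_spec(d = 1, D_order = 0),
                    diff_spec(d = 1, D_order = 1, D_lag = 7))) {
    x <- rnorm(60, 100, 10)
    w <- difference_series(x, spec)
    off <- spec$d + spec$D_order * spec$D_lag
    rebuilt <- invert_difference(w, x[seq_len(off)], spec)
    expect_equal(rebuilt, x[(off + 1):60], tolerance = 1e-12)
  }
  # all-zero differenced forecasts repeat the last observed week
  hist <- rep(c(10, 20, 30, 40, 50, 60, 70), 3)
  fc <- invert_difference(rep(0, 14), hist, diff_spec())
  expect_equal(fc, rep(c(10, 20, 30, 40, 50, 60, 70), 2))
  expect_error(invert_difference(0, 1:3, diff_spec()), "at least 7")
})

test_that("sample ACF/PACF behave like the standard estimators", {
  set.seed(102)
  x <- rnorm(2000)
  r <- sample_acf(x, 10)
  expect_equal(unname(r[1]), 1)
  expect_true(all(abs(r[-1]) < 3 / sqrt(2000) + 0.02))

  phi <- 0.5
  y <- as.numeric(stats::filter(rnorm(5000), phi, method = "recursive"))
  expect_equal(unname(sample_acf(y, 1)[2]), phi, tolerance = 0.1)
  expect_equal(unname(sample_pacf(y, 2)[1]), phi, tolerance = 0.1)
  # beyond lag 1 the partial autocorrelation of an AR(1) vanishes
  expect_lt(abs(sample_pacf(y, 2)[2]), 0.05)
  expect_error(sample_acf(rep(3, 50), 5), "zero-variance")
})

test_that("CSS residuals match a naive double-loop oracle", {
  set.seed(103)
  w <- rnorm(200)
  ar_lags <- c(1L, 4L); ar_coef <- c(0.3, -0.2)
  ma_lags <- c(2L, 7L); ma_coef <- c(0.25, -0.4)
  ours <- visitcast:::css_residuals(w, ar_lags, ar_coef, ma_lags, ma_coef)
  theirs <- oracle_css_residuals(w, ar_lags, ar_coef, ma_lags, ma_coef)
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("a no-term fit recovers the noise variance", {
  set.seed(104)
  w <- rnorm(1000, 0, 3)
  m <- fit_subset_arma(w)
  expect_equal(m$sigma2, mean(w^2), tolerance = 1e-12)
  expect_equal(m$sigma2, 9, tolerance = 0.8)
})

test_that("AR(1) coefficient is recovered within its asymptotic CI and agrees with stats::arima", {
  set.seed(105)
  n <- 3000
  w <- simulate_subset_arma(n, ar_lags = 1L, ar_coef = -0.5)
  m <- fit_subset_arma(w, ar_lags = 1L)
  se_asym <- sqrt((1 - 0.5^2) / n)
  expect_lt(abs(unname(m$ar_coef) - (-0.5)), 3 * se_asym + 0.03)
  # independent route: stats::arima with conditional sum of squares
  ref <- stats::arima(w, order = c(1, 0, 0), include.mean = FALSE,
                      method = "CSS")
  expect_equal(unname(m$ar_coef), unname(coef(ref)[1]), tolerance = 0.01)
  expect_equal(unname(m$se[1]), sqrt(ref$var.coef[1, 1]), tolerance = 0.01)
})

test_that("the Table-style subset model is recovered from its own simulation", {
  # self-consistency at n = 3000: AR at lag 1, sparse MA at lags 2,3,6,7
  set.seed(106)
  true_ar <- -0.51364
  true_ma <- c(0.45393, 0.25916, -0.14116, 0.42807)
  w <- simulate_subset_arma(3000, ar_lags = 1L, ar_coef = true_ar,
                            ma_lags = c(2L, 3L, 6L, 7L), ma_coef = true_ma)
  m <- fit_subset_arma(w, ar_lags = 1L, ma_lags = c(2L, 3L, 6L, 7L))
  est <- c(m$ar_coef, m$ma_coef)
  truth <- c(true_ar, true_ma)
  expect_true(all(abs(est - truth) <= 3 * m$se),
              info = paste(round(est - truth, 4), collapse = " "))
  # sign convention: a negative AR coefficient means (1 + |phi| B) in the
  # AR polynomial, i.e. the lag-1 autoregression pulls with alternating sign
  expect_lt(unname(m$ar_coef), 0)
})

test_that("the CSS objective never exceeds its value at the zero vector", {
  set.seed(107)
  for (i in 1:3) {
    w <- simulate_subset_arma(400, ar_lags = 1L, ar_coef = 0.6,
                              ma_lags = 1L, ma_coef = 0.3)
    m <- fit_subset_arma(w, ar_lags = 1L, ma_lags = 1L)
    expect_lte(m$rss, sum(w[-1]^2) + 1e-8)
  }
})

test_that("BIC selection finds white noise and strong autoregression", {
  set.seed(108)
  sel <- select_orders_bic(rnorm(500), p_max = 2, q_max = 2)
  expect_length(sel$ar_lags, 0)
  expect_length(sel$ma_lags, 0)
  # the winner's BIC is minimal over the whole candidate table by construction
  expect_true(all(sel$bic <= sel$table$bic + 1e-9))

  y <- simulate_subset_arma(500, ar_lags = 1L, ar_coef = 0.8)
  sel <- select_orders_bic(y, p_max = 2, q_max = 2)
  expect_gte(length(sel$ar_lags), 1)
})

test_that("pruning drops only insignificant terms and never adds any", {
  set.seed(109)
  w <- simulate_subset_arma(3000, ar_lags = 1L, ar_coef = 0.6)
  # significant model comes back unchanged
  m <- fit_subset_arma(w, ar_lags = 1L)
  expect_identical(prune_insignificant(m), m)
  # a spurious lag-5 term is dropped
  m2 <- prune_insignificant(fit_subset_arma(w, ar_lags = c(1L, 5L)))
  expect_equal(m2$ar_lags, 1L)
  k_before <- 2L
  expect_lte(length(m2$ar_lags) + length(m2$ma_lags), k_before)
})

test_that("Ljung-Box statistic follows its definition and matches Box.test", {
  set.seed(110)
  e <- rnorm(300)
  lb <- ljung_box(e, lags = c(6, 12, 18), n_params = 0)
  expect_true(all(diff(lb$statistic) >= 0))  # Q non-decreasing in m
  bt <- stats::Box.test(e, lag = 12, type = "Ljung-Box")
  expect_equal(lb$statistic[lb$lag == 12], unname(bt$statistic), tolerance = 1e-10)
  expect_equal(lb$p_value[lb$lag == 12], bt$p.value, tolerance = 1e-10)
  # df floor at 1
  lb2 <- ljung_box(e, lags = 2, n_params = 5)
  expect_equal(lb2$df, 1L)
  expect_error(ljung_box(rep(1, 50), lags = 6), "zero-variance")
  expect_error(ljung_box(e, lags = 400), "smaller than")
})

test_that("Ljung-Box type-I error is near the nominal 5% level", {
  set.seed(111)
  reps <- 500
  reject <- logical(reps)
  for (i in seq_len(reps)) {
    e <- rnorm(1000)
    lb <- ljung_box(e, lags = 12, n_params = 0)
    reject[i] <- lb$p_value < 0.05
  }
  expect_lt(abs(mean(reject) - 0.05), 0.02)
})

test_that("forecasts reduce to the seasonal naive under a null model and match the oracle otherwise", {
  s <- weekly_series(6)
  f0 <- fit_sarima(s$values, diff_spec())
  expect_equal(predict(f0, 7), s$values[1:7], tolerance = 1e-10)

  # brute-force oracle on a toy subset model
  set.seed(112)
  x <- rep(c(150, 140, 130, 120, 110, 60, 30), 5) + rnorm(35, 0, 5)
  fit <- fit_sarima(x, diff_spec(), ar_lags = 1L, ma_lags = 2L)
  ours <- predict(fit, 7)
  theirs <- oracle_forecast_original(
    x, 7L, fit$model$ar_lags, unname(fit$model$ar_coef),
    fit$model$ma_lags, unname(fit$model$ma_coef), 7L)
  expect_equal(ours, theirs, tolerance = 1e-10)
  expect_error(predict(fit, 0), ">= 1")
})

test_that("one-step fitted values are consistent with the residual identity", {
  set.seed(113)
  x <- rep(c(150, 140, 130, 120, 110, 60, 30), 8) + rnorm(56, 0, 4)
  fit <- fit_sarima(x, diff_spec(), ar_lags = 1L)
  ok <- !is.na(fit$residuals)
  expect_equal(fit$fitted[ok] + fit$residuals[ok], x[ok], tolerance = 1e-12)
  expect_equal(sum(!ok), 7 + 1)  # differencing offset + AR warm-up
})

test_that("a deterministic period-7 series is forecast exactly under one seasonal difference", {
  s <- weekly_series(8)
  w <- difference_series(s$values, diff_spec())
  expect_true(all(w == 0))
  fit <- fit_sarima(s$values, diff_spec())
  expect_equal(predict(fit, 14), rep(s$values[1:7], 2), tolerance = 1e-10)
})

test_that("model serialization round-trips through plain text", {
  set.seed(114)
  x <- rep(c(150, 140, 130, 120, 110, 60, 30), 8) + rnorm(56, 0, 4)
  fit <- fit_sarima(x, diff_spec(), ar_lags = 1L, ma_lags = c(2L, 7L))
  tmp <- withr::local_tempfile(fileext = ".dcf")
  write_sarima(fit, tmp)
  back <- read_sarima_spec(tmp)
  expect_equal(back$ar_lags, fit$model$ar_lags)
  expect_equal(back$ma_lags, fit$model$ma_lags)
  expect_equal(back$ar_coef, unname(fit$model$ar_coef), tolerance = 1e-12)
  expect_equal(back$ma_coef, unname(fit$model$ma_coef), tolerance = 1e-12)
  expect_equal(back$sigma2, fit$model$sigma2, tolerance = 1e-12)
})
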