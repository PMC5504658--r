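test_that("residual energy is the root sum of squares", {
  expect_equal(residual_energy(c(3, 4)), 5)
  expect_equal(residual_energy(rep(0, 5)), 0)
  expect_equal(residual_energy(-2.5), 2.5)
  expect_error(residual_energy(numeric()), "non-empty")
})

test_that("inverse-energy weights obey the defining identities", {
  expect_equal(unname(combine_weights(2, 2)), c(0.5, 0.5))
  expect_equal(unname(combine_weights(1, 3)), c(0.75, 0.25))
  expect_equal(unname(combine_weights(0, 3)), c(1, 0))
  expect_error(combine_weights(0, 0), "both")
  # monotonicity: the lower-energy arm always gets the larger weight
  grid <- expand.grid(E1 = c(0.1, 1, 2, 7), E2 = c(0.3, 1.5, 4))
  for (i in seq_len(nrow(grid))) {
    l <- combine_weights(grid$E1[i], grid$E2[i])
    expect_equal(sum(l), 1, tolerance = 1e-12)
    if (grid$E1[i] < grid$E2[i]) expect_gt(l[1], l[2])
    if (grid$E1[i] > grid$E2[i]) expect_lt(l[1], l[2])
  }
})

test_that("per-weekday weights reflect relative residual scale", {
  res <- lapply(1:7, function(i) rnorm(10))
  w_equal <- compute_weights_for_origin(res, res)
  expect_equal(w_equal$l1, rep(0.5, 7))
  scaled <- lapply(res, function(e) 2 * e)
  w_scaled <- compute_weights_for_origin(scaled, res)
  expect_equal(w_scaled$l1, rep(1 / 3, 7), tolerance = 1e-12)
  expect_equal(w_scaled$l2, rep(2 / 3, 7), tolerance = 1e-12)
  # degenerate perfect fits on both arms fall back to equal weights
  zero <- lapply(1:7, function(i) 0)
  expect_equal(compute_weights_for_origin(zero, zero)$l1, rep(0.5, 7))
})

test_that("the combined forecast is the per-day convex combination", {
  fx <- worked_example_fixture()
  w <- data.frame(day = 1:7, E1 = NA, E2 = NA, l1 = fx$eov$l1, l2 = fx$eov$l2)
  class(w) <- c("combination_weights", "data.frame")
  comb <- combined_forecast(fx$eov$arima, fx$eov$ses, w)
  expect_equal(comb[1], 0.53 * 194.40 + 0.47 * 196.76, tolerance = 1e-12)
  expect_true(all(comb >= pmin(fx$eov$arima, fx$eov$ses) - 1e-9 &
                  comb <= pmax(fx$eov$arima, fx$eov$ses) + 1e-9))
  w$l1 <- 1; w$l2 <- 0
  expect_equal(combined_forecast(fx$eov$arima, fx$eov$ses, w), fx$eov$arima)
  expect_error(combined_forecast(1:3, 1:3, w), "length 7")
})

test_that("rolling driver emits complete, structurally valid records", {
  s <- generate_series(scenario_preset("eov_like"))
  rec <- rolling_forecast(s, rolling_config(train_weeks = 43, p_max = 1,
                                            q_max = 7))
  expect_s3_class(rec, "forecast_records")
  expect_equal(nrow(rec), 56L)
  expect_equal(length(unique(rec$origin_week)), 8L)
  expect_true(all(table(rec$origin_week) == 7))
  # every origin covers weekdays 1..7 exactly once
  for (o in unique(rec$origin_week)) {
    expect_setequal(rec$day[rec$origin_week == o], 1:7)
  }
  # weights valid at every origin
  for (w in attr(rec, "weights")) {
    expect_equal(w$l1 + w$l2, rep(1, 7), tolerance = 1e-12)
    expect_true(all(w$l1 > 0 & w$l1 < 1))
  }
})

test_that("a noise-free weekly cycle is forecast perfectly by all three models", {
  s <- weekly_series(12)
  rec <- rolling_forecast(s, rolling_config(train_weeks = 8, p_max = 1,
                                            q_max = 1))
  expect_equal(rec$pred_arima, rec$observed, tolerance = 1e-8)
  expect_equal(rec$pred_ses, rec$observed, tolerance = 1e-8)
  expect_equal(rec$pred_combined, rec$observed, tolerance = 1e-8)
  rep <- build_report(rec)
  expect_equal(rep$combined$overall, 0, tolerance = 1e-8)
})

test_that("training-window combination is never worse than the worse arm", {
  # with weights computed from training residuals, the combined in-sample
  # squared error cannot exceed that of the worse single arm per weekday
  s <- generate_series(scenario_preset("flat_control"))
  panel <- to_weekday_panel(s)
  train <- split_train_test(panel, 43)$train
  x <- panel_to_series(train)$values
  fit <- fit_sarima(x, diff_spec(), ar_lags = 1L, ma_lags = 7L)
  ses <- ses_forecast_week(train)
  r1 <- visitcast:::slice_residuals_by_tau(fit$residuals)
  r2 <- lapply(ses$states, `[[`, "one_step_errors")
  wts <- compute_weights_for_origin(r1, r2)
  for (tau in 1:7) {
    e1 <- wts$E1[tau]^2; e2 <- wts$E2[tau]^2
    # energy of the weighted residual mix is bounded by the worse arm
    mix <- (wts$l1[tau]^2) * e1 + (wts$l2[tau]^2) * e2  # independent-case bound
    expect_lte(mix, max(e1, e2) + 1e-9)
  }
})

test_that("reruns under the same seed are byte-identical", {
  cfg <- scenario_preset("eov_like")
  run_once <- function() {
    s <- generate_series(cfg)
    rec <- rolling_forecast(s, rolling_config(train_weeks = 45, p_max = 1,
                                              q_max = 7))
    f <- tempfile(fileext = ".csv")
    write_forecast_records(rec, f)
    f
  }
  f1 <- run_once(); f2 <- run_once()
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  unlink(c(f1, f2))
})

test_that("failures are reported with the offending origin", {
  s <- weekly_series(7)  # too few weeks for SES after the first origins
  expect_error(
    rolling_forecast(s, rolling_config(train_weeks = 43)),
    "train_weeks")
})
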