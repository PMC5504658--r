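Package: visitcast
Title: Forecasting Daily Hospital Outpatient Visits with a Combined
    Seasonal ARIMA and Exponential Smoothing Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Short-term (one-week-ahead) forecasting of daily hospital
    outpatient visit counts. Fits a seasonal ARIMA arm (lag-7 differencing,
    subset-lag ARMA estimated by conditional least squares with BIC order
    selection and significance pruning) on the daily series, a single
    exponential smoothing arm on each day-of-week sub-series, and combines
    the two by per-weekday inverse error-energy weights. Includes holiday
    singularity preprocessing (2-SD rule with neighbour-week replacement),
    a rolling-origin evaluation driver with MAPE-based reports, a synthetic
    demand generator for testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
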