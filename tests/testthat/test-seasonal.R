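test_that("design matrix has the documented columns and phases", {
  spec <- seasonal_spec(periods = data.frame(period = 7, order = 1L),
                        n_changepoints = 0L)
  dm <- design_matrix(0:27, spec)
  expect_identical(ncol(dm$X), 4L)   # intercept, t, cos, sin
  expect_equal(unname(dm$X[1, "cos_7_1"]), 1)  # cos at t = 0
  expect_equal(unname(dm$X[1, "sin_7_1"]), 0)  # sin at t = 0
  # periodicity: columns at t and t + P coincide
  expect_equal(dm$X[1:7, c("cos_7_1", "sin_7_1")],
               dm$X[8:14, c("cos_7_1", "sin_7_1")], tolerance = 1e-12)

  spec2 <- seasonal_spec(periods = data.frame(period = c(7, 365.25), order = c(2L, 3L)),
                         n_changepoints = 4L, effects = "holiday")
  dm2 <- design_matrix(1:365, spec2, calendar = calendar_2019())
  # 2 + 4 changepoints + 2 * (2 + 3) harmonics + 1 effect
  expect_identical(ncol(dm2$X), 2L + 4L + 10L + 1L)
  expect_identical(dm2$meta$component[dm2$meta$column == "effect_holiday"],
                   "effect_holiday")

  expect_error(design_matrix(1:10, spec, changepoints = 50), "outside")
})

test_that("a model-generating series is fitted and forecast essentially exactly", {
  spec <- seasonal_spec(periods = data.frame(period = 7, order = 1L),
                        n_changepoints = 0L, lambda_seasonal = 1e-8)
  t <- 1:140
  y <- 100 + 0.2 * t + 5 * cos(2 * pi * t / 7) - 3 * sin(2 * pi * t / 7)
  fit <- fit_seasonal(y, spec, time = t, bootstrap = 0L)
  expect_lt(max(abs(fit$residuals)), 1e-6)
  cv <- rolling_cv(y, spec, initial_train = 70, horizon = 14, step = 14, time = t)
  expect_lt(cv$mean_rmse, 1e-6)
})

test_that("predictions decompose exactly into trend, seasonal and effect parts", {
  set.seed(10)
  cal <- calendar_2019()
  spec <- seasonal_spec(periods = data.frame(period = c(7, 365.25), order = c(2L, 3L)),
                        n_changepoints = 5L, effects = c("holiday", "event"))
  y <- 100 + rnorm(365, sd = 5) + 10 * sin(2 * pi * (1:365) / 365.25)
  fit <- fit_seasonal(y, spec, time = 1:365, calendar = cal, bootstrap = 0L)
  total <- predict(fit)
  parts <- sapply(unique(fit$meta$component),
                  function(cmp) predict(fit, component = cmp))
  expect_equal(rowSums(parts), total, tolerance = 1e-9)
  expect_equal(total, fit$fitted, tolerance = 1e-9)
})

test_that("refitting with the same seed is bit-stable", {
  set.seed(2)
  y <- 50 + rnorm(120)
  spec <- seasonal_spec(periods = data.frame(period = 7, order = 1L),
                        n_changepoints = 2L)
  a <- fit_seasonal(y, spec, bootstrap = 50L, seed = 7L)
  b <- fit_seasonal(y, spec, bootstrap = 50L, seed = 7L)
  expect_identical(a$coefficients, b$coefficients)
  expect_identical(a$coef_intervals, b$coef_intervals)
  expect_identical(a$components, b$components)
})

test_that("injected amplitudes are recovered and null components flagged non-significant", {
  # yearly amplitude 0.3 * mean, no weekly/monthly signal, SNR = 3
  mean_level <- 100
  amp <- 0.3 * mean_level
  t <- 1:365
  truth <- mean_level + amp * sin(2 * pi * t / 365.25)
  set.seed(123)
  y <- truth + rnorm(365, sd = amp / 3)
  spec <- seasonal_spec(
    periods = data.frame(period = c(7, 30.5, 365.25), order = c(2L, 2L, 3L)),
    n_changepoints = 0L
  )
  fit <- fit_seasonal(y, spec, time = t, bootstrap = 300L, seed = 99L)
  comp <- fit$components

  yearly <- comp[comp$component == "seasonal_P365.25", ]
  monthly <- comp[comp$component == "seasonal_P30.5", ]

  expect_true(yearly$significant)
  expect_false(monthly$significant)
  # relative amplitude error < 20% and truth inside the bootstrap interval
  expect_lt(abs(yearly$amplitude - amp) / amp, 0.2)
  expect_gte(amp, yearly$lo)
  expect_lte(amp, yearly$hi)

  # constant series: all amplitudes near zero, trend slope near zero
  flat <- fit_seasonal(rep(42, 365), spec, time = t, bootstrap = 0L)
  expect_lt(max(flat$components$amplitude), 1e-6)
})

test_that("significance flags have high power and a near-nominal false-positive rate", {
  # the interval rule is a 5%-level test per component, so a single noise
  # realization can legitimately flag a null block; the property to hold is
  # the rate: yearly (true signal) always flagged, weekly/monthly (null)
  # rarely flagged.
  t <- 1:365; amp <- 30
  spec <- seasonal_spec(
    periods = data.frame(period = c(7, 30.5, 365.25), order = c(2L, 2L, 3L)),
    n_changepoints = 0L)
  flags <- sapply(1:10, function(s) {
    set.seed(s)
    y <- 100 + amp * sin(2 * pi * t / 365.25) + rnorm(365, sd = amp / 3)
    fit <- fit_seasonal(y, spec, time = t, bootstrap = 300L, seed = 99L)
    comp <- fit$components
    c(yearly = comp$significant[comp$component == "seasonal_P365.25"],
      weekly = comp$significant[comp$component == "seasonal_P7"],
      monthly = comp$significant[comp$component == "seasonal_P30.5"],
      amp_ok = abs(comp$amplitude[comp$component == "seasonal_P365.25"] - amp) / amp < 0.2)
  })
  expect_true(all(flags["yearly", ]))
  expect_true(all(flags["amp_ok", ]))
  # 20 null-component decisions at ~5-10% false-positive rate: seeing more
  # than 5 flags would indicate a miscalibrated rule
  expect_lte(sum(flags["weekly", ]) + sum(flags["monthly", ]), 5L)
})

test_that("rolling cross-validation respects chronology and window arithmetic", {
  set.seed(31)
  y <- 100 + 20 * sin(2 * pi * (1:365) / 365.25) + rnorm(365, sd = 4)
  spec <- seasonal_spec(periods = data.frame(period = 365.25, order = 2L),
                        n_changepoints = 0L)
  cv <- rolling_cv(y, spec, initial_train = 180, horizon = 14, step = 14)
  expect_identical(nrow(cv$windows), 13L)  # floor((365-180-14)/14) + 1
  expect_true(all(cv$windows$cutoff >= 180))
  expect_true(all(cv$windows$cutoff + 14 <= 365))
  expect_equal(cv$mean_rmse, mean(cv$windows$rmse))

  expect_error(rolling_cv(y, spec, initial_train = 180, horizon = 0),
               "horizon")
  expect_error(rolling_cv(y, spec, initial_train = 360, horizon = 14),
               "too short")
})

test_that("cross-validation prefers the true seasonal structure", {
  set.seed(77)
  y <- 100 + 20 * sin(2 * pi * (1:365) / 365.25) + rnorm(365, sd = 4)
  with_yearly <- seasonal_spec(periods = data.frame(period = 365.25, order = 2L),
                               n_changepoints = 0L)
  without <- seasonal_spec(periods = data.frame(period = numeric(0), order = integer(0)),
                           n_changepoints = 0L)
  cv_with <- rolling_cv(y, with_yearly, initial_train = 180, horizon = 28, step = 28)
  cv_without <- rolling_cv(y, without, initial_train = 180, horizon = 28, step = 28)
  expect_lt(cv_with$mean_rmse, cv_without$mean_rmse)
})
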