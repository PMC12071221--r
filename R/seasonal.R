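#' Specification of the additive seasonal demand model
#'
#' The model decomposes a demand series into a piecewise-linear trend g(t),
#' Fourier seasonal blocks s(t) and calendar-effect regressors h(t) plus
#' Gaussian noise: `y(t) = g(t) + s(t) + h(t) + e(t)`. Each seasonal block
#' with period P and order K contributes `sum_k a_k cos(2 pi k t / P) +
#' b_k sin(2 pi k t / P)`.
#'
#' @param periods data.frame with columns `period` (in units of the time
#'   index, e.g. 7 or 365.25 for daily data, 24 for hourly data) and `order`
#'   (number of harmonics K >= 1). Default: weekly (K = 2) and yearly
#'   (K = 6) blocks for a daily series.
#' @param n_changepoints Number of evenly spaced trend changepoint
#'   candidates over the first `changepoint_range` of the training span
#'   (default 12).
#' @param changepoint_range Fraction of the training span eligible for
#'   changepoints (default 0.8).
#' @param effects Character subset of `c("break", "holiday", "event")`;
#'   indicator regressors taken from a study calendar.
#' @param lambda_seasonal Ridge penalty on Fourier and effect coefficients
#'   (default 0.1; small relative to the information in a year of data, so
#'   genuine amplitudes are essentially unshrunk).
#' @param lambda_changepoint Ridge penalty on changepoint slope deltas
#'   (default 10; strong shrinkage keeps the trend from chasing
#'   seasonality).
#' @return List of class `seasonal_spec`.
#' @export
seasonal_spec <- function(periods = data.frame(period = c(7, 365.25), order = c(2L, 6L)),
                          n_changepoints = 12L,
                          changepoint_range = 0.8,
                          effects = character(0),
                          lambda_seasonal = 0.1,
                          lambda_changepoint = 10) {
  periods <- as.data.frame(periods)
  if (nrow(periods) > 0 && (any(periods$period <= 0) || any(periods$order < 1L))) {
    stop("seasonal periods must be positive with order >= 1")
  }
  bad <- setdiff(effects, c("break", "holiday", "event"))
  if (length(bad) > 0L) stop("unknown effect(s): ", paste(bad, collapse = ", "))
  structure(list(
    periods = periods,
    n_changepoints = as.integer(n_changepoints),
    changepoint_range = changepoint_range,
    effects = effects,
    lambda_seasonal = lambda_seasonal,
    lambda_changepoint = lambda_changepoint
  ), class = "seasonal_spec")
}

# Evenly spaced changepoint candidates over the first part of the span.
default_changepoints <- function(time, spec) {
  if (spec$n_changepoints < 1L) return(numeric(0))
  span <- range(time)
  upper <- span[1L] + spec$changepoint_range * diff(span)
  cps <- seq(span[1L], upper, length.out = spec$n_changepoints + 1L)[-1L]
  cps
}

#' Design matrix for the additive seasonal model
#'
#' Columns: intercept, linear time, one hinge `max(0, t - c)` per
#' changepoint, cos/sin pairs per (period, harmonic) and one indicator per
#' calendar effect. Column metadata assigns each column to a component
#' (`trend`, `seasonal_P<period>`, `effect_<name>`).
#'
#' @param time Numeric time index (e.g. day of year 1..365).
#' @param spec `seasonal_spec`.
#' @param calendar `cep_calendar`, required when `spec$effects` is
#'   non-empty; `time` then indexes calendar rows.
#' @param changepoints Changepoint locations; default: computed from the
#'   span of `time` per the spec. Changepoints outside the span are an
#'   error.
#' @return List: `X` (matrix), `meta` (data.frame `column`, `component`),
#'   `changepoints`.
#' @export
design_matrix <- function(time, spec, calendar = NULL, changepoints = NULL) {
  if (is.null(changepoints)) changepoints <- default_changepoints(time, spec)
  if (length(changepoints) > 0 &&
      (min(changepoints) < min(time) || max(changepoints) > max(time))) {
    stop("changepoint outside the time span")
  }
  scale_t <- max(time) - min(time)
  if (scale_t == 0) scale_t <- 1
  t0 <- min(time)
  cols <- list(intercept = rep(1, length(time)),
               t = (time - t0) / scale_t)
  comp <- c("trend", "trend")
  for (j in seq_along(changepoints)) {
    cols[[paste0("hinge_", j)]] <- pmax(0, (time - changepoints[j]) / scale_t)
    comp <- c(comp, "trend")
  }
  if (nrow(spec$periods) > 0) {
    for (i in seq_len(nrow(spec$periods))) {
      P <- spec$periods$period[i]
      K <- spec$periods$order[i]
      label <- paste0("seasonal_P", format(P, trim = TRUE))
      for (k in seq_len(K)) {
        cols[[paste0("cos_", P, "_", k)]] <- cos(2 * pi * k * time / P)
        cols[[paste0("sin_", P, "_", k)]] <- sin(2 * pi * k * time / P)
        comp <- c(comp, label, label)
      }
    }
  }
  if (length(spec$effects) > 0L) {
    if (is.null(calendar)) stop("calendar required for effect regressors")
    idx <- match(time, calendar$day_of_year)
    if (anyNA(idx)) stop("time points outside the calendar for effect regressors")
    flag_col <- c(`break` = "is_break", holiday = "is_holiday", event = "is_event")
    for (ef in spec$effects) {
      cols[[paste0("effect_", ef)]] <- as.numeric(calendar[[flag_col[[ef]]]][idx])
      comp <- c(comp, paste0("effect_", ef))
    }
  }
  X <- do.call(cbind, cols)
  list(X = X,
       meta = data.frame(column = colnames(X), component = comp,
                         stringsAsFactors = FALSE),
       changepoints = changepoints,
       t0 = t0, scale_t = scale_t)
}

#' Fit the additive seasonal model
#'
#' Coefficients are estimated by ridge-penalized least squares (the
#' Gaussian-prior maximum a posteriori analogue of the Bayesian additive
#' fit); intercept and base slope are unpenalized. Coefficient 95%
#' intervals come from a seeded parametric bootstrap: residual noise is
#' re-drawn around the fitted curve and the penalized fit repeated. A
#' component is flagged significant when any of its coefficients'
#' Bonferroni-corrected intervals excludes zero.
#'
#' @param y Numeric response (counts; no missing values).
#' @param spec `seasonal_spec`.
#' @param time Time index, default `seq_along(y)`.
#' @param calendar Calendar for effect regressors (see [design_matrix()]).
#' @param bootstrap Number of bootstrap replicates (default 500; 0 skips
#'   intervals).
#' @param seed Seed for the bootstrap.
#' @return Object of class `seasonal_fit`: coefficients, fitted values,
#'   residuals, `noise_scale`, per-coefficient intervals, component table.
#' @export
fit_seasonal <- function(y, spec, time = seq_along(y), calendar = NULL,
                         bootstrap = 500L, seed = 1L) {
  if (anyNA(y)) stop("series contains missing values; fill or drop gaps first")
  dm <- design_matrix(time, spec, calendar)
  X <- dm$X
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("series shorter than the number of model columns (", p, ")")
  pen <- numeric(p)
  pen[dm$meta$component == "trend"] <- spec$lambda_changepoint
  pen[dm$meta$column %in% c("intercept", "t")] <- 0
  pen[startsWith(dm$meta$component, "seasonal_")] <- spec$lambda_seasonal
  pen[startsWith(dm$meta$component, "effect_")] <- spec$lambda_seasonal

  XtX <- crossprod(X) + diag(pen, p)
  solver <- solve(XtX, t(X))          # p x n: beta = solver %*% y
  beta <- drop(solver %*% y)
  names(beta) <- colnames(X)
  fitted <- drop(X %*% beta)
  resid <- y - fitted
  sigma <- sqrt(sum(resid^2) / max(n - p, 1L))

  coef_int <- NULL
  beta_boot <- NULL
  if (bootstrap > 0L) {
    set.seed(seed)
    Ystar <- matrix(stats::rnorm(n * bootstrap, mean = fitted, sd = sigma),
                    nrow = n, ncol = bootstrap)
    beta_boot <- solver %*% Ystar     # p x B
    coef_int <- t(apply(beta_boot, 1L, stats::quantile, probs = c(0.025, 0.975)))
    colnames(coef_int) <- c("lo", "hi")
    rownames(coef_int) <- colnames(X)
  }

  fit <- structure(list(
    spec = spec, coefficients = beta, meta = dm$meta,
    changepoints = dm$changepoints, t0 = dm$t0, scale_t = dm$scale_t,
    time = time, fitted = fitted, residuals = resid,
    noise_scale = sigma, coef_intervals = coef_int,
    beta_boot = beta_boot, bootstrap = bootstrap, seed = seed,
    calendar = calendar
  ), class = "seasonal_fit")
  fit$components <- component_report(fit)
  fit
}

#' Predict from a fitted seasonal model
#'
#' @param object `seasonal_fit`.
#' @param time Time points to predict at (default: training times).
#' @param component Optional component label (see the fit's `meta`) to
#'   return only that additive part; the parts sum exactly to the full
#'   prediction.
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.seasonal_fit <- function(object, time = object$time, component = NULL, ...) {
  dm <- design_matrix_like(object, time)
  keep <- if (is.null(component)) {
    rep(TRUE, ncol(dm$X))
  } else {
    dm$meta$component == component
  }
  drop(dm$X[, keep, drop = FALSE] %*% object$coefficients[keep])
}

# Rebuild a design matrix at new times with the training-time scaling,
# changepoints and calendar.
design_matrix_like <- function(fit, time) {
  spec <- fit$spec
  X <- list(intercept = rep(1, length(time)),
            t = (time - fit$t0) / fit$scale_t)
  comp <- c("trend", "trend")
  for (j in seq_along(fit$changepoints)) {
    X[[paste0("hinge_", j)]] <- pmax(0, (time - fit$changepoints[j]) / fit$scale_t)
    comp <- c(comp, "trend")
  }
  if (nrow(spec$periods) > 0) {
    for (i in seq_len(nrow(spec$periods))) {
      P <- spec$periods$period[i]; K <- spec$periods$order[i]
      label <- paste0("seasonal_P", format(P, trim = TRUE))
      for (k in seq_len(K)) {
        X[[paste0("cos_", P, "_", k)]] <- cos(2 * pi * k * time / P)
        X[[paste0("sin_", P, "_", k)]] <- sin(2 * pi * k * time / P)
        comp <- c(comp, label, label)
      }
    }
  }
  if (length(spec$effects) > 0L) {
    idx <- match(time, fit$calendar$day_of_year)
    if (anyNA(idx)) stop("time points outside the calendar for effect regressors")
    flag_col <- c(`break` = "is_break", holiday = "is_holiday", event = "is_event")
    for (ef in spec$effects) {
      X[[paste0("effect_", ef)]] <- as.numeric(fit$calendar[[flag_col[[ef]]]][idx])
      comp <- c(comp, paste0("effect_", ef))
    }
  }
  Xm <- do.call(cbind, X)
  list(X = Xm, meta = data.frame(column = colnames(Xm), component = comp,
                                 stringsAsFactors = FALSE))
}

#' Per-component significance table
#'
#' One row per component (trend, each seasonal block, each effect) with the
#' point amplitude (maximum absolute value of the component curve over the
#' training span; for the trend, the base slope per unit of scaled time),
#' its bootstrap 95% interval and the significance flag: any coefficient's
#' Bonferroni-corrected interval excluding zero.
#'
#' @param fit `seasonal_fit`.
#' @return data.frame: `component`, `amplitude`, `lo`, `hi`, `significant`.
#' @export
component_report <- function(fit) {
  comps <- unique(fit$meta$component)
  dm <- design_matrix_like(fit, fit$time)
  rows <- lapply(comps, function(cmp) {
    sel <- dm$meta$component == cmp
    amp_of <- function(b) {
      if (cmp == "trend") return(unname(b[dm$meta$column == "t"]))
      max(abs(drop(dm$X[, sel, drop = FALSE] %*% b[sel])))
    }
    amplitude <- amp_of(fit$coefficients)
    lo <- hi <- NA_real_; signif <- NA
    if (!is.null(fit$beta_boot)) {
      amps <- apply(fit$beta_boot, 2L, amp_of)
      qs <- stats::quantile(amps, c(0.025, 0.975))
      lo <- qs[[1L]]; hi <- qs[[2L]]
      m <- sum(sel & !(dm$meta$column %in% c("intercept")))
      alpha <- 0.05 / max(m, 1L)
      ints <- t(apply(fit$beta_boot[sel, , drop = FALSE], 1L,
                      stats::quantile, probs = c(alpha / 2, 1 - alpha / 2)))
      keep <- dm$meta$column[sel] != "intercept"
      ints <- ints[keep, , drop = FALSE]
      signif <- any(ints[, 1L] > 0 | ints[, 2L] < 0)
    }
    data.frame(component = cmp, amplitude = amplitude, lo = lo, hi = hi,
               significant = signif, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Rolling-origin cross-validation
#'
#' Chronological train/forecast windows: train on observations up to a
#' cutoff, forecast the next `horizon` points, score by RMSE, slide the
#' cutoff by `step` and repeat. No test point ever precedes its cutoff.
#'
#' @param y Series.
#' @param spec `seasonal_spec`.
#' @param initial_train Length of the first training window.
#' @param horizon Forecast length per window (> 0).
#' @param step Cutoff increment (default: `horizon`).
#' @param time Time index (default `seq_along(y)`).
#' @param calendar Calendar for effect regressors.
#' @return List of class `cv_report`: `windows` (data.frame `cutoff`,
#'   `rmse`), `horizon`, `mean_rmse`.
#' @export
rolling_cv <- function(y, spec, initial_train, horizon, step = horizon,
                       time = seq_along(y), calendar = NULL) {
  n <- length(y)
  if (horizon < 1L) stop("horizon must be positive")
  if (initial_train + horizon > n) stop("series too short for the requested windows")
  cutoffs <- seq(initial_train, n - horizon, by = step)
  rmse <- vapply(cutoffs, function(cut) {
    tr <- seq_len(cut)
    te <- seq(cut + 1L, cut + horizon)
    fit <- fit_seasonal(y[tr], spec, time = time[tr], calendar = calendar,
                        bootstrap = 0L)
    pred <- predict(fit, time = time[te])
    sqrt(mean((y[te] - pred)^2))
  }, numeric(1L))
  structure(list(
    windows = data.frame(cutoff = time[cutoffs], rmse = rmse),
    horizon = horizon,
    mean_rmse = mean(rmse)
  ), class = "cv_report")
}
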