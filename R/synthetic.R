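#' Configuration for the synthetic call-event generator
#'
#' The generator emulates one year of non-time-critical call events with the
#' structure the downstream analysis assumes: per-station Poisson counts per
#' day and hour slot, a diurnal shape, mild weekly and yearly modulation and
#' multiplicative uplifts on break/holiday/event days. Annual volumes and
#' transport probabilities default to the 2019 registry counts; the default
#' diurnal shape is the Wandsbek hourly profile (the only full 24-slot
#' profile available), normalized to sum to one.
#'
#' @param registry `station_registry` supplying station ids, default annual
#'   volumes (`ops_total`) and transport probabilities
#'   (`ops_with / ops_total`).
#' @param year Study year (non-leap), default 2019.
#' @param annual_volume Optional named vector of expected annual event counts
#'   per station abbreviation (overrides registry totals).
#' @param transport_probability Optional named vector of probabilities that
#'   an operation ends with hospital transport.
#' @param diurnal_shape 24 non-negative weights, normalized internally.
#' @param weekly_amplitude Relative amplitude of the weekday modulation
#'   (default 0.04: observed weekday totals vary about +/-4% around their
#'   mean).
#' @param yearly_amplitude Relative amplitude of the smooth annual cycle
#'   (default 0.15).
#' @param effect_uplifts Named multiplicative factors for flagged days,
#'   default `c(break_ = 1.05, holiday = 1.08, event = 1.20)` (event weeks
#'   run up to ~20-28% above the weekly average).
#' @param seed Master seed; per-station streams are derived from it.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(registry,
                             year = 2019L,
                             annual_volume = NULL,
                             transport_probability = NULL,
                             diurnal_shape = NULL,
                             weekly_amplitude = 0.04,
                             yearly_amplitude = 0.15,
                             effect_uplifts = c(break_ = 1.05, holiday = 1.08, event = 1.20),
                             seed = 1L) {
  vol <- stats::setNames(as.numeric(registry$ops_total), registry$abbr)
  if (!is.null(annual_volume)) vol[names(annual_volume)] <- annual_volume
  if (any(vol < 0)) stop("annual_volume must be non-negative")

  tp <- stats::setNames(ifelse(registry$ops_total > 0,
                               registry$ops_with / pmax(registry$ops_total, 1), 0),
                        registry$abbr)
  if (!is.null(transport_probability)) tp[names(transport_probability)] <- transport_probability
  if (any(tp < 0 | tp > 1)) stop("transport_probability must lie in [0, 1]")

  if (is.null(diurnal_shape)) diurnal_shape <- load_wandsbek_hourly()$rate
  if (length(diurnal_shape) != 24L || any(diurnal_shape < 0) || sum(diurnal_shape) <= 0) {
    stop("diurnal_shape must be 24 non-negative weights with positive sum")
  }
  if (any(effect_uplifts <= 0)) stop("effect uplifts must be positive")
  if (weekly_amplitude < 0 || weekly_amplitude >= 1 ||
      yearly_amplitude < 0 || yearly_amplitude >= 1) {
    stop("seasonal amplitudes must lie in [0, 1)")
  }
  uplifts <- c(break_ = 1, holiday = 1, event = 1)
  uplifts[names(effect_uplifts)] <- effect_uplifts

  structure(list(
    year = as.integer(year),
    stations = registry$abbr,
    annual_volume = vol,
    transport_probability = tp,
    diurnal_shape = diurnal_shape / sum(diurnal_shape),
    weekly_amplitude = weekly_amplitude,
    yearly_amplitude = yearly_amplitude,
    effect_uplifts = uplifts,
    seed = as.integer(seed)
  ), class = "generator_config")
}

#' Scale a generator configuration by area-level demand multipliers
#'
#' Applies per-area multiplicative factors to every station's expected
#' annual volume, e.g. to mimic the 2021-like demand shift (East +19%,
#' South +22%, West +14% relative to 2019). Everything else is unchanged.
#'
#' @param config `generator_config`.
#' @param multipliers Named numeric vector with one positive factor per
#'   area, default `c(East = 1.19, South = 1.22, West = 1.14)`.
#' @param registry `station_registry` mapping stations to areas.
#' @return The rescaled `generator_config`.
#' @export
apply_scenario <- function(config,
                           multipliers = c(East = 1.19, South = 1.22, West = 1.14),
                           registry) {
  if (any(multipliers <= 0)) stop("scenario multipliers must be positive")
  areas <- registry$area[match(names(config$annual_volume), registry$abbr)]
  unknown <- setdiff(unique(areas), names(multipliers))
  if (length(unknown) > 0L) stop("no multiplier for area(s): ",
                                 paste(unknown, collapse = ", "))
  config$annual_volume <- config$annual_volume * multipliers[areas]
  config
}

# Expected intensity matrix (365 x 24) for one station before volume scaling.
station_intensity <- function(config, calendar, volume) {
  wmod <- 1 + config$weekly_amplitude * cos(2 * pi * (calendar$weekday - 1) / 7)
  ymod <- 1 - config$yearly_amplitude * cos(2 * pi * calendar$day_of_year / 365)
  uplift <- ifelse(calendar$is_break, config$effect_uplifts[["break_"]], 1) *
    ifelse(calendar$is_holiday, config$effect_uplifts[["holiday"]], 1) *
    ifelse(calendar$is_event, config$effect_uplifts[["event"]], 1)
  day_part <- wmod * ymod * uplift
  lam <- outer(day_part, config$diurnal_shape)
  if (volume == 0) return(lam * 0)
  lam * (volume / sum(lam))
}

#' Generate one year of synthetic call events
#'
#' For station s, day d and hour slot h, the event count is Poisson with
#' intensity `base_s * shape_h * weekly(weekday) * yearly(day) * uplift(flags)`,
#' where `base_s` is scaled so the expected annual total equals the
#' configured volume. Transport outcomes are Bernoulli with the station's
#' transport probability. Each station uses its own random stream derived
#' deterministically from the master seed and the station's position, so a
#' fixed seed reproduces the table bit for bit.
#'
#' @param registry `station_registry`.
#' @param calendar `cep_calendar` for the configured year.
#' @param config `generator_config`.
#' @return Call-event data.frame with columns `station`, `date`,
#'   `hour_slot`, `transported`, ordered by station, date, hour.
#' @export
generate_year <- function(registry, calendar, config) {
  stopifnot(inherits(config, "generator_config"))
  if (nrow(calendar) != 365L) stop("calendar must cover a 365-day year")
  out <- vector("list", length(config$stations))
  for (i in seq_along(config$stations)) {
    st <- config$stations[i]
    lam <- station_intensity(config, calendar, config$annual_volume[[st]])
    set.seed((config$seed + 7919L * i) %% .Machine$integer.max)
    counts <- matrix(stats::rpois(length(lam), lam), nrow = nrow(lam))
    idx <- which(counts > 0, arr.ind = TRUE)
    if (nrow(idx) == 0L) { out[[i]] <- NULL; next }
    n_rep <- counts[idx]
    events <- data.frame(
      station = st,
      date = rep(calendar$date[idx[, 1L]], n_rep),
      hour_slot = rep(idx[, 2L] - 1L, n_rep)
    )
    events <- events[order(events$date, events$hour_slot), , drop = FALSE]
    events$transported <- stats::rbinom(nrow(events), 1L,
                                        config$transport_probability[[st]]) == 1L
    out[[i]] <- events
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
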