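#' Validate a call-event table
#'
#' @param events data.frame with columns `station` (registry abbreviation),
#'   `date` (Date or ISO-8601 string), `hour_slot` (0..23) and `transported`
#'   (logical).
#' @param registry A `station_registry`; stations must be registered.
#' @param calendar Optional `cep_calendar`; when given, event dates must fall
#'   inside the calendar year.
#' @return The validated events, `date` coerced to `Date`.
#' @export
validate_events <- function(events, registry, calendar = NULL) {
  req <- c("station", "date", "hour_slot", "transported")
  missing <- setdiff(req, names(events))
  if (length(missing) > 0L) {
    stop("event table is missing column(s): ", paste(missing, collapse = ", "))
  }
  events$date <- as.Date(events$date)
  unknown <- setdiff(unique(events$station), registry$abbr)
  if (length(unknown) > 0L) {
    stop("event table references unregistered station(s): ",
         paste(unknown, collapse = ", "))
  }
  if (any(events$hour_slot < 0 | events$hour_slot > 23)) {
    stop("hour_slot outside 0..23")
  }
  if (!is.null(calendar) && (any(events$date < calendar$date[1L]) ||
                             any(events$date > calendar$date[nrow(calendar)]))) {
    stop("event dates outside the calendar year")
  }
  events
}

#' Aggregate call events over chosen keys
#'
#' Counts events for every combination of the requested keys, reporting
#' zero for combinations that did not occur, so aggregation always
#' conserves the total event count.
#'
#' @param events Validated call-event table.
#' @param keys Non-empty subset of `station`, `week`, `weekday`,
#'   `hour_slot`, `day_of_year`.
#' @param calendar `cep_calendar` used to map dates to week/weekday/
#'   day-of-year (required for those keys).
#' @param registry Optional registry; when supplied, zero rows are emitted
#'   for registered stations that produced no events.
#' @return data.frame with one column per key plus `count`.
#' @export
aggregate_events <- function(events, keys, calendar = NULL, registry = NULL) {
  valid <- c("station", "week", "weekday", "hour_slot", "day_of_year")
  if (length(keys) == 0L) stop("at least one aggregation key is required")
  bad <- setdiff(keys, valid)
  if (length(bad) > 0L) stop("unknown aggregation key(s): ", paste(bad, collapse = ", "))

  cal_keys <- intersect(keys, c("week", "weekday", "day_of_year"))
  if (length(cal_keys) > 0L) {
    if (is.null(calendar)) stop("calendar required for key(s): ",
                                paste(cal_keys, collapse = ", "))
    idx <- match(as.Date(events$date), calendar$date)
    if (anyNA(idx)) stop("event dates outside the calendar year")
    for (k in cal_keys) events[[k]] <- calendar[[k]][idx]
  }

  levels_for <- function(k) {
    switch(k,
      station = if (!is.null(registry)) registry$abbr else sort(unique(events$station)),
      week = 1:52, weekday = 1:7, hour_slot = 0:23, day_of_year = 1:365)
  }
  factors <- lapply(keys, function(k) factor(events[[k]], levels = levels_for(k)))
  names(factors) <- keys
  tab <- as.data.frame(table(factors), stringsAsFactors = FALSE)
  names(tab)[ncol(tab)] <- "count"
  for (k in keys) {
    if (k != "station") tab[[k]] <- as.integer(tab[[k]])
  }
  tab[order(tab[[keys[1L]]]), , drop = FALSE] -> tab
  rownames(tab) <- NULL
  tab
}

#' Build a station x day x hour count cube from call events
#'
#' @param events Validated call-event table.
#' @param calendar `cep_calendar` for the study year.
#' @param registry `station_registry`; the cube has one slice per
#'   registered station (alphabetical), including stations with no events.
#' @return 3-d integer array `[station, day_of_year, hour_slot]` with
#'   dimnames `abbr`, `1..365`, `0..23`.
#' @export
count_cube <- function(events, calendar, registry) {
  events <- validate_events(events, registry, calendar)
  doy <- calendar$day_of_year[match(events$date, calendar$date)]
  tab <- table(
    factor(events$station, levels = registry$abbr),
    factor(doy, levels = 1:365),
    factor(events$hour_slot, levels = 0:23)
  )
  cube <- array(as.integer(tab), dim = dim(tab),
                dimnames = list(station = registry$abbr,
                                day_of_year = as.character(1:365),
                                hour_slot = as.character(0:23)))
  cube
}

#' Hourly demand profile of a station or group of stations
#'
#' Rates are average non-time-critical operations per hour slot per day:
#' the annual count in each slot (summed over member stations) divided
#' by 365.
#'
#' @param cube Count cube from [count_cube()].
#' @param ids Station abbreviation(s) to pool.
#' @return An `hourly_profile`: numeric vector of 24 rates, names `0..23`,
#'   with attribute `ids`.
#' @export
hourly_profile <- function(cube, ids) {
  unknown <- setdiff(ids, dimnames(cube)$station)
  if (length(unknown) > 0L) stop("unknown station id(s): ",
                                 paste(unknown, collapse = ", "))
  sub <- cube[ids, , , drop = FALSE]
  rates <- apply(sub, 3, sum) / 365
  structure(as.numeric(rates), names = as.character(0:23), ids = ids,
            class = "hourly_profile")
}

#' Hourly profile from explicit per-slot rates
#'
#' @param rates 24 non-negative rates (operations per hour slot per day).
#' @param id Identifier for the station or group.
#' @return An `hourly_profile`.
#' @export
profile_from_rates <- function(rates, id = "profile") {
  if (length(rates) != 24L || any(rates < 0)) {
    stop("rates must be 24 non-negative values")
  }
  structure(as.numeric(rates), names = as.character(0:23), ids = id,
            class = "hourly_profile")
}

#' Flat hourly profile from an annual total
#'
#' Spreads an annual operation count uniformly over the 8760 hour slots of
#' the year; the average workload of such a profile with one paramedic on
#' duty equals `total / 8760 * 100` percent.
#'
#' @param total Annual operation count.
#' @param id Identifier.
#' @return An `hourly_profile` with 24 equal rates summing to `total / 365`.
#' @export
profile_from_total <- function(total, id = "profile") {
  profile_from_rates(rep(total / 365 / 24, 24L), id = id)
}
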