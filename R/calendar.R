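#' Load calendar definitions (breaks, holidays, events) from YAML
#'
#' @param source Path to a YAML file with a `year` and lists `breaks`,
#'   `holidays`, `events`. Break and event entries are ranges with `start`
#'   and `end` dates; holidays are single dates. Defaults to the packaged
#'   Hamburg 2019 definitions.
#' @return A list with elements `year`, `breaks`, `holidays`, `events`,
#'   dates as `Date`.
#' @export
load_calendar_definitions <- function(source = cep_fixture("calendar_hamburg_2019.yaml")) {
  raw <- yaml::read_yaml(source)
  as_range <- function(x) {
    data.frame(name = if (is.null(x$name)) NA_character_ else x$name,
               start = as.Date(x$start), end = as.Date(x$end),
               stringsAsFactors = FALSE)
  }
  list(
    year = as.integer(raw$year),
    breaks = do.call(rbind, lapply(raw$breaks, as_range)),
    holidays = as.Date(vapply(raw$holidays, as.character, "")),
    events = do.call(rbind, lapply(raw$events, as_range))
  )
}

#' Build the 365-day study calendar
#'
#' Expands break/holiday/event definitions into one row per day of a
#' non-leap year, with the week convention used throughout the analysis:
#' `week = min(ceiling(day_of_year / 7), 52)`, so weeks 1..51 hold 7 days
#' and week 52 absorbs the final 8 days (matching a 52-week average of
#' annual totals). Weekday is 1..7 with 1 = Monday.
#'
#' @param year Integer year; must be a 365-day (non-leap) year.
#' @param definitions Definitions as returned by
#'   [load_calendar_definitions()]; any subset of `breaks`, `holidays`,
#'   `events` may be omitted or NULL. Defaults to the packaged definitions
#'   when `year` is 2019, otherwise empty flags.
#' @return data.frame of class `cep_calendar` with columns `date`,
#'   `day_of_year`, `week`, `weekday`, `is_break`, `is_holiday`, `is_event`.
#' @export
build_calendar <- function(year, definitions = NULL) {
  year <- as.integer(year)
  start <- as.Date(sprintf("%d-01-01", year))
  end <- as.Date(sprintf("%d-12-31", year))
  dates <- seq(start, end, by = "day")
  if (length(dates) != 365L) {
    stop("year ", year, " is not a 365-day year; the analysis assumes a non-leap year")
  }
  if (is.null(definitions) && year == 2019L) {
    definitions <- load_calendar_definitions()
  }
  doy <- seq_len(365L)
  cal <- data.frame(
    date = dates,
    day_of_year = doy,
    week = as.integer(pmin(ceiling(doy / 7), 52L)),
    weekday = (as.integer(format(dates, "%u"))),
    is_break = FALSE, is_holiday = FALSE, is_event = FALSE
  )

  flag_ranges <- function(cal, ranges, col) {
    if (is.null(ranges) || nrow(ranges) == 0L) return(cal)
    for (i in seq_len(nrow(ranges))) {
      if (ranges$start[i] > ranges$end[i]) {
        stop("range start after end in ", col, " definition ", i)
      }
      if (ranges$start[i] < cal$date[1L] || ranges$end[i] > cal$date[365L]) {
        stop(col, " range ", i, " lies outside year ", unique(format(cal$date[1], "%Y")))
      }
      cal[[col]] <- cal[[col]] | (cal$date >= ranges$start[i] & cal$date <= ranges$end[i])
    }
    cal
  }
  cal <- flag_ranges(cal, definitions$breaks, "is_break")
  cal <- flag_ranges(cal, definitions$events, "is_event")
  if (!is.null(definitions$holidays) && length(definitions$holidays) > 0L) {
    hol <- as.Date(definitions$holidays)
    if (any(hol < start | hol > end)) {
      stop("holiday outside year ", year, ": ",
           paste(format(hol[hol < start | hol > end]), collapse = ", "))
    }
    cal$is_holiday <- cal$date %in% hol
  }
  class(cal) <- c("cep_calendar", "data.frame")
  cal
}
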