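#' Load a station registry from a CSV table
#'
#' Reads one row per rescue station with demography and annual counts of
#' non-time-critical operations, validates the internal consistency of the
#' counts and returns a `station_registry` object ordered alphabetically by
#' station name.
#'
#' @param source Path to a CSV file with columns `name`, `abbr`, `area`,
#'   `population`, `area_km2`, `density`, `ops_total`, `ops_with`,
#'   `ops_without`. Defaults to the packaged 17-station Hamburg 2019 fixture.
#' @return A data.frame of class `station_registry`, one row per station,
#'   sorted by name.
#' @details Validation enforces: unique 3-letter abbreviations, area one of
#'   East/South/West, non-negative counts, positive area size, and
#'   `ops_with + ops_without == ops_total` per row. Any violation is an
#'   error naming the offending station.
#' @examples
#' reg <- load_station_table()
#' sum(reg$ops_total)  # 48035 non-time-critical operations in 2019
#' @export
load_station_table <- function(source = cep_fixture("stations_2019.csv")) {
  req <- c("name", "abbr", "area", "population", "area_km2", "density",
           "ops_total", "ops_with", "ops_without")
  df <- utils::read.csv(source, stringsAsFactors = FALSE)
  missing <- setdiff(req, names(df))
  if (length(missing) > 0L) {
    stop("station table is missing column(s): ", paste(missing, collapse = ", "))
  }
  totals <- grepl("^total$", df$name, ignore.case = TRUE)
  if (any(totals)) {
    body <- df[!totals, , drop = FALSE]
    for (col in c("ops_total", "ops_with", "ops_without")) {
      if (sum(body[[col]]) != df[[col]][totals][1L]) {
        stop("totals row does not match the sum of station rows for ", col)
      }
    }
    df <- body
  }
  station_registry(df[req])
}

#' Construct and validate a station registry
#'
#' @param df data.frame with the registry columns (see [load_station_table()]).
#' @return data.frame of class `station_registry`, sorted by station name.
#' @export
station_registry <- function(df) {
  if (anyDuplicated(df$abbr)) {
    stop("duplicate station abbreviation: ",
         paste(unique(df$abbr[duplicated(df$abbr)]), collapse = ", "))
  }
  bad_area <- setdiff(unique(df$area), c("East", "South", "West"))
  if (length(bad_area) > 0L) {
    stop("unknown area: ", paste(bad_area, collapse = ", "))
  }
  counts <- c("population", "ops_total", "ops_with", "ops_without")
  for (col in counts) {
    if (any(df[[col]] < 0)) stop("negative ", col, " in row ",
                                 df$name[which(df[[col]] < 0)[1L]])
  }
  if (any(df$area_km2 <= 0)) {
    stop("non-positive area size in row ", df$name[which(df$area_km2 <= 0)[1L]])
  }
  off <- which(df$ops_with + df$ops_without != df$ops_total)
  if (length(off) > 0L) {
    stop("with + without transport does not equal total for station: ",
         paste(df$name[off], collapse = ", "))
  }
  df <- df[order(df$name), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("station_registry", "data.frame")
  df
}

#' Path to a packaged fixture file
#'
#' @param file File name under the package's `extdata` directory. With no
#'   argument, lists the available fixtures.
#' @return A file path (or a character vector of file names).
#' @export
cep_fixture <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "cepplanr")))
  }
  path <- system.file("extdata", file, package = "cepplanr")
  if (!nzchar(path)) stop("no packaged fixture named ", file)
  path
}

#' Weekday totals of non-time-critical operations (packaged table)
#'
#' @return data.frame with columns `weekday` (Monday..Sunday),
#'   `weekday_index` (1..7, 1 = Monday) and `total` annual operations.
#' @export
load_weekday_totals <- function() {
  utils::read.csv(cep_fixture("weekday_totals_2019.csv"), stringsAsFactors = FALSE)
}

#' Hourly operation rates for the Wandsbek station (packaged table)
#'
#' Average non-time-critical operations per hour slot and day
#' (annual slot count divided by 365) for the busiest station.
#'
#' @return data.frame with columns `hour_slot` (0..23) and `rate`.
#' @export
load_wandsbek_hourly <- function() {
  utils::read.csv(cep_fixture("wandsbek_hourly_2019.csv"), stringsAsFactors = FALSE)
}
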