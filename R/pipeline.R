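#' Configuration for a full analysis run
#'
#' @param mode Input mode: `"fixtures"` (packaged 2019 tables only),
#'   `"synthetic"` (generate a year of call events) or `"events"` (read an
#'   event CSV).
#' @param seed Master seed for every random stage.
#' @param output_dir Directory for report files.
#' @param events_file Event CSV path (mode `"events"` only): columns
#'   `station`, `date`, `hour_slot`, `transported`.
#' @param strategies Strategy ids to evaluate (default: the full catalogue).
#' @param seasonal Seasonal model settings: `spec` (a [seasonal_spec()]),
#'   `cv_initial`, `cv_horizon`, `cv_step`, `bootstrap`.
#' @return List of class `run_config`.
#' @export
run_config <- function(mode = c("fixtures", "synthetic", "events"),
                       seed = 1L,
                       output_dir = tempfile("cep_run_"),
                       events_file = NULL,
                       strategies = NULL,
                       seasonal = list()) {
  mode <- match.arg(mode)
  if (mode == "events" && is.null(events_file)) {
    stop("mode 'events' requires events_file")
  }
  defaults <- list(
    spec = seasonal_spec(effects = c("break", "holiday", "event")),
    cv_initial = 180L, cv_horizon = 14L, cv_step = 14L, bootstrap = 200L
  )
  seasonal <- utils::modifyList(defaults, seasonal)
  structure(list(mode = mode, seed = as.integer(seed),
                 output_dir = output_dir, events_file = events_file,
                 strategies = strategies, seasonal = seasonal),
            class = "run_config")
}

#' Run the full demand analysis
#'
#' Reproduces the complete 2019-style pipeline: registry statistics
#' (Kruskal-Wallis and Dunn post hoc tests on population density, Spearman
#' and OLS diagnostics on weekday totals), station clustering, and the
#' staffing-strategy comparison. In `"synthetic"` and `"events"` modes it
#' additionally builds the count cube, fits the additive seasonal model to
#' daily totals and runs rolling-origin cross-validation.
#'
#' @param config `run_config`.
#' @return Invisibly, a list of class `report_bundle` with elements `stats`,
#'   `clusters`, `strategies`, and (when events exist) `seasonal`, `cv`,
#'   plus a `manifest` of written files and their MD5 hashes. All files are
#'   written under `config$output_dir`.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  registry <- load_station_table()
  calendar <- build_calendar(2019L)

  groups <- split(registry$density, registry$area)
  weekday <- load_weekday_totals()
  wd_ols <- ols_with_durbin_watson(weekday$weekday_index, weekday$total)
  stats_out <- list(
    kw_density = unclass(kruskal_wallis(groups)),
    dunn_density = as.data.frame(dunn_bonferroni(groups)),
    spearman_weekday = unclass(spearman(weekday$weekday_index, weekday$total)),
    spearman_total_vs_no_transport =
      unclass(spearman(registry$ops_total, registry$ops_without)),
    ols_weekday = wd_ols[c("slope", "intercept", "r_squared", "adj_r_squared",
                           "p_slope", "dw_stat", "dw_p")]
  )

  clus <- cluster_stations(registry, k = 5L)

  events <- switch(config$mode,
    fixtures = NULL,
    synthetic = {
      cfg <- generator_config(registry, seed = config$seed)
      generate_year(registry, calendar, cfg)
    },
    events = validate_events(
      utils::read.csv(config$events_file, stringsAsFactors = FALSE),
      registry, calendar)
  )

  seasonal_fit <- NULL; cv <- NULL; profiles <- NULL
  if (!is.null(events)) {
    cube <- count_cube(events, calendar, registry)
    profiles <- lapply(stats::setNames(registry$abbr, registry$abbr),
                       function(a) hourly_profile(cube, a))
    daily <- aggregate_events(events, "day_of_year", calendar)
    s <- config$seasonal
    seasonal_fit <- fit_seasonal(daily$count, s$spec, time = daily$day_of_year,
                                 calendar = calendar, bootstrap = s$bootstrap,
                                 seed = config$seed)
    cv <- rolling_cv(daily$count, s$spec, initial_train = s$cv_initial,
                     horizon = s$cv_horizon, step = s$cv_step,
                     time = daily$day_of_year, calendar = calendar)
  }

  strategies <- cep_strategies()
  if (!is.null(config$strategies)) strategies <- strategies[config$strategies]
  comparison <- evaluate_strategies(registry, profiles, strategies)

  bundle <- structure(list(
    stats = stats_out,
    clusters = clus$labels,
    strategies = comparison,
    seasonal = if (!is.null(seasonal_fit)) seasonal_fit$components,
    cv = if (!is.null(cv)) cv$windows,
    cv_mean_rmse = if (!is.null(cv)) cv$mean_rmse,
    config = config
  ), class = "report_bundle")
  bundle$manifest <- write_report(bundle, config$output_dir)
  invisible(bundle)
}

#' Write a report bundle to disk
#'
#' @param bundle `report_bundle` from [run_full_analysis()].
#' @param dir Output directory.
#' @param format `"csv"`, `"json"` or both (default).
#' @return data.frame manifest (`file`, `md5`), also written as
#'   `manifest.csv`.
#' @export
write_report <- function(bundle, dir, format = c("csv", "json")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  if ("json" %in% format) {
    f <- file.path(dir, "stats.json")
    jsonlite::write_json(bundle$stats, f, auto_unbox = TRUE, digits = NA)
    files <- c(files, f)
  }
  if ("csv" %in% format) {
    f <- file.path(dir, "clusters.csv")
    utils::write.csv(data.frame(station = names(bundle$clusters),
                                cluster = as.integer(bundle$clusters)),
                     f, row.names = FALSE)
    files <- c(files, f)
    f <- file.path(dir, "strategy_comparison.csv")
    utils::write.csv(bundle$strategies, f, row.names = FALSE)
    files <- c(files, f)
    if (!is.null(bundle$seasonal)) {
      f <- file.path(dir, "seasonal_components.csv")
      utils::write.csv(bundle$seasonal, f, row.names = FALSE)
      files <- c(files, f)
    }
    if (!is.null(bundle$cv)) {
      f <- file.path(dir, "cv_windows.csv")
      utils::write.csv(bundle$cv, f, row.names = FALSE)
      files <- c(files, f)
    }
  }
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  manifest
}
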