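#' Feasibility thresholds for CEP workload
#'
#' @param realistic_limit Sustainable utilisation limit in percent
#'   (default 85).
#' @param hard_limit Hard capacity ceiling in percent (default 100).
#' @return List of class `feasibility_thresholds`.
#' @export
feasibility_thresholds <- function(realistic_limit = 85, hard_limit = 100) {
  if (realistic_limit >= hard_limit) stop("realistic limit must be below the hard limit")
  structure(list(realistic_limit = realistic_limit, hard_limit = hard_limit),
            class = "feasibility_thresholds")
}

#' Per-slot CEP counts for a shift plan
#'
#' A 24-h paramedic contributes one unit of capacity to every hour slot; an
#' optional second 12-h paramedic covers a duty window (default
#' 07:00-19:00); optional extension hours prolong the second shift past its
#' window end.
#'
#' @param n_24h Number of around-the-clock CEPs (default 1).
#' @param second_window `NULL` or `c(start_hour, end_hour)` half-open window
#'   of the second CEP, e.g. `c(7, 19)` for 07:00-18:59.
#' @param extension_hours Extra whole hours appended after the second
#'   window's end (default 0).
#' @return Integer vector of length 24 (slots 0..23) of CEPs on duty.
#' @export
shift_plan <- function(n_24h = 1L, second_window = NULL, extension_hours = 0L) {
  plan <- rep(as.integer(n_24h), 24L)
  if (!is.null(second_window)) {
    if (length(second_window) != 2L || second_window[1L] >= second_window[2L] ||
        second_window[1L] < 0 || second_window[2L] > 24) {
      stop("second_window must be c(start, end) with 0 <= start < end <= 24")
    }
    slots <- seq(second_window[1L], second_window[2L] + extension_hours - 1L)
    slots <- slots[slots <= 23L]
    plan[slots + 1L] <- plan[slots + 1L] + 1L
  } else if (extension_hours > 0L) {
    stop("extension_hours requires a second_window")
  }
  plan
}

#' Workload of one hour slot
#'
#' Demand minutes are the operation rate times the mean operation time;
#' supply minutes are the paramedics on duty times 60. Workload is their
#' ratio in percent. A slot with demand but nobody on duty is marked
#' uncovered (infinite workload) rather than raising a division error.
#'
#' @param rate Operations per hour slot per day (>= 0).
#' @param n_cep Paramedics on duty in the slot (integer >= 0).
#' @param operation_time Mean minutes per operation (default 60).
#' @return One-row data.frame: `rate`, `operation_time`, `demand`, `n_cep`,
#'   `supply`, `workload`, `over85`, `over100`, `uncovered`.
#' @export
slot_workload <- function(rate, n_cep, operation_time = 60) {
  if (rate < 0) stop("rate must be non-negative")
  if (operation_time <= 0) stop("operation time must be positive")
  demand <- rate * operation_time
  supply <- n_cep * 60
  workload <- if (supply == 0) {
    if (demand > 0) Inf else 0
  } else {
    demand / supply * 100
  }
  data.frame(rate = rate, operation_time = operation_time, demand = demand,
             n_cep = n_cep, supply = supply, workload = workload,
             over85 = workload > 85, over100 = workload > 100,
             uncovered = supply == 0 & demand > 0)
}

#' Hourly workload table for a station
#'
#' One row per hour slot plus a summary average (the mean of the 24 per-slot
#' workloads, which for a constant one-CEP plan equals
#' `annual_total / 8760 * 100` percent).
#'
#' @param profile `hourly_profile` of the station.
#' @param plan 24 per-slot CEP counts from [shift_plan()] (default: one
#'   24-h CEP).
#' @param thresholds `feasibility_thresholds`.
#' @param operation_time Mean minutes per operation (default 60).
#' @return data.frame of class `workload_table`, 24 rows with `hour_slot`
#'   and the [slot_workload()] columns; attributes `average` (mean
#'   workload, percent) and `feasibility` (see [classify_feasibility()]).
#' @export
station_workload_table <- function(profile, plan = shift_plan(),
                                   thresholds = feasibility_thresholds(),
                                   operation_time = 60) {
  stopifnot(length(profile) == 24L, length(plan) == 24L)
  rows <- do.call(rbind, lapply(0:23, function(h) {
    slot_workload(profile[[h + 1L]], plan[[h + 1L]], operation_time)
  }))
  tab <- cbind(hour_slot = 0:23, rows)
  tab$over85 <- tab$workload > thresholds$realistic_limit
  tab$over100 <- tab$workload > thresholds$hard_limit
  class(tab) <- c("workload_table", "data.frame")
  attr(tab, "average") <- mean(tab$workload)
  attr(tab, "feasibility") <- classify_feasibility(tab, thresholds)
  tab
}

#' Pooled workload table for a station group
#'
#' Member demand rates are summed per slot; the per-CEP workload in each
#' slot divides the pooled demand by the paramedics on duty there (shared
#' 24-h CEP, optionally a shared second 12-h CEP).
#'
#' @param profiles List of member `hourly_profile`s (or a single profile).
#' @param plan 24 per-slot CEP counts.
#' @param thresholds `feasibility_thresholds`.
#' @param operation_time Mean minutes per operation.
#' @return `workload_table` as in [station_workload_table()].
#' @export
group_workload_table <- function(profiles, plan = shift_plan(),
                                 thresholds = feasibility_thresholds(),
                                 operation_time = 60) {
  if (inherits(profiles, "hourly_profile")) profiles <- list(profiles)
  if (length(profiles) < 1L) stop("a group needs at least one member profile")
  combined <- Reduce(`+`, lapply(profiles, as.numeric))
  station_workload_table(profile_from_rates(combined, id = "group"),
                         plan = plan, thresholds = thresholds,
                         operation_time = operation_time)
}

#' Count threshold exceedances in a workload table
#'
#' @param table `workload_table`.
#' @param thresholds `feasibility_thresholds`.
#' @return List: `slots_over85`, `slots_over100`, `sufficient` (TRUE iff no
#'   slot exceeds the realistic limit).
#' @export
classify_feasibility <- function(table, thresholds = feasibility_thresholds()) {
  over85 <- sum(table$workload > thresholds$realistic_limit)
  over100 <- sum(table$workload > thresholds$hard_limit)
  list(slots_over85 = over85, slots_over100 = over100,
       sufficient = over85 == 0L)
}

#' Define a CEP staffing strategy
#'
#' A strategy is a set of staffed units; each unit covers one station or a
#' pooled group of stations with one or more 24-h CEPs and optionally a
#' second 12-h CEP (with optional extension hours).
#'
#' @param id Strategy label (e.g. `"3b"`).
#' @param units List of units; each unit is a list with `stations`
#'   (character), and optionally `n_24h` (default 1), `second_window`
#'   (default NULL) and `extension_hours` (default 0).
#' @return List of class `strategy_spec`.
#' @export
strategy_spec <- function(id, units) {
  all_st <- unlist(lapply(units, `[[`, "stations"))
  if (anyDuplicated(all_st)) {
    stop("station assigned to more than one unit: ",
         paste(unique(all_st[duplicated(all_st)]), collapse = ", "))
  }
  units <- lapply(units, function(u) {
    u$n_24h <- if (is.null(u$n_24h)) 1L else as.integer(u$n_24h)
    u$extension_hours <- if (is.null(u$extension_hours)) 0L else as.integer(u$extension_hours)
    u$plan <- shift_plan(u$n_24h, u$second_window, u$extension_hours)
    u
  })
  structure(list(id = id, units = units), class = "strategy_spec")
}

#' Staff-hour and coverage accounting for a strategy
#'
#' Daily staff hours sum each unit's scheduled hours (24 per 24-h CEP, the
#' window length per second CEP, plus extension hours); yearly hours are
#' daily hours times 365. Coverage is the share of the 17 stations staffed.
#'
#' @param strategy `strategy_spec`.
#' @param n_stations Total station count for the coverage rate (default 17).
#' @return List of class `staffing_summary`: `id`, `n_24h_ceps`,
#'   `n_12h_ceps`, `staff_hours_per_day`, `staff_hours_per_year`,
#'   `stations_covered`, `area_coverage_rate`.
#' @export
staff_hours <- function(strategy, n_stations = 17L) {
  per_day <- 0L
  n24 <- 0L
  n12 <- 0L
  for (u in strategy$units) {
    hours <- 24L * u$n_24h + u$extension_hours
    if (!is.null(u$second_window)) {
      hours <- hours + as.integer(u$second_window[2L] - u$second_window[1L])
      n12 <- n12 + 1L
    }
    per_day <- per_day + hours
    n24 <- n24 + u$n_24h
  }
  covered <- length(unique(unlist(lapply(strategy$units, `[[`, "stations"))))
  structure(list(
    id = strategy$id,
    n_24h_ceps = n24,
    n_12h_ceps = n12,
    staff_hours_per_day = per_day,
    staff_hours_per_year = per_day * 365L,
    stations_covered = covered,
    area_coverage_rate = covered / n_stations * 100
  ), class = "staffing_summary")
}

#' Built-in catalogue of CEP staffing strategies
#'
#' The investigated schemes: #1[a] one 24-h CEP per station; #1[b] the six
#' higher-demand stations only; #1[c] the four high-demand stations only;
#' #2[a-c] as #1[a-c] plus a second 12-h CEP at the four high-demand
#' stations; #3[a] ten pooled groups sharing one 24-h CEP each; #3[b] as
#' #3[a] plus second 12-h CEPs for the eight higher-demand groups; and
#' "3b_extended", which lengthens the second shift in groups 3, 4, 5 and 7
#' by 1, 1, 3 and 5 hours.
#'
#' @param second_window Duty window of second CEPs, default `c(7, 19)`
#'   (07:00-19:00).
#' @return Named list of `strategy_spec`s, including the group definitions
#'   as attribute `groups`.
#' @export
cep_strategies <- function(second_window = c(7, 19)) {
  high4 <- c("Bar", "Sas", "Ste", "Wan")
  higher6 <- c("Alo", "Bar", "Beg", "Sas", "Ste", "Wan")
  all17 <- c("Als", "Alo", "Bar", "Beg", "Bet", "Bil", "Fin", "Har", "Inn",
             "Osd", "Rot", "Sas", "Ste", "Sue", "Ved", "Wan", "Wil")
  groups <- list(
    g1 = c("Sue", "Fin"), g2 = c("Har", "Ved", "Wil"), g3 = c("Bil", "Beg"),
    g4 = c("Inn", "Bet"), g5 = c("Alo", "Osd"), g6 = "Rot",
    g7 = c("Ste", "Als"), g8 = "Bar", g9 = "Sas", g10 = "Wan"
  )
  second_groups <- paste0("g", c(2, 3, 4, 5, 7, 8, 9, 10))
  extensions <- c(g3 = 1L, g4 = 1L, g5 = 3L, g7 = 5L)

  solo <- function(stations, second = character(0), ext = integer(0)) {
    lapply(stations, function(s) {
      u <- list(stations = s)
      if (s %in% second) u$second_window <- second_window
      u
    })
  }
  grouped <- function(second = character(0), ext = integer(0)) {
    lapply(names(groups), function(gn) {
      u <- list(stations = groups[[gn]])
      if (gn %in% second) {
        u$second_window <- second_window
        if (gn %in% names(ext)) u$extension_hours <- ext[[gn]]
      }
      u
    })
  }

  strategies <- list(
    `1a` = strategy_spec("1a", solo(all17)),
    `1b` = strategy_spec("1b", solo(higher6)),
    `1c` = strategy_spec("1c", solo(high4)),
    `2a` = strategy_spec("2a", solo(all17, second = high4)),
    `2b` = strategy_spec("2b", solo(higher6, second = high4)),
    `2c` = strategy_spec("2c", solo(high4, second = high4)),
    `3a` = strategy_spec("3a", grouped()),
    `3b` = strategy_spec("3b", grouped(second = second_groups)),
    `3b_extended` = strategy_spec("3b_extended",
                                  grouped(second = second_groups, ext = extensions))
  )
  attr(strategies, "groups") <- groups
  strategies
}

#' Evaluate staffing strategies against station demand profiles
#'
#' Computes staff-hour accounting for every strategy and, when profiles are
#' supplied, the per-unit workload tables and total exceedance counts.
#'
#' @param registry `station_registry`.
#' @param profiles Named list of `hourly_profile`s per station abbreviation,
#'   or `NULL` to derive flat profiles from the registry's annual totals.
#' @param strategies Named list of `strategy_spec`s (default: the built-in
#'   catalogue).
#' @param thresholds `feasibility_thresholds`.
#' @param operation_time Mean minutes per operation.
#' @return data.frame, one row per strategy: staffing summary fields plus
#'   `slots_over85`, `slots_over100` summed over units and the worst unit's
#'   average workload.
#' @export
evaluate_strategies <- function(registry, profiles = NULL,
                                strategies = cep_strategies(),
                                thresholds = feasibility_thresholds(),
                                operation_time = 60) {
  if (is.null(profiles)) {
    profiles <- lapply(stats::setNames(registry$ops_total, registry$abbr),
                       profile_from_total)
  }
  rows <- lapply(strategies, function(strat) {
    summ <- staff_hours(strat, n_stations = nrow(registry))
    over85 <- 0L; over100 <- 0L; worst <- 0
    for (u in strat$units) {
      missing <- setdiff(u$stations, names(profiles))
      if (length(missing) > 0L) {
        stop("no profile for station(s): ", paste(missing, collapse = ", "))
      }
      tab <- group_workload_table(profiles[u$stations], plan = u$plan,
                                  thresholds = thresholds,
                                  operation_time = operation_time)
      fe <- attr(tab, "feasibility")
      over85 <- over85 + fe$slots_over85
      over100 <- over100 + fe$slots_over100
      worst <- max(worst, attr(tab, "average"))
    }
    data.frame(id = summ$id, n_24h_ceps = summ$n_24h_ceps,
               n_12h_ceps = summ$n_12h_ceps,
               staff_hours_per_day = summ$staff_hours_per_day,
               staff_hours_per_year = summ$staff_hours_per_year,
               stations_covered = summ$stations_covered,
               area_coverage_rate = summ$area_coverage_rate,
               slots_over85 = over85, slots_over100 = over100,
               worst_unit_avg_workload = worst,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
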