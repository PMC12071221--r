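test_that("slot workload follows the demand/supply arithmetic", {
  w <- slot_workload(0.8877, 1, 60)
  expect_equal(round(w$workload, 2), 88.77)
  expect_equal(w$demand, 0.8877 * 60)
  expect_equal(slot_workload(0, 1, 60)$workload, 0)
  expect_equal(slot_workload(1, 2, 60)$workload, 50)
  # nobody on duty with demand: uncovered marker, not an error
  unc <- slot_workload(0.5, 0, 60)
  expect_true(unc$uncovered)
  expect_identical(unc$workload, Inf)
  expect_false(slot_workload(0, 0, 60)$uncovered)
  expect_error(slot_workload(-1, 1), "non-negative")
  expect_error(slot_workload(1, 1, 0), "positive")
})

test_that("the Wandsbek hourly table reproduces the printed workload profile", {
  wan <- profile_from_rates(load_wandsbek_hourly()$rate, "Wan")
  tab <- station_workload_table(wan)
  expect_equal(round(attr(tab, "average"), 2), 55.70)
  expect_equal(round(tab$workload[tab$hour_slot == 10], 2), 88.77)
  fe <- attr(tab, "feasibility")
  expect_identical(fe$slots_over85, 1L)
  expect_identical(fe$slots_over100, 0L)
  expect_false(fe$sufficient)
  # every hourly workload equals rate * 100 with one paramedic and 60 min
  expect_equal(tab$workload, as.numeric(wan) * 100)
})

test_that("station averages with one 24-h paramedic equal total/8760", {
  reg <- hamburg_registry()
  avg_of <- function(abbr) {
    p <- profile_from_total(reg$ops_total[reg$abbr == abbr], abbr)
    attr(station_workload_table(p), "average")
  }
  expect_equal(round(avg_of("Fin"), 2), 4.37)
  expect_equal(round(avg_of("Ved"), 2), 12.13)
  expect_equal(round(avg_of("Wil"), 2), 15.47)
  expect_equal(round(avg_of("Alo"), 2), 44.26)
})

test_that("group workload is additive and scales inversely with staffing", {
  set.seed(8)
  p1 <- profile_from_rates(runif(24, 0, 0.5), "A")
  p2 <- profile_from_rates(runif(24, 0, 0.5), "B")
  g <- group_workload_table(list(p1, p2))
  expect_equal(attr(g, "average"),
               attr(station_workload_table(p1), "average") +
                 attr(station_workload_table(p2), "average"), tolerance = 1e-12)
  # single-member group identical to the station table
  expect_equal(group_workload_table(list(p1))$workload,
               station_workload_table(p1)$workload)
  # doubling every slot's staffing halves every workload
  half <- group_workload_table(list(p1, p2), plan = shift_plan(2))
  expect_equal(half$workload, g$workload / 2)
})

test_that("a second 07:00-19:00 paramedic yields the printed per-CEP average", {
  wan <- profile_from_rates(load_wandsbek_hourly()$rate, "Wan")
  tab <- group_workload_table(wan, plan = shift_plan(1, second_window = c(7, 19)))
  expect_equal(round(attr(tab, "average"), 2), 37.89)
  # pooled Altona + Osdorf on one shared paramedic
  reg <- hamburg_registry()
  alo <- profile_from_total(reg$ops_total[reg$abbr == "Alo"], "Alo")
  osd <- profile_from_total(reg$ops_total[reg$abbr == "Osd"], "Osd")
  g5 <- group_workload_table(list(alo, osd))
  expect_lt(abs(attr(g5, "average") - 78.29), 0.05)
})

test_that("shift plans place paramedics in the right slots", {
  expect_identical(shift_plan(1), rep(1L, 24L))
  plan <- shift_plan(1, c(7, 19))
  expect_identical(plan[8:19], rep(2L, 12L))   # slots 7..18
  expect_identical(plan[c(1:7, 20:24)], rep(1L, 12L))
  ext <- shift_plan(1, c(7, 19), extension_hours = 3L)
  expect_identical(ext[8:22], rep(2L, 15L))    # slots 7..21
  expect_error(shift_plan(1, c(19, 7)), "start < end")
  expect_error(shift_plan(1, extension_hours = 2L), "requires")
})

test_that("staff-hour accounting matches the strategy catalogue", {
  reg <- hamburg_registry()
  res <- evaluate_strategies(reg)
  hours <- setNames(res$staff_hours_per_year, res$id)
  expect_identical(hours[["1a"]], 148920L)
  expect_identical(hours[["2a"]], 166440L)
  expect_identical(hours[["2b"]], 70080L)
  expect_identical(hours[["2c"]], 52560L)
  expect_identical(hours[["3a"]], 87600L)
  expect_identical(hours[["3b"]], 122640L)
  expect_identical(hours[["3b_extended"]], 126290L)
  expect_true(all(res$staff_hours_per_year %% 365L == 0L))
  expect_equal(res$area_coverage_rate[res$id == "1a"], 100)
  expect_equal(res$area_coverage_rate[res$id == "3a"], 100)
  expect_equal(round(res$area_coverage_rate[res$id == "1c"], 1), 23.5)
})

test_that("staff hours are linear in disjoint units and guard double assignment", {
  s1 <- strategy_spec("one", list(list(stations = "A")))
  s2 <- strategy_spec("two", list(list(stations = "A"),
                                  list(stations = "B", second_window = c(7, 19))))
  h1 <- staff_hours(s1)
  h2 <- staff_hours(s2)
  expect_identical(h2$staff_hours_per_year - h1$staff_hours_per_year,
                   (24L + 12L) * 365L)
  expect_identical(staff_hours(strategy_spec("none", list()))$staff_hours_per_year, 0L)
  expect_error(strategy_spec("dup", list(list(stations = "A"),
                                         list(stations = c("A", "B")))),
               "more than one")
})

test_that("feasibility classification counts threshold exceedances", {
  zero <- station_workload_table(profile_from_rates(rep(0, 24)))
  expect_true(attr(zero, "feasibility")$sufficient)
  expect_true(all(zero$workload == 0))

  hot <- station_workload_table(profile_from_rates(c(rep(0.5, 22), 0.9, 1.2)))
  fe <- attr(hot, "feasibility")
  expect_identical(fe$slots_over85, 2L)
  expect_identical(fe$slots_over100, 1L)
  expect_false(fe$sufficient)
})
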