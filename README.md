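# cepplanr

Demand analysis and staffing strategies for **community emergency
paramedics** (CEPs) — single advanced paramedics in small vehicles who
handle non-time-critical ambulance calls, the large share of dispatches
that need neither special rights of way nor, in many cases, hospital
transport.

The package answers the planning question behind a CEP roll-out for a city
with 17 major rescue stations in three operational areas (East, South,
West): *where* is non-time-critical demand concentrated, *when* does it
peak, and *how many staff hours* do alternative CEP shift schemes cost at a
sustainable utilisation?

## What it provides

* **Station registry and calendar** — the 2019 registry of the 17 Hamburg
  stations (demography plus annual operation counts with/without
  transport), weekday totals, the hourly profile of the busiest station and
  a reconstructed 2019 Hamburg calendar (school breaks, legal holidays,
  public events), all as plain-text fixtures; aggregation of call events
  into station × day × hour count cubes.
* **Rank-based statistics** — tie-corrected Kruskal–Wallis, Dunn–Bonferroni
  post hoc comparisons, Spearman correlation, and OLS diagnostics with the
  Durbin–Watson test.
* **Hierarchical clustering** of stations (average linkage, Euclidean
  distance) on annual demand volume.
* **Additive seasonal demand model** — piecewise-linear trend with
  changepoints, Fourier seasonal blocks per cycle (daily, weekly, monthly,
  yearly), and break/holiday/event regressors:

  `y(t) = g(t) + s(t) + h(t) + e(t)`,  `s(t) = Σ_k α_k cos(2πkt/P) + β_k sin(2πkt/P)`

  fitted by ridge-penalized least squares with parametric-bootstrap
  intervals, and validated by rolling-origin cross-validation (RMSE over
  sliding train/forecast windows).
* **Synthetic call-event generator** — seeded per-station Poisson counts
  with diurnal shape, weekly/yearly modulation and calendar uplifts,
  calibrated to the published annual totals, plus an area-multiplier
  scenario (East +19%, South +22%, West +14%).
* **Workload and staffing evaluator** — hourly workload = rate × operation
  time / (CEPs on duty × 60) as a percentage, 85%/100% feasibility
  thresholds, pooled station groups, and staff-hour accounting for the
  full catalogue of 24-h/12-h staffing strategies.

## Worked example

```r
library(cepplanr)

registry <- load_station_table()
sum(registry$ops_total)
#> [1] 48035            # non-time-critical operations, 2019

# Do the three areas differ in population density?
kw <- kruskal_wallis(split(registry$density, registry$area))
round(kw$p, 3)
#> [1] 0.023
dunn <- dunn_bonferroni(split(registry$density, registry$area))
round(dunn$p_adj[dunn$group_a == "South" & dunn$group_b == "West"], 3)
#> [1] 0.018            # South and West differ after Bonferroni adjustment

# Hourly workload of the busiest station with one 24-h CEP
wan <- profile_from_rates(load_wandsbek_hourly()$rate, "Wan")
tab <- station_workload_table(wan)
round(attr(tab, "average"), 2)
#> [1] 55.7             # average utilisation over the day (percent)
round(tab$workload[tab$hour_slot == 10], 2)
#> [1] 88.77            # 10:00-10:59 is the only slot above the 85% limit

# Adding a second 12-h CEP (07:00-19:00) relieves the peak
round(attr(group_workload_table(wan, plan = shift_plan(1, c(7, 19))), "average"), 2)
#> [1] 37.89

# Staff-hour price tags of the staffing strategies
evaluate_strategies(registry)[, c("id", "staff_hours_per_year")]
#>             id staff_hours_per_year
#> 1           1a               148920
#> 2           1b                52560
#> 3           1c                35040
#> 4           2a               166440
#> 5           2b                70080
#> 6           2c                52560
#> 7           3a                87600
#> 8           3b               122640
#> 9  3b_extended               126290
```

A staffing scheme is *sufficient* for a unit when no hour slot exceeds the
85% realistic utilisation limit; slots above 100% mark uncovered demand.
Strategy `3a` (ten pooled groups sharing one 24-h CEP each) covers all 17
stations at 59% of the staff hours of one-CEP-per-station (`1a`); `3b` adds
second 12-h shifts to the eight busier groups.

The complete pipeline — statistics, clustering, a synthetic demand year,
the seasonal fit with cross-validation, and the strategy comparison — runs
as one call and writes CSV/JSON reports plus a hash manifest:

```r
bundle <- run_full_analysis(run_config("synthetic", seed = 1L,
                                       output_dir = "cep-report"))
```

See the vignette `vignettes/cep-demand-planning.Rmd` for the model details,
defaults and design decisions.

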