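---
title: "Modelling non-time-critical ambulance demand and CEP staffing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling non-time-critical ambulance demand and CEP staffing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cepplanr)
```

## The planning problem

A community emergency paramedic (CEP) is a single advanced paramedic in a
small vehicle who handles *non-time-critical* ambulance calls — dispatches
triaged as not requiring special rights of way, a large share of which end
without hospital transport. Whether CEP shifts are worth staffing at a rescue
station depends on how the demand for such calls is distributed over
stations, hours of the day, weekdays and the calendar year.

`cepplanr` implements that analysis end to end for a city with 17 major
rescue stations grouped into three operational areas (East, South, West):

1. **Demand pattern statistics** — rank-based comparisons between areas and
   time units.
2. **Station clustering** — grouping stations by annual demand volume.
3. **An additive seasonal demand model** — piecewise-linear trend, Fourier
   seasonal blocks and calendar-effect regressors, validated by
   rolling-origin cross-validation.
4. **Workload and staffing evaluation** — hourly utilisation tables and
   staff-hour accounting for 24-h/12-h CEP shift strategies, including
   pooled station groups.
5. **A synthetic call-event generator** — so that every stage is testable
   without access to dispatch-system records.

The package ships the published 2019 registry of the 17 Hamburg stations
(populations, area sizes, densities, annual operation counts with and
without transport), the weekday totals, the hourly demand profile of the
busiest station (Wandsbek) and a reconstructed 2019 Hamburg calendar as
plain-text fixtures.

## Conventions for the study year

All per-day arithmetic uses a fixed **365-day, non-leap year**. Weeks follow
the convention `week = min(ceiling(day_of_year / 7), 52)`: weeks 1–51 hold
exactly seven days and week 52 absorbs the final eight, so the weekly mean
of an annual total is `total / 52` (e.g. `48035 / 52 = 923.75`). ISO weeks
were rejected because they produce 53 partial weeks and break that identity.
Hour slots are half-open clock hours `[h:00, h+1:00)`, indexed 0–23.
Weekdays are 1–7 with Monday = 1. Station iteration order is alphabetical by
name everywhere, which makes every downstream tie-break deterministic.

The calendar fixture enumerates five school-break ranges (ski, Pentecost,
summer, autumn, Christmas), the ten legal holidays of Hamburg and the major
public events (the three DOM fairs, Harbour Birthday, Harley Days,
Schlagermove, Christopher Street Day, and the Advent market season). The
sources enumerate the *categories*; the concrete 2019 date ranges in
`calendar_hamburg_2019.yaml` are a reconstruction from the public Hamburg
calendar, and a day may carry several flags at once.

## Rank-based statistics

Normality cannot be assumed for 17 station-level values, so group
comparisons are rank-based:

* `kruskal_wallis()` uses mid-ranks with the tie-corrected H statistic and
  an upper-tail chi-square p-value (`df = groups - 1`).
* `dunn_bonferroni()` computes pairwise `z = (R_i - R_j) / sqrt(V (1/n_i +
  1/n_j))` with tie-corrected `V`, and multiplies two-sided normal
  p-values by the number of pairs (per-family Bonferroni; with three areas
  the factor is 3).
* `spearman()` correlates mid-ranks and uses the t approximation
  `t = rho sqrt((n-2)/(1-rho^2))` with `n - 2` degrees of freedom. For n of
  7 or 8 an exhaustive permutation oracle in the test suite checks the
  approximation.
* `ols_with_durbin_watson()` reports the usual least-squares diagnostics
  plus the Durbin–Watson statistic. Its p-value comes from the exact
  small-sample null algorithm in the `lmtest` package rather than a
  simulation: the exact distribution is available, deterministic and
  strictly better calibrated than a resampled null.

The chi-square approximation to the Kruskal–Wallis null is *coarse* below
about eight observations: for two groups of two the exact permutation
p-value of the most extreme split is 1/3 while the chi-square tail gives
0.12. The tests therefore treat exhaustive enumeration as the truth at those
sizes and check the approximation only where it is known to track the exact
null (n = 8 tail cases agree within 0.02).

## Station clustering

`cluster_stations()` applies agglomerative average-linkage (UPGMA)
clustering with Euclidean distance. The published protocol does not state
the feature vector; the package default — the 1-D annual total of
non-time-critical operations, unscaled — is a documented reconstruction that
reproduces the published five-cluster partition exactly: the isolated
low-demand station (Finkenwerder, 383 operations), the Veddel/Wilhelmsburg
pair, the Altona/Bergedorf pair, the four high-demand stations (≥ 4494) and
the remaining eight mid-demand stations. A 2-D variant adding the
without/with-transport ratio is available via `features = c("total",
"ratio")`.

One published statement is *not* reproducible under this (or any) feature
convention we examined: that a four-cluster cut would merge Altona/Bergedorf
into the eight-station cluster. Average-linkage arithmetic on the annual
totals necessarily merges Finkenwerder into the Veddel/Wilhelmsburg pair
first (mean inter-cluster distance 826 versus 1090.5 to the nearest
alternative), so the package's k = 4 cut differs from that statement and the
corresponding check is expected to disagree.

## The additive seasonal demand model

Daily (or hourly) counts are modelled as

$$y(t) = g(t) + s(t) + h(t) + \varepsilon_t,$$

with a piecewise-linear trend $g$, Fourier seasonal blocks
$s(t) = \sum_{k=1}^{K} \alpha_k \cos\frac{2\pi k t}{P} + \beta_k
\sin\frac{2\pi k t}{P}$ per period $P$, and 0/1 calendar-effect regressors
$h$ for break, holiday and event days.

**Estimation.** Coefficients are obtained by ridge-penalized least squares —
the maximum-a-posteriori analogue of a Bayesian linear fit with Gaussian
priors. Full posterior sampling (Hamiltonian Monte Carlo) is deliberately
not used: at this problem size the penalized fit is exact, deterministic,
and orders of magnitude cheaper, and the intervals below play the same
"excludes zero" role as posterior credible intervals. The intercept and the
base slope are unpenalized; Fourier and effect coefficients carry a small
penalty (`lambda_seasonal = 0.1`, negligible against the ~180 observations
per harmonic in a year of daily data, so genuine amplitudes are essentially
unshrunk); changepoint slope deltas carry a strong penalty
(`lambda_changepoint = 10`) so the trend cannot chase seasonality.

**Changepoints.** Twelve candidates, evenly spaced over the first 80% of
the training span. The count and placement are the package's choice; the
strong shrinkage makes results insensitive to the exact grid.

**Defaults.** Harmonic orders K = 3 (daily cycle on hourly data, P = 24),
2 (weekly, P = 7), 2 (monthly, P = 30.5) and 6 (yearly, P = 365.25) — the
smallest orders that can represent the observed single-peaked diurnal curve
and the multi-bump annual curve. The likelihood is Gaussian, not Poisson:
city-scale daily counts are large (≈ 130/day) and the additive
decomposition is the object of interest.

**Intervals and significance.** A seeded parametric bootstrap (default 500
replicates) re-draws Gaussian noise around the fitted curve and refits.
A component is flagged *significant* when any of its coefficients'
Bonferroni-corrected bootstrap intervals excludes zero (correction within
the component, i.e. level $0.05/2K$ per coefficient). This is a ~5%-level
test per component, so on pure noise a null block is still flagged about one
time in twenty; the test suite asserts exactly that calibration (power 1.0
for an injected yearly cycle at signal-to-noise 3, false-positive rate well
below 25% over repeated realizations) rather than pretending single
realizations are deterministic.

**Cross-validation.** `rolling_cv()` trains on data up to a cutoff,
forecasts the next `horizon` days, scores the RMSE, slides the cutoff by
`step` and repeats; chronology is enforced structurally. Comparing mean
RMSE with and without a block gives the predictive counterpart of the
interval criterion.

## The synthetic call-event generator

Real dispatch records are not redistributable, so `generate_year()` emulates
them. For station $s$, day $d$, hour slot $h$:

$$N_{sdh} \sim \text{Poisson}\big(b_s \cdot \text{shape}_h \cdot
w(\text{weekday}_d) \cdot u(\text{doy}_d) \cdot \text{uplift}(d)\big),$$

with $b_s$ scaled so the expected annual total equals the configured volume
(the 2019 registry totals by default). Composition is *multiplicative*, not
additive as in the fitted model — intensities must stay non-negative, and
the deliberate generator/model mismatch doubles as a robustness check on
the fitting stage. Counts are Poisson rather than negative binomial because
no dispersion information is available; overdispersion would enter as a
config extension. Transport outcomes are Bernoulli with the station's
published transport share.

Defaults, chosen once from the published summaries: the diurnal shape is
Wandsbek's hourly profile (the only full 24-slot profile published),
weekday modulation amplitude 0.04 (published weekday totals vary about ±4%
around their mean), smooth yearly amplitude 0.15, and uplifts 1.05 / 1.08 /
1.20 for break / holiday / event days (event weeks run up to ~20–28% above
the weekly average). `apply_scenario()` rescales expected volumes by area
(default East +19%, South +22%, West +14%) to mimic the 2021-like demand
shift; per-station 2021 volumes were never published, so this scenario is
illustrative, not a reproduction. Each station draws from its own stream
derived from the master seed, so tables are bit-reproducible.

What the generator does *not* emulate: spatial locations, within-hour
arrival times, inter-station correlation, overdispersion, and multi-year
trend. Tests passing on synthetic data therefore certify the pipeline's
arithmetic and statistical behaviour, not the fidelity of any real-world
forecast.

## Hourly workload and staffing strategies

The capacity rule is the standard frequency calculation for emergency
services: the demand in an hour slot is the average operation rate (annual
slot count / 365) times the mean operation time (default 60 minutes, an
upper-point estimate for a compact city); the supply is 60 minutes per CEP
on duty; workload is their ratio in percent. With one around-the-clock CEP
the daily average workload of a station reduces to
`annual_total / 8760 * 100`, which reproduces the published station
averages (e.g. Finkenwerder 4.37%, Altona 44.26%) exactly, and the
published Wandsbek hourly table to the printed two decimals. A handful of
published averages differ from this identity by 0.01–0.03 percentage
points (they appear to average pre-rounded hourly rates); comparisons to
those use a 0.05-pp tolerance.

Feasibility uses two thresholds: 85% ("realistic" sustainable utilisation,
leaving headroom for administration and recovery) and 100% (hard ceiling);
a unit is *sufficient* when no slot exceeds 85%.

`cep_strategies()` builds the investigated catalogue: one 24-h CEP per
station (#1a), per six higher-demand stations (#1b) or per four high-demand
stations (#1c); the same plus a second 12-h CEP at the four high-demand
stations (#2a–c); ten pooled groups sharing one 24-h CEP (#3a); second
12-h CEPs for the eight higher-demand groups (#3b); and an extended #3b
adding 1, 1, 3 and 5 evening hours to four groups. The second-CEP duty
window is 07:00–19:00 throughout: the published staff-hour totals all price
the second shift at 12 hours, which contradicts one textual "9.00 to 19.00"
— the 12-hour accounting wins, and the window is a configuration knob.
Group pooling sums member rates per slot and divides by the CEPs on duty
there, which makes the one-CEP group average exactly additive in member
averages.

Staff-hour accounting is pure arithmetic — daily scheduled hours times 365 —
and reproduces all published yearly totals exactly (148,920 / 166,440 /
70,080 / 52,560 / 87,600 / 122,640 / 126,290 hours for strategies
1a/2a/2b/2c/3a/3b/3b-extended).

## Worked example

```{r example, eval = FALSE}
registry <- load_station_table()
wan <- profile_from_rates(load_wandsbek_hourly()$rate, "Wan")

tab <- station_workload_table(wan)
attr(tab, "average")            # 55.69625  -> printed as 55.70%
tab$workload[tab$hour_slot == 10]  # 88.77, the only slot above 85%

evaluate_strategies(registry)[, c("id", "staff_hours_per_year")]
```

The full pipeline (statistics, clustering, generator, seasonal fit,
cross-validation, strategy comparison) runs as one call:

```{r pipeline, eval = FALSE}
bundle <- run_full_analysis(run_config("synthetic", seed = 1L,
                                       output_dir = "cep-report"))
bundle$strategies
```

## Problem sizes and numerical choices

The test suite works at desk scale: one synthetic year (≈ 48,000 events),
bootstrap sizes of 300–500, ten-replicate calibration checks and 3–13
cross-validation windows. Degenerate inputs are defined, not accidental:
identical groups give H = 0 and p = 1; a constant sequence is an error for
rank correlation; a slot with demand but nobody on duty is an *uncovered*
marker (infinite workload), not a division error; a zero-volume station
generates zero events. Reported percentages are rounded to two decimals
only at the reporting edge; full precision is kept internally.

## Limitations

* The workload model is a frequency average, not a queueing model: no
  waiting times, no stochastic coverage guarantees, no vehicle routing, no
  mid-shift floating of CEPs between stations.
* The 2021-like scenario rescales area volumes only; the true 2021
  station-level distribution is unknown.
* The seasonal model's intervals are bootstrap approximations of posterior
  credible intervals, not posterior samples.
* Clustering reconstructs an unstated feature convention; see the k = 4
  caveat above.
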