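Package: cepplanr
Title: Demand Analysis and Staffing Strategies for Community Emergency Paramedics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing non-time-critical ambulance demand at the
    station level and for sizing community emergency paramedic (CEP) shift
    plans. Provides rank-based group comparisons (Kruskal-Wallis with
    Dunn-Bonferroni post hoc tests, Spearman correlation), hierarchical
    clustering of rescue stations, an additive demand model with
    piecewise-linear trend, Fourier seasonal blocks and holiday/event
    regressors evaluated by rolling-origin cross-validation, a Poisson
    call-event generator with calendar effects, and an hourly workload and
    staff-hour evaluator for 24-hour and 12-hour CEP staffing strategies.
    Ships a registry of the 17 major Hamburg rescue stations with their
    2019 operation counts as a worked fixture.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    lmtest
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
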