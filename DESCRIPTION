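Package: carbonsplit
Title: Weather-Normalized Black Carbon Source Attribution and Pandemic
    Mobility Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for converting daily pollutant and meteorology time series
    into transport-attributed black-carbon emission proxies and for
    quantifying how epidemic waves and quarantine policy shifted private
    versus public transport usage. Implements random-forest weather
    normalization by counterfactual meteorology resampling, tracer-based
    decomposition of normalized black carbon into transport- and
    factory-attributed components, long-run trend removal against a
    pre-pandemic baseline, day-of-week and outbreak percent-change transport
    statistics, regime-wise public-versus-private regressions, and
    partial-dependence analysis of epidemic covariates. Ships a synthetic
    emission-dispersion scenario generator so the full chain is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lubridate,
    purrr,
    ranger,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
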