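# Shared fixtures, built once per test run and cached in this environment.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# Three years, no outbreaks: the workhorse for normalization/attribution
# unit tests.
quiet_config <- function(seed = 5, n_days = 1096, ...) {
  synthetic_config(n_days = n_days, seed = seed, outbreak_windows = NULL, ...)
}

quiet_scenario <- function() {
  fixture("quiet", function() simulate_scenario(quiet_config()))
}

# Fully deterministic emissions with no dispersion: observed equals the
# noiseless emission total on every day.
deterministic_config <- function(seed = 5, ...) {
  synthetic_config(
    n_days = 1096, seed = seed, outbreak_windows = NULL,
    dispersion_strength = c(wind = 0, blh = 0), noise_sd = 0,
    biomass_spike_rate = 0, transport_noise_sd = 0,
    weekly_amplitude = 0, demand_noise_sd = 0, ...)
}

# The default six-year study scenario (outbreaks, dispersion, noise).
default_scenario <- function(seed = 1) {
  fixture(paste0("default", seed),
          function() simulate_scenario(synthetic_config(seed = seed)))
}

# Full normalization -> attribution chain on the default scenario, shared
# by attribution and response tests.
default_chain <- function(seed = 1, n_samples = 100) {
  fixture(paste0("chain", seed), function() {
    scn <- default_scenario(seed)
    norm <- list()
    for (sp in c("BC", "NO3", "SO4")) {
      m <- fit_met_model(scn$pollutants, scn$met, sp,
                         seed = carbonsplit:::substream_seed(seed, paste0("normalize.", sp)))
      norm[[sp]] <- normalize_pollutant(m, n_samples = n_samples, seed = seed)
    }
    normalized <- tibble::tibble(
      date = norm$BC$date, BC = norm$BC$normalized,
      NO3 = norm$NO3$normalized, SO4 = norm$SO4$normalized)
    model <- fit_attribution_model(normalized, seed = seed)
    split <- attribute_sources(model, normalized)
    panel <- build_monthly_panel(split, scn$monthly_volumes, scn$met,
                                 scn$epidemic)
    list(scenario = scn, normalized = normalized, model = model,
         split = split, panel = panel)
  })
}

monthly_mean <- function(data, value) {
  data |>
    dplyr::group_by(month = lubridate::floor_date(date, "month")) |>
    dplyr::summarise(x = mean(.data[[value]]), .groups = "drop")
}
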