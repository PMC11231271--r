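#' Configuration for the synthetic emission--dispersion scenario
#'
#' Builds and validates the parameter set for the scenario generator. The
#' defaults encode a six-year urban record (2018--2023) in which transport
#' and factory emissions of black carbon are diluted or concentrated by a
#' multiplicative meteorological dispersion factor, nitrate is co-emitted
#' with transport and sulfate with factories, public-transport demand is
#' suppressed during three epidemic outbreak windows, and private-transport
#' emissions respond to public-transport volume with a regime-dependent
#' coupling slope (positive before the pandemic era, negative inside it).
#'
#' Units: emission levels are in concentration-equivalent µg/m³; transport
#' volumes in million passengers per day (monthly volumes use a 30-day
#' month); `factory_trend` is the fractional decline per decade;
#' `weekly_amplitude` the fractional workday/weekend modulation of
#' transport emissions.
#'
#' @param n_days Number of days (>= 730).
#' @param start_date First calendar day.
#' @param seed Integer master seed; each generator draws from an
#'   independent deterministic substream.
#' @param factory_level,factory_trend Factory emission level (µg/m³) and
#'   fractional decline per decade.
#' @param transport_level Mean transport emission level (µg/m³).
#' @param weekly_amplitude Fractional weekly cycle on transport emissions.
#' @param transport_noise_sd,transport_noise_rho Marginal sd and AR(1)
#'   coefficient of the fast daily transport-emission noise.
#' @param transport_slow_sd,transport_slow_rho Relative sd and AR(1)
#'   coefficient of a slowly varying multiplicative demand-shock
#'   component of transport emissions (month-scale scatter).
#' @param biomass_spike_rate Expected biomass-burning spike events per year.
#' @param biomass_mean Mean spike magnitude (µg/m³).
#' @param outbreak_windows Data frame with columns `name`, `start`, `end`,
#'   `suppression` (metro), `bus_suppression`, `taxi_suppression`,
#'   `private_shift`, `transmission`, `fatality`, `case_total`.
#'   Suppression/shift fractions lie in [0, 1]; windows must fall inside
#'   the date range.
#' @param pandemic_start,pandemic_end Bounds of the pandemic coupling
#'   regime (the era, wider than any single outbreak window).
#' @param residual_suppression Fractional volume suppression on
#'   pandemic-era days outside outbreak windows (partial recovery).
#' @param post_recovery Named fractions of baseline volume reached after
#'   the pandemic era, per mode.
#' @param coupling Named slopes (µg/m³ per million monthly passengers) of
#'   private-transport emission on public-transport volume, per regime
#'   `pre`, `pandemic`, `post`.
#' @param metro_level,bus_level,taxi_level Baseline daily volumes
#'   (million passengers/day).
#' @param demand_growth Fractional demand growth per year.
#' @param demand_seasonal_amplitude Fractional seasonal demand cycle.
#' @param demand_noise_sd,demand_noise_rho Relative AR(1) demand noise.
#' @param noise_sd Observation noise sd (µg/m³) on each pollutant.
#' @param dispersion_strength Named k-coefficients `wind`, `blh` of the
#'   log-linear dispersion factor.
#' @param tracer_gains Named gains `a_no3`, `b_so4` linking tracers to
#'   transport/factory emissions.
#' @param met_ar AR(1) coefficient shared by the meteorology columns.
#' @param met_amp_scale,met_noise_scale Multipliers on the seasonal
#'   amplitudes and noise sds of the meteorology columns.
#' @param met_trend Named fractional trends per decade applied to the
#'   ventilation variables (`blh`, `wind`); a slow increase in ventilation
#'   makes the raw concentration trend steeper than the emission trend.
#' @param holiday_blocks Data frame with `start_md`, `end_md`
#'   ("MM-DD" strings) repeated every year as legal-vacation blocks.
#'
#' @return A validated list of class `synthetic_config`.
#' @export
#' @examples
#' cfg <- synthetic_config(n_days = 730, seed = 1, outbreak_windows = NULL)
#' cfg$transport_level
synthetic_config <- function(
    n_days = 2191,
    start_date = as.Date("2018-01-01"),
    seed = 1L,
    factory_level = 3.0,
    factory_trend = 0.66,
    transport_level = 2.0,
    weekly_amplitude = 0.2,
    transport_noise_sd = 0.3,
    transport_noise_rho = 0.6,
    transport_slow_sd = 0,
    transport_slow_rho = 0.9,
    biomass_spike_rate = 10,
    biomass_mean = 1.0,
    outbreak_windows = default_outbreak_windows(),
    pandemic_start = as.Date("2020-02-01"),
    pandemic_end = as.Date("2022-12-31"),
    residual_suppression = 0.12,
    post_recovery = c(metro = 0.92, bus = 0.58, taxi = 0.90),
    coupling = c(pre = 0.03, pandemic = -0.17, post = 0.03),
    metro_level = 0.9,
    bus_level = 0.8,
    taxi_level = 0.3,
    demand_growth = 0.002,
    demand_seasonal_amplitude = 0.07,
    demand_noise_sd = 0.03,
    demand_noise_rho = 0.8,
    noise_sd = 0.3,
    dispersion_strength = c(wind = 0.25, blh = 0.35),
    tracer_gains = c(a_no3 = 1.5, b_so4 = 1.2),
    met_ar = 0.7,
    met_amp_scale = 1,
    met_noise_scale = 1,
    met_trend = c(blh = 0.18, wind = 0.06),
    holiday_blocks = data.frame(start_md = "02-01", end_md = "02-07")) {
  if (is.null(outbreak_windows)) {
    outbreak_windows <- default_outbreak_windows()[0, ]
  }
  cfg <- list(
    n_days = as.integer(n_days), start_date = as.Date(start_date),
    seed = as.integer(seed),
    factory_level = factory_level, factory_trend = factory_trend,
    transport_level = transport_level, weekly_amplitude = weekly_amplitude,
    transport_noise_sd = transport_noise_sd,
    transport_noise_rho = transport_noise_rho,
    transport_slow_sd = transport_slow_sd,
    transport_slow_rho = transport_slow_rho,
    biomass_spike_rate = biomass_spike_rate, biomass_mean = biomass_mean,
    outbreak_windows = tibble::as_tibble(outbreak_windows),
    pandemic_start = as.Date(pandemic_start),
    pandemic_end = as.Date(pandemic_end),
    residual_suppression = residual_suppression,
    post_recovery = post_recovery,
    coupling = coupling,
    metro_level = metro_level, bus_level = bus_level, taxi_level = taxi_level,
    demand_growth = demand_growth,
    demand_seasonal_amplitude = demand_seasonal_amplitude,
    demand_noise_sd = demand_noise_sd, demand_noise_rho = demand_noise_rho,
    noise_sd = noise_sd,
    dispersion_strength = dispersion_strength,
    tracer_gains = tracer_gains,
    met_ar = met_ar, met_amp_scale = met_amp_scale,
    met_noise_scale = met_noise_scale, met_trend = met_trend,
    holiday_blocks = tibble::as_tibble(holiday_blocks))
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
}

#' Default epidemic outbreak windows
#'
#' Three month-aligned outbreak windows with volume-suppression fractions
#' per transport mode, private-transport emission shifts, ordinal
#' transmission/fatality ranks and epidemic pulse totals. The ordinal
#' encoding deliberately gives the first and third windows the same pair
#' (1, 3) and the middle window (2, 2); the encoding is configurable but
#' this default is kept as printed in the source it mirrors.
#'
#' @return A tibble with one row per window.
#' @export
default_outbreak_windows <- function() {
  tibble::tibble(
    name = c("alpha", "delta", "omicron"),
    start = as.Date(c("2020-02-01", "2021-07-01", "2022-11-01")),
    end = as.Date(c("2020-05-31", "2021-08-31", "2022-12-31")),
    suppression = c(0.16, 0.30, 0.49),
    bus_suppression = c(0.30, 0.37, 0.66),
    taxi_suppression = c(0.47, 0.48, 0.49),
    private_shift = c(0.02, 0.03, 0.05),
    transmission = c(1, 2, 1),
    fatality = c(3, 2, 3),
    case_total = c(93, 235, 2000))
}

validate_synthetic_config <- function(cfg) {
  if (!is.finite(cfg$n_days) || cfg$n_days < 730) {
    abort("`n_days` must be at least 730 (two full years).",
          class = "carbonsplit_config_error")
  }
  lvls <- c(cfg$factory_level, cfg$transport_level, cfg$noise_sd,
            cfg$biomass_mean, cfg$metro_level, cfg$bus_level, cfg$taxi_level)
  if (any(lvls < 0)) {
    abort("Emission levels, volumes and noise_sd must be nonnegative.",
          class = "carbonsplit_config_error")
  }
  w <- cfg$outbreak_windows
  if (nrow(w) > 0) {
    need <- c("name", "start", "end", "suppression", "private_shift")
    miss <- setdiff(need, names(w))
    if (length(miss)) {
      abort(paste0("outbreak_windows lacks column(s): ",
                   paste(miss, collapse = ", ")),
            class = "carbonsplit_config_error")
    }
    sup <- c(w$suppression, w$private_shift,
             w$bus_suppression %||% 0, w$taxi_suppression %||% 0)
    if (any(sup < 0 | sup > 1)) {
      abort("Suppression and shift fractions must lie in [0, 1].",
            class = "carbonsplit_config_error")
    }
    end_date <- cfg$start_date + cfg$n_days - 1
    if (any(w$start < cfg$start_date) || any(w$end > end_date) ||
        any(w$start > w$end)) {
      abort("Outbreak windows must lie inside the simulated date range.",
            class = "carbonsplit_config_error")
    }
  }
  cfg
}

scenario_dates <- function(cfg) seq(cfg$start_date, by = "day", length.out = cfg$n_days)

# Per-day outbreak window index (NA outside all windows).
window_index <- function(dates, windows) {
  idx <- rep(NA_integer_, length(dates))
  if (nrow(windows) == 0) return(idx)
  for (i in seq_len(nrow(windows))) {
    idx[dates >= windows$start[i] & dates <= windows$end[i]] <- i
  }
  idx
}
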