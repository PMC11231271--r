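#' Generate synthetic daily meteorology
#'
#' Each variable is a seasonal sinusoid plus an AR(1) perturbation, with the
#' physical constraints of the real reanalysis fields it emulates: dew point
#' never exceeds air temperature, boundary layer height is positive, and
#' precipitation is nonnegative. The ventilation variables (BLH, wind) carry
#' a slow configurable upward trend so that raw pollutant concentrations can
#' decline faster than the underlying emissions, as multi-year urban records
#' show once meteorology is accounted for.
#'
#' @param config A [synthetic_config()].
#' @return A tibble with columns `date`, `U10`, `V10`, `D2M`, `T2M`, `BLH`,
#'   `MBLD`, `SP`, `TP` (SI units: m/s, K, m, W/m², Pa, m of water).
#' @export
#' @examples
#' met <- generate_meteorology(synthetic_config(n_days = 730, outbreak_windows = NULL))
#' summary(met$T2M)
generate_meteorology <- function(config) {
  cfg <- validate_synthetic_config(config)
  dates <- scenario_dates(cfg)
  n <- length(dates)
  doy <- as.numeric(format(dates, "%j"))
  yrs <- days_elapsed(dates) / 365.25
  seas <- function(amp, peak_doy) {
    cfg$met_amp_scale * amp * cos(2 * pi * (doy - peak_doy) / 365.25)
  }
  set.seed(substream_seed(cfg$seed, "met"))
  ar <- function(sdv) ar1_noise(n, cfg$met_ar, cfg$met_noise_scale * sdv)

  t2m <- 289 + seas(11, 200) + ar(2.5)
  dew_gap <- pmax(0.2, 4 + ar(2))            # keeps D2M <= T2M everywhere
  trend_of <- function(nm) {
    if (nm %in% names(cfg$met_trend)) cfg$met_trend[[nm]] else 0
  }
  wind_trend <- 1 + trend_of("wind") * yrs / 10
  blh_trend <- 1 + trend_of("blh") * yrs / 10
  met <- tibble::tibble(
    date = dates,
    U10 = (1.5 + seas(0.8, 30) + ar(1.2)) * wind_trend,
    V10 = (0.8 + seas(0.6, 210) + ar(1.2)) * wind_trend,
    T2M = t2m,
    D2M = t2m - dew_gap,
    BLH = pmax(50, (550 + seas(200, 180) + ar(120)) * blh_trend),
    MBLD = pmax(5, 300 + seas(100, 180) + ar(60)),
    SP = 101000 + seas(800, 15) + ar(300),
    TP = pmax(0, 0.004 + seas(0.003, 190) + ar(0.004)))
  met[, c("date", "U10", "V10", "D2M", "T2M", "BLH", "MBLD", "SP", "TP")]
}

#' Generate ground-truth emissions, dispersion and transport volumes
#'
#' Builds the noiseless components of the ambient black-carbon budget:
#' factory emissions declining linearly over years, transport emissions
#' carrying a weekly cycle and a regime-dependent coupling to
#' public-transport volume, sparse biomass-burning spikes whose occurrence
#' probability rises on dry days, and a multiplicative dispersion factor
#' `exp(-k_w * z_wind - k_b * z_BLH)` from standardized wind speed and
#' boundary layer height. Public transport volume is the sum of metro and
#' bus daily volumes, each suppressed by its configured fraction inside
#' outbreak windows, by a residual fraction elsewhere in the pandemic era,
#' and held at a partial-recovery level afterwards.
#'
#' @param config A [synthetic_config()].
#' @param met Meteorology table from [generate_meteorology()], covering the
#'   full date range.
#' @return A tibble with per-day `E_transport`, `E_factory`, `E_biomass`
#'   (µg/m³ equivalents), `dispersion_factor`, mode volumes and
#'   `public_volume` (million passengers/day), `regime`, `window`,
#'   `suppression` and `private_shift`.
#' @export
generate_truth <- function(config, met) {
  cfg <- validate_synthetic_config(config)
  dates <- scenario_dates(cfg)
  if (!all(dates %in% met$date)) {
    abort("`met` does not cover the full simulated date range.",
          class = "carbonsplit_alignment_error")
  }
  met <- met[match(dates, met$date), ]
  n <- length(dates)
  yrs <- days_elapsed(dates) / 365.25
  set.seed(substream_seed(cfg$seed, "truth"))

  ## regimes and windows ------------------------------------------------
  regime <- dplyr::case_when(
    dates < cfg$pandemic_start ~ "pre",
    dates <= cfg$pandemic_end ~ "pandemic",
    TRUE ~ "post")
  widx <- window_index(dates, cfg$outbreak_windows)
  in_window <- !is.na(widx)
  supp_metro <- supp_bus <- supp_taxi <- numeric(n)
  shift <- numeric(n)
  if (nrow(cfg$outbreak_windows) > 0) {
    w <- cfg$outbreak_windows
    supp_metro[in_window] <- w$suppression[widx[in_window]]
    supp_bus[in_window] <- (w$bus_suppression %||% w$suppression)[widx[in_window]]
    supp_taxi[in_window] <- (w$taxi_suppression %||% w$suppression)[widx[in_window]]
    shift[in_window] <- w$private_shift[widx[in_window]]
  }
  resid <- regime == "pandemic" & !in_window
  supp_metro[resid] <- cfg$residual_suppression
  supp_bus[resid] <- cfg$residual_suppression
  supp_taxi[resid] <- cfg$residual_suppression
  post <- regime == "post"
  supp_metro[post] <- 1 - cfg$post_recovery[["metro"]]
  supp_bus[post] <- 1 - cfg$post_recovery[["bus"]]
  supp_taxi[post] <- 1 - cfg$post_recovery[["taxi"]]

  ## transport demand and volumes ---------------------------------------
  doy <- as.numeric(format(dates, "%j"))
  demand <- (1 + cfg$demand_growth * yrs) *
    (1 + cfg$demand_seasonal_amplitude * cos(2 * pi * (doy - 100) / 365.25)) *
    (1 + ar1_noise(n, cfg$demand_noise_rho, cfg$demand_noise_sd))
  demand <- pmax(demand, 0)
  metro_volume <- cfg$metro_level * demand * (1 - supp_metro)
  bus_volume <- cfg$bus_level * demand * (1 - supp_bus)
  taxi_volume <- cfg$taxi_level * demand * (1 - supp_taxi)
  public_volume <- metro_volume + bus_volume

  ## factory ------------------------------------------------------------
  e_factory <- pmax(0, cfg$factory_level * (1 - cfg$factory_trend * yrs / 10))

  ## transport: level + regime coupling + weekly cycle + window shift ----
  v_monthly <- 30 * public_volume        # million passengers / 30-day month
  v_base <- 30 * (cfg$metro_level + cfg$bus_level)
  v_ref <- dplyr::case_when(
    regime == "pandemic" ~ v_base * (1 - cfg$residual_suppression),
    TRUE ~ v_base)
  beta <- unname(cfg$coupling[regime])
  dow <- lubridate::wday(dates, week_start = 1)        # 1 = Monday
  weekly <- ifelse(dow <= 5, 0.5, -1.25)               # mean zero over a week
  slow <- ar1_noise(n, cfg$transport_slow_rho, cfg$transport_slow_sd)
  base <- cfg$transport_level * (1 + shift) + beta * (v_monthly - v_ref)
  e_transport <- base * (1 + cfg$weekly_amplitude * weekly) * (1 + slow) +
    ar1_noise(n, cfg$transport_noise_rho, cfg$transport_noise_sd)
  e_transport <- pmax(0, e_transport)

  ## biomass spikes, more likely on dry days -----------------------------
  p_base <- cfg$biomass_spike_rate / 365.25
  dry <- met$TP <= quantile(met$TP, 0.2)
  wgt <- ifelse(dry, 3, 0.5)
  p_spike <- pmin(1, p_base * wgt / mean(wgt))
  spikes <- runif(n) < p_spike
  e_biomass <- numeric(n)
  e_biomass[spikes] <- rexp(sum(spikes), rate = 1 / max(cfg$biomass_mean, 1e-12))

  ## dispersion ----------------------------------------------------------
  wind <- sqrt(met$U10^2 + met$V10^2)
  zs <- function(x) if (sd(x) > 0) (x - mean(x)) / sd(x) else x * 0
  dispersion <- exp(-cfg$dispersion_strength[["wind"]] * zs(wind) -
                      cfg$dispersion_strength[["blh"]] * zs(met$BLH))

  tibble::tibble(
    date = dates,
    E_transport = e_transport, E_factory = e_factory, E_biomass = e_biomass,
    dispersion_factor = unname(dispersion),
    metro_volume = metro_volume, bus_volume = bus_volume,
    taxi_volume = taxi_volume, public_volume = public_volume,
    regime = regime, window = ifelse(in_window, cfg$outbreak_windows$name[widx], NA_character_),
    suppression = supp_metro, private_shift = shift)
}

#' Generate noisy pollutant observations from ground truth
#'
#' Ambient concentrations follow the dispersion model: total emission times
#' the dispersion factor plus Gaussian noise, clipped at zero. Nitrate is
#' co-emitted with transport (scaled by a cold-season gas--particle
#' partitioning factor) and sulfate with factories, making the two tracers
#' usable for source attribution downstream.
#'
#' @param truth Output of [generate_truth()].
#' @param config The same [synthetic_config()].
#' @return A pollutant tibble with columns `date`, `BC`, `NO3`, `SO4`
#'   (µg/m³).
#' @export
generate_observations <- function(truth, config) {
  cfg <- validate_synthetic_config(config)
  dates <- scenario_dates(cfg)
  if (!identical(as.Date(truth$date), dates)) {
    abort("`truth` dates are not aligned with the configuration.",
          class = "carbonsplit_alignment_error")
  }
  n <- length(dates)
  set.seed(substream_seed(cfg$seed, "obs"))
  doy <- as.numeric(format(dates, "%j"))
  chem_seasonal <- 1 + 0.3 * cos(2 * pi * (doy - 15) / 365.25)  # winter-high NO3
  disp <- truth$dispersion_factor
  noise <- function() rnorm(n, 0, cfg$noise_sd)
  bc <- (truth$E_transport + truth$E_factory + truth$E_biomass) * disp + noise()
  no3 <- cfg$tracer_gains[["a_no3"]] * truth$E_transport * disp * chem_seasonal + noise()
  so4 <- cfg$tracer_gains[["b_so4"]] * truth$E_factory * disp + noise()
  tibble::tibble(date = dates, BC = pmax(0, bc), NO3 = pmax(0, no3),
                 SO4 = pmax(0, so4))
}

#' Generate epidemic covariates
#'
#' Daily case counts are zero outside the configured outbreak windows and
#' follow a seeded log-normal epidemic pulse inside each window (Poisson
#' counts around a pulse whose expected total is the window's
#' `case_total`). Each window carries its ordinal transmission/fatality
#' ranks; the calendar flags every day as workday, weekend or
#' legal-vacation using the configured holiday blocks (a synthetic
#' Spring-Festival block each February by default).
#'
#' @param config A [synthetic_config()].
#' @return A tibble with `date`, `cases`, `transmission`, `fatality`,
#'   `period`, `variant`.
#' @export
generate_epidemic <- function(config) {
  cfg <- validate_synthetic_config(config)
  dates <- scenario_dates(cfg)
  n <- length(dates)
  set.seed(substream_seed(cfg$seed, "epi"))
  cases <- integer(n)
  transmission <- fatality <- numeric(n)
  variant <- rep(NA_character_, n)
  w <- cfg$outbreak_windows
  if (nrow(w) > 0) {
    for (i in seq_len(nrow(w))) {
      sel <- which(dates >= w$start[i] & dates <= w$end[i])
      len <- length(sel)
      shape <- stats::dlnorm(seq_len(len), meanlog = log(len / 3), sdlog = 0.6)
      lambda <- w$case_total[i] * shape / sum(shape)
      cases[sel] <- rpois(len, lambda)
      transmission[sel] <- w$transmission[i]
      fatality[sel] <- w$fatality[i]
      variant[sel] <- w$name[i]
    }
  }
  md <- format(dates, "%m-%d")
  vacation <- rep(FALSE, n)
  hb <- cfg$holiday_blocks
  for (i in seq_len(nrow(hb))) {
    vacation <- vacation | (md >= hb$start_md[i] & md <= hb$end_md[i])
  }
  dow <- lubridate::wday(dates, week_start = 1)
  period <- dplyr::case_when(
    vacation ~ "legal-vacation",
    dow >= 6 ~ "weekend",
    TRUE ~ "workday")
  tibble::tibble(date = dates, cases = cases, transmission = transmission,
                 fatality = fatality, period = period, variant = variant)
}

#' Simulate a complete synthetic scenario
#'
#' Runs the four generators with one master seed and returns every table
#' the analysis pipeline consumes, plus the ground truth used as the
#' recovery oracle in tests.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `synthetic_scenario` with elements `config`,
#'   `met`, `truth`, `pollutants`, `epidemic`, `daily_volumes` and
#'   `monthly_volumes` (million passengers per 30-day month).
#' @export
#' @examples
#' scn <- simulate_scenario(synthetic_config(n_days = 730, seed = 7, outbreak_windows = NULL))
#' names(scn)
simulate_scenario <- function(config = synthetic_config()) {
  cfg <- validate_synthetic_config(config)
  met <- generate_meteorology(cfg)
  truth <- generate_truth(cfg, met)
  pollutants <- generate_observations(truth, cfg)
  epidemic <- generate_epidemic(cfg)
  daily_volumes <- truth[, c("date", "metro_volume", "bus_volume",
                             "taxi_volume", "public_volume")]
  monthly_volumes <- daily_volumes |>
    dplyr::mutate(month = month_start(.data$date)) |>
    dplyr::group_by(month = .data$month) |>
    dplyr::summarise(dplyr::across(
      c("metro_volume", "bus_volume", "taxi_volume", "public_volume"),
      ~ 30 * mean(.x)), .groups = "drop")
  structure(list(config = cfg, met = met, truth = truth,
                 pollutants = pollutants, epidemic = epidemic,
                 daily_volumes = daily_volumes,
                 monthly_volumes = monthly_volumes),
            class = "synthetic_scenario")
}

#' Write a simulated scenario to CSV files
#'
#' @param scenario A [simulate_scenario()] result.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    met = file.path(dir, "meteorology.csv"),
    pollutants = file.path(dir, "pollutants.csv"),
    epidemic = file.path(dir, "epidemic.csv"),
    truth = file.path(dir, "truth.csv"),
    daily_volumes = file.path(dir, "daily_volumes.csv"),
    monthly_volumes = file.path(dir, "monthly_volumes.csv"))
  utils::write.csv(scenario$met, paths["met"], row.names = FALSE)
  utils::write.csv(scenario$pollutants, paths["pollutants"], row.names = FALSE)
  utils::write.csv(scenario$epidemic, paths["epidemic"], row.names = FALSE)
  utils::write.csv(scenario$truth, paths["truth"], row.names = FALSE)
  utils::write.csv(scenario$daily_volumes, paths["daily_volumes"], row.names = FALSE)
  utils::write.csv(scenario$monthly_volumes, paths["monthly_volumes"], row.names = FALSE)
  invisible(paths)
}
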