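test_that("generators are deterministic and respect physical bounds", {
  cfg <- quiet_config(seed = 11)
  met1 <- generate_meteorology(cfg)
  met2 <- generate_meteorology(cfg)
  expect_identical(met1, met2)
  expect_named(met1, c("date", "U10", "V10", "D2M", "T2M", "BLH", "MBLD",
                       "SP", "TP"))
  expect_true(all(met1$D2M <= met1$T2M))
  expect_true(all(met1$BLH > 0))
  expect_true(all(met1$TP >= 0))

  t1 <- generate_truth(cfg, met1)
  t2 <- generate_truth(cfg, met1)
  expect_identical(t1, t2)
  expect_true(all(t1$E_transport >= 0 & t1$E_factory >= 0 & t1$E_biomass >= 0))
  expect_true(all(t1$dispersion_factor > 0))

  o1 <- generate_observations(t1, cfg)
  expect_identical(o1, generate_observations(t1, cfg))
  expect_true(all(o1$BC >= 0 & o1$NO3 >= 0 & o1$SO4 >= 0))

  e1 <- generate_epidemic(cfg)
  expect_identical(e1, generate_epidemic(cfg))
})

test_that("degenerate process settings yield constant meteorology", {
  cfg <- quiet_config(met_ar = 0, met_amp_scale = 0, met_noise_scale = 0,
                      met_trend = c(blh = 0, wind = 0))
  met <- generate_meteorology(cfg)
  for (v in c("U10", "V10", "D2M", "T2M", "BLH", "MBLD", "SP", "TP")) {
    expect_equal(sd(met[[v]]), 0, info = v)
  }
  expect_equal(met$T2M[1], 289)
  expect_equal(met$SP[1], 101000)
})

test_that("T2M lag-1 autocorrelation matches the configured AR coefficient", {
  cfg <- synthetic_config(n_days = 2192, seed = 7, outbreak_windows = NULL)
  met <- generate_meteorology(cfg)
  doy <- as.numeric(format(met$date, "%j"))
  seas <- lm(met$T2M ~ sin(2 * pi * doy / 365.25) + cos(2 * pi * doy / 365.25))
  resid <- residuals(seas)
  ac1 <- cor(resid[-1], resid[-length(resid)])
  expect_lt(abs(ac1 - cfg$met_ar), 0.1)
})

test_that("null outbreak forcing reproduces the no-outbreak run", {
  win0 <- default_outbreak_windows()
  win0$suppression <- 0
  win0$bus_suppression <- 0
  win0$taxi_suppression <- 0
  win0$private_shift <- 0
  # residual pandemic-era suppression is zeroed too: the comparison isolates
  # the window forcing itself
  cfg_null <- synthetic_config(seed = 3, outbreak_windows = win0,
                               residual_suppression = 0)
  cfg_none <- synthetic_config(seed = 3, outbreak_windows = NULL,
                               residual_suppression = 0)
  met <- generate_meteorology(cfg_null)
  t_null <- generate_truth(cfg_null, met)
  t_none <- generate_truth(cfg_none, met)
  cols <- c("E_transport", "E_factory", "E_biomass", "dispersion_factor",
            "metro_volume", "bus_volume", "taxi_volume", "public_volume")
  expect_equal(t_null[, cols], t_none[, cols])
})

test_that("zero dispersion coefficients force a unit dispersion factor", {
  cfg <- quiet_config(dispersion_strength = c(wind = 0, blh = 0))
  truth <- generate_truth(cfg, generate_meteorology(cfg))
  expect_equal(truth$dispersion_factor, rep(1, nrow(truth)))
})

test_that("zero noise and unit dispersion conserve the emission budget", {
  cfg <- quiet_config(dispersion_strength = c(wind = 0, blh = 0), noise_sd = 0)
  scn <- simulate_scenario(cfg)
  total <- scn$truth$E_transport + scn$truth$E_factory + scn$truth$E_biomass
  expect_equal(scn$pollutants$BC, total, tolerance = 1e-12)
  # and the three-way split is the noiseless BC by construction
  expect_true(all(abs(scn$pollutants$BC - total) < 1e-9))
})

test_that("window suppression 0.49 halves public volume against matched months", {
  win <- tibble::tibble(
    name = "omicron", start = as.Date("2022-11-01"), end = as.Date("2022-12-31"),
    suppression = 0.49, bus_suppression = 0.49, taxi_suppression = 0.49,
    private_shift = 0.05, transmission = 1, fatality = 3, case_total = 2000)
  cfg <- synthetic_config(n_days = 1827, seed = 1, outbreak_windows = win)
  truth <- generate_truth(cfg, generate_meteorology(cfg))
  inwin <- truth$date >= win$start & truth$date <= win$end
  base <- truth$date < as.Date("2020-01-01") &
    format(truth$date, "%m") %in% c("11", "12")
  ratio <- mean(truth$public_volume[inwin]) / mean(truth$public_volume[base])
  expect_lt(abs(ratio - 0.51), 0.02)
})

test_that("tracers are proportional to their source emissions", {
  cfg <- quiet_config(factory_level = 0, noise_sd = 0)
  scn <- simulate_scenario(cfg)
  expect_equal(scn$pollutants$SO4, rep(0, nrow(scn$pollutants)))

  cfg2 <- quiet_config(transport_level = 0, noise_sd = 0, coupling = c(
    pre = 0, pandemic = 0, post = 0), transport_noise_sd = 0)
  scn2 <- simulate_scenario(cfg2)
  expect_equal(scn2$pollutants$NO3, rep(0, nrow(scn2$pollutants)))
})

test_that("dispersion degrades the raw emission-concentration correlation", {
  scn <- quiet_scenario()
  total <- scn$truth$E_transport + scn$truth$E_factory + scn$truth$E_biomass
  r_raw <- cor(scn$pollutants$BC, total)
  r_corrected <- cor(scn$pollutants$BC / scn$truth$dispersion_factor, total)
  expect_lt(r_raw, r_corrected)
})

test_that("epidemic pulses honor windows, totals and ordinal encodings", {
  cfg0 <- quiet_config()
  epi0 <- generate_epidemic(cfg0)
  expect_true(all(epi0$cases == 0))

  cfg <- synthetic_config(seed = 2)
  epi <- generate_epidemic(cfg)
  w <- cfg$outbreak_windows
  for (i in seq_len(nrow(w))) {
    sel <- epi$date >= w$start[i] & epi$date <= w$end[i]
    expect_equal(unique(epi$transmission[sel]), w$transmission[i])
    expect_equal(unique(epi$fatality[sel]), w$fatality[i])
    # Poisson pulse: total within 4 sd of the configured total
    expect_lt(abs(sum(epi$cases[sel]) - w$case_total[i]),
              4 * sqrt(w$case_total[i]) + 1)
  }
  expect_true(all(epi$cases[is.na(epi$variant)] == 0))
  # printed ordinal encoding: first and third windows share (1, 3)
  expect_equal(w$transmission, c(1, 2, 1))
  expect_equal(w$fatality, c(3, 2, 3))
})

test_that("calendar flags mark weekends and the February vacation block", {
  epi <- generate_epidemic(quiet_config())
  feb_days <- format(epi$date, "%m-%d") >= "02-01" &
    format(epi$date, "%m-%d") <= "02-07"
  expect_true(all(epi$period[feb_days] == "legal-vacation"))
  dow <- lubridate::wday(epi$date, week_start = 1)
  expect_true(all(epi$period[dow >= 6 & !feb_days] == "weekend"))
  expect_true(all(epi$period[dow < 6 & !feb_days] == "workday"))
})

test_that("suppression and shift induce a negative within-window association", {
  scn <- default_scenario(1)
  tr <- scn$truth[!is.na(scn$truth$window), ]
  m <- tr |>
    dplyr::group_by(month = lubridate::floor_date(date, "month")) |>
    dplyr::summarise(v = mean(public_volume), e = mean(E_transport),
                     .groups = "drop")
  expect_lt(cor(m$v, m$e), 0)
})

test_that("configuration validation rejects invalid settings", {
  expect_error(synthetic_config(n_days = 100),
               class = "carbonsplit_config_error")
  expect_error(synthetic_config(noise_sd = -1),
               class = "carbonsplit_config_error")
  win <- default_outbreak_windows()
  win$suppression[1] <- 1.2
  expect_error(synthetic_config(outbreak_windows = win),
               class = "carbonsplit_config_error")
  win2 <- default_outbreak_windows()
  win2$end[3] <- as.Date("2031-01-01")
  expect_error(synthetic_config(outbreak_windows = win2),
               class = "carbonsplit_config_error")
  cfg <- quiet_config()
  expect_error(generate_truth(synthetic_config(seed = 1),
                              generate_meteorology(cfg)),
               class = "carbonsplit_alignment_error")
})
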