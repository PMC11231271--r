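test_that("day-of-week table reproduces the published worked example", {
  stats <- day_of_week_stats(metro_daily_table())
  bd <- stats$by_day
  row <- function(d) bd[bd$weekday == d, ]
  expect_equal(row("Sunday")$mean, 1.15)
  expect_equal(row("Sunday")$sd, 0.33)
  expect_equal(row("Tuesday")$mean, 1.54)
  expect_equal(row("Tuesday")$sd, 0.55)
  expect_equal(row("Thursday")$mean, 1.63)  # half-away rounding, not half-even
  expect_equal(row("Saturday")$mean, 1.71)
  expect_equal(row("Saturday")$sd, 0.51)
  expect_equal(unname(stats$workday["mean"]), 1.47)
  expect_equal(unname(stats$workday["sd"]), 0.55)
  expect_equal(unname(stats$weekend["mean"]), 1.43)
  expect_equal(unname(stats$weekend["sd"]), 0.51)
  expect_equal(unname(stats$workday["n"] + stats$weekend["n"]), 45)
  expect_gt(stats$p_value, 0.05)
})

test_that("degenerate equal-volume groups give sd 0 and p 1", {
  df <- tibble::tibble(
    weekday = rep(c("Monday", "Tuesday", "Saturday", "Sunday"), each = 3),
    volume = 1.2)
  s <- day_of_week_stats(df)
  expect_equal(unname(s$workday["sd"]), 0)
  expect_equal(s$p_value, 1)
  expect_equal(s$t_statistic, 0)
})

test_that("weekday labels derive from dates when absent", {
  df <- tibble::tibble(date = as.Date("2023-01-02") + 0:13,  # two full weeks
                       volume = rep(c(rep(2, 5), rep(1, 2)), 2))
  s <- day_of_week_stats(df)
  expect_equal(unname(s$workday["mean"]), 2)
  expect_equal(unname(s$weekend["mean"]), 1)
  expect_error(day_of_week_stats(tibble::tibble(volume = 1:5)),
               class = "carbonsplit_schema_error")
})

test_that("percent change is exact on constructed ratios and scale-invariant", {
  months <- seq(as.Date("2018-01-01"), as.Date("2020-05-01"), by = "month")
  vol <- tibble::tibble(month = months, mode = "metro", volume = 10)
  periods <- default_periods()[1:2, ]  # pre baseline + alpha

  pc0 <- percent_change(vol, periods)
  expect_equal(pc0$percent_change[pc0$period == "alpha"], 0)

  vol_half <- vol
  vol_half$volume[vol_half$month >= as.Date("2020-02-01")] <- 5
  pc <- percent_change(vol_half, periods)
  expect_equal(pc$percent_change[pc$period == "alpha"], -50)

  vol_scaled <- vol_half
  vol_scaled$volume <- vol_scaled$volume * 7.3
  pc_s <- percent_change(vol_scaled, periods)
  expect_equal(pc_s$percent_change, pc$percent_change, tolerance = 1e-12)
})

test_that("a missing matched-month baseline is an error", {
  months <- seq(as.Date("2019-06-01"), as.Date("2020-05-01"), by = "month")
  vol <- tibble::tibble(month = months, mode = "metro", volume = 10)
  periods <- default_periods()[1:2, ]
  # baseline period lacks Feb-May calendar months before 2019-06
  expect_error(percent_change(vol[months >= as.Date("2019-06-01") &
                                    months <= as.Date("2019-09-01") |
                                    months >= as.Date("2020-02-01"), ],
                              periods),
               class = "carbonsplit_baseline_error")
})

test_that("segment regression recovers exact lines and respects boundaries", {
  months <- seq(as.Date("2018-01-01"), by = "month", length.out = 25)
  pre <- tibble::tibble(month = months, public_volume = seq(40, 64, by = 1))
  pre$bc_private <- pre$public_volume  # y = x
  seg <- suppressWarnings(segment_regression(pre, default_regimes()))
  expect_equal(seg$slope[seg$period == "pre"], 1, tolerance = 1e-10)
  expect_equal(seg$r_squared[seg$period == "pre"], 1, tolerance = 1e-10)

  # two adjacent periods with opposite true slopes must not be pooled
  m2 <- seq(as.Date("2020-02-01"), by = "month", length.out = 12)
  pand <- tibble::tibble(month = m2, public_volume = seq(30, 52, by = 2))
  pand$bc_private <- 100 - pand$public_volume  # slope -1
  both <- dplyr::bind_rows(pre, pand)
  seg2 <- suppressWarnings(segment_regression(both, default_regimes()))
  expect_equal(seg2$slope[seg2$period == "pre"], 1, tolerance = 1e-10)
  expect_equal(seg2$slope[seg2$period == "pandemic"], -1, tolerance = 1e-10)
})

test_that("independent noise yields a slope within two standard errors of zero", {
  set.seed(21)
  months <- seq(as.Date("2018-01-01"), by = "month", length.out = 24)
  df <- tibble::tibble(month = months, public_volume = runif(24, 40, 60),
                       bc_private = rnorm(24))
  seg <- suppressWarnings(segment_regression(df, default_regimes()))
  se <- (seg$conf_high[1] - seg$conf_low[1]) / (2 * qt(0.975, 22))
  expect_lt(abs(seg$slope[1]), 2 * se)
})

test_that("month overrides reassign or exclude ambiguous months", {
  months <- seq(as.Date("2019-10-01"), by = "month", length.out = 8)
  df <- tibble::tibble(month = months, public_volume = 1:8,
                       bc_private = 1:8)
  seg <- suppressWarnings(segment_regression(
    df, default_regimes(), overrides = c("2020-01" = "pandemic")))
  expect_equal(seg$n[seg$period == "pandemic"], 5)  # Jan 2020 moved over

  seg2 <- suppressWarnings(segment_regression(
    df, default_regimes(), overrides = c("2020-01" = "exclude")))
  expect_equal(seg2$n[seg2$period == "pandemic"], 4)
})

test_that("segments with fewer than three months are skipped with a warning", {
  months <- seq(as.Date("2020-02-01"), by = "month", length.out = 2)
  df <- tibble::tibble(month = months, public_volume = c(1, 2),
                       bc_private = c(1, 2))
  w <- testthat::capture_warnings(
    seg <- segment_regression(df, default_regimes()))
  expect_true(any(grepl("skipped", w)))
  expect_false("pandemic" %in% seg$period)
})
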