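#' Fit a long-run linear trend to a time series
#'
#' Ordinary least squares of the value on days elapsed since the first
#' observation. The per-decade slope uses the exact conversion 3652.5
#' days per decade.
#'
#' @param data Tibble with a `date` column.
#' @param value Name of the value column (default "normalized").
#' @return A `trend_fit` object: slope per day and per decade, intercept,
#'   R², two-sided slope p-value, n, and the underlying `lm` fit.
#' @export
#' @examples
#' df <- tibble::tibble(date = seq(as.Date("2018-01-01"), by = "day",
#'                                 length.out = 100),
#'                      normalized = 5 - 0.0005 * (0:99))
#' tidy(fit_linear_trend(df))
fit_linear_trend <- function(data, value = "normalized") {
  df <- data[!is.na(data[[value]]), ]
  if (nrow(df) < 24) {
    abort(sprintf("Need at least 24 points for a trend fit, got %d.", nrow(df)),
          class = "carbonsplit_insufficient_data_error")
  }
  days <- days_elapsed(df$date)
  if (sd(days) == 0) {
    abort("Degenerate design: all observations share one date.",
          class = "carbonsplit_degenerate_error")
  }
  if (sd(df[[value]]) == 0) {
    # constant series: flat line, nothing explained
    return(structure(list(
      slope_per_day = 0, slope_per_decade = 0,
      intercept = df[[value]][1], r_squared = 0, p_value = 1,
      conf_low_per_decade = 0, conf_high_per_decade = 0,
      n = nrow(df), origin = min(df$date), value = value, fit = NULL),
      class = "trend_fit"))
  }
  fit <- lm(df[[value]] ~ days)
  sm <- summary(fit)
  structure(list(
    slope_per_day = unname(coef(fit)[2]),
    slope_per_decade = unname(coef(fit)[2]) * 3652.5,
    intercept = unname(coef(fit)[1]),
    r_squared = sm$r.squared,
    p_value = sm$coefficients[2, 4],
    conf_low_per_decade = stats::confint(fit)[2, 1] * 3652.5,
    conf_high_per_decade = stats::confint(fit)[2, 2] * 3652.5,
    n = nrow(df), origin = min(df$date), value = value, fit = fit),
    class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf(
    "<trend_fit> slope = %.4g ug/m3 per decade (R^2 = %.2f, p = %.3g, n = %d)\n",
    x$slope_per_decade, x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' @export
tidy.trend_fit <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope_per_day", "slope_per_decade"),
    estimate = c(x$intercept, x$slope_per_day, x$slope_per_decade))
}

#' @export
glance.trend_fit <- function(x, ...) {
  tibble::tibble(slope_per_decade = x$slope_per_decade,
                 r_squared = x$r_squared, p_value = x$p_value,
                 conf_low_per_decade = x$conf_low_per_decade,
                 conf_high_per_decade = x$conf_high_per_decade, n = x$n)
}

#' Remove a fitted linear trend from a series
#'
#' Subtracts the trend line, yielding signed anomalies around zero, and a
#' recentered variant that adds back the whole-record mean so the series
#' can feed level-based analyses while staying trend-free.
#'
#' @param data Tibble with `date` and the value column.
#' @param value Value column name.
#' @param trend Optional pre-computed [fit_linear_trend()]; fitted from
#'   `data` when `NULL`.
#' @return `data` plus `anomaly` and `recentered` columns.
#' @export
detrend <- function(data, value = "normalized", trend = NULL) {
  if (is.null(trend)) trend <- fit_linear_trend(data, value)
  days <- as.numeric(data$date - trend$origin)
  line <- trend$intercept + trend$slope_per_day * days
  out <- data
  out$anomaly <- data[[value]] - line
  out$recentered <- out$anomaly + mean(data[[value]], na.rm = TRUE)
  out
}

#' Per-calendar-month baseline from designated baseline periods
#'
#' For every calendar month, the baseline is the mean of the series over
#' the baseline-flagged periods only; observations outside those periods
#' never enter the baseline. A missing calendar month yields a warning and
#' an NA baseline.
#'
#' @param data Tibble with `date` and the value column.
#' @param periods Validated period tibble with a `baseline` flag.
#' @param value Value column name.
#' @return A tibble `month` (1--12), `baseline`; the whole-baseline mean
#'   is attached as attribute `overall`.
#' @export
compute_baseline <- function(data, periods, value = "normalized") {
  base_p <- periods[periods$baseline, , drop = FALSE]
  if (nrow(base_p) == 0) {
    abort("No baseline-flagged period supplied.",
          class = "carbonsplit_config_error")
  }
  in_base <- rep(FALSE, nrow(data))
  for (i in seq_len(nrow(base_p))) {
    in_base <- in_base | (data$date >= base_p$start[i] &
                            data$date <= base_p$end[i])
  }
  bd <- data[in_base & !is.na(data[[value]]), ]
  got_months <- sort(unique(as.numeric(format(bd$date, "%m"))))
  if (length(got_months) < 12) {
    warn(sprintf("Baseline data covers only %d calendar months; others are NA.",
                 length(got_months)))
  }
  monthly <- bd |>
    dplyr::mutate(month = as.numeric(format(.data$date, "%m"))) |>
    dplyr::group_by(month = .data$month) |>
    dplyr::summarise(baseline = mean(.data[[value]]), .groups = "drop")
  out <- dplyr::left_join(tibble::tibble(month = 1:12), monthly, by = "month")
  attr(out, "overall") <- mean(bd[[value]])
  out
}
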