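#' Day-of-week statistics of daily metro volumes
#'
#' Per-weekday arithmetic mean and population (n-denominator) standard
#' deviation, rounded half-away-from-zero at two decimals -- the
#' conventions under which published daily-variation tables reproduce
#' exactly -- plus pooled workday (Mon--Fri) and weekend (Sat--Sun)
#' statistics and a two-sided Welch t-test between the two groups on the
#' unrounded values. Missing cells are excluded, never imputed.
#'
#' @param daily Tibble with `volume` (million passengers/day) and either
#'   `date` or `weekday` ("Monday" ... "Sunday").
#' @return A `dow_stats` object: `$by_day` tibble, `$workday` and
#'   `$weekend` summaries, `$t_statistic`, `$p_value`.
#' @export
#' @examples
#' tidy(day_of_week_stats(metro_daily_table()))
day_of_week_stats <- function(daily) {
  wd_levels <- c("Monday", "Tuesday", "Wednesday", "Thursday", "Friday",
                 "Saturday", "Sunday")
  df <- tibble::as_tibble(daily)
  if (!"weekday" %in% names(df)) {
    if (!"date" %in% names(df)) {
      abort("Need a `date` or `weekday` column.",
            class = "carbonsplit_schema_error")
    }
    df$weekday <- weekdays(as.Date(df$date))
  }
  df <- df[!is.na(df$volume), ]
  df$weekday <- factor(df$weekday, levels = wd_levels)
  if (anyNA(df$weekday)) {
    abort("Unrecognized weekday labels.", class = "carbonsplit_schema_error")
  }
  by_day <- df |>
    dplyr::group_by(weekday = .data$weekday) |>
    dplyr::summarise(n = dplyr::n(),
                     mean = round_half_away(mean(.data$volume)),
                     sd = round_half_away(sd_pop(.data$volume)),
                     .groups = "drop")
  workday_v <- df$volume[df$weekday %in% wd_levels[1:5]]
  weekend_v <- df$volume[df$weekday %in% wd_levels[6:7]]
  if (length(workday_v) < 2 || length(weekend_v) < 2) {
    abort("Need at least 2 observations in each of workday and weekend groups.",
          class = "carbonsplit_insufficient_data_error")
  }
  if (sd(workday_v) == 0 && sd(weekend_v) == 0) {
    # degenerate: Welch statistic undefined; equal constants are maximally
    # indistinguishable
    tt <- list(statistic = c(t = 0),
               p.value = if (mean(workday_v) == mean(weekend_v)) 1 else 0)
  } else {
    tt <- t.test(workday_v, weekend_v, var.equal = FALSE)
  }
  structure(list(
    by_day = by_day,
    workday = c(n = length(workday_v),
                mean = round_half_away(mean(workday_v)),
                sd = round_half_away(sd_pop(workday_v))),
    weekend = c(n = length(weekend_v),
                mean = round_half_away(mean(weekend_v)),
                sd = round_half_away(sd_pop(weekend_v))),
    t_statistic = unname(tt$statistic),
    p_value = tt$p.value),
    class = "dow_stats")
}

#' @export
print.dow_stats <- function(x, ...) {
  print(x$by_day)
  cat(sprintf("workday %.2f (sd %.2f, n %d) vs weekend %.2f (sd %.2f, n %d)\n",
              x$workday["mean"], x$workday["sd"], x$workday["n"],
              x$weekend["mean"], x$weekend["sd"], x$weekend["n"]))
  cat(sprintf("Welch t = %.3f, two-sided p = %.3f\n", x$t_statistic, x$p_value))
  invisible(x)
}

#' @export
tidy.dow_stats <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$by_day, group = as.character(.data$weekday)) |>
      dplyr::select("group", "n", "mean", "sd"),
    tibble::tibble(group = c("workday", "weekend"),
                   n = c(x$workday["n"], x$weekend["n"]),
                   mean = c(x$workday["mean"], x$weekend["mean"]),
                   sd = c(x$workday["sd"], x$weekend["sd"])))
}

#' @export
glance.dow_stats <- function(x, ...) {
  tibble::tibble(t_statistic = x$t_statistic, p_value = x$p_value,
                 n_workday = x$workday["n"], n_weekend = x$weekend["n"])
}

#' Published daily metro volumes (45 values, late Nov 2022 -- early Jan 2023)
#'
#' The worked-example table of daily metro passenger volumes by weekday
#' and week, shipped as plain text under `extdata`. Volumes are in
#' million passengers per day.
#'
#' @return A tibble with `weekday`, `week`, `volume`.
#' @export
metro_daily_table <- function() {
  path <- system.file("extdata", "metro_daily_table.csv",
                      package = "carbonsplit", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Percent change of transport volumes against a matched-month baseline
#'
#' For every non-baseline period, each month's volume is divided by the
#' baseline value of the same calendar month (computed from the
#' baseline-flagged periods only) and the percent change is
#' `100 * (mean(ratio) - 1)`; negative means a decrease. The measure is
#' scale-invariant.
#'
#' @param monthly Long tibble with `month` (Date, first of month), `mode`
#'   and `volume`.
#' @param periods Validated period tibble ([load_periods()]).
#' @return A `percent_change` tibble: `period`, `mode`, `percent_change`,
#'   `n_months`.
#' @export
percent_change <- function(monthly, periods) {
  stopifnot(all(c("month", "mode", "volume") %in% names(monthly)))
  monthly <- dplyr::mutate(monthly, calmonth = as.numeric(format(.data$month, "%m")))
  base_p <- periods[periods$baseline, , drop = FALSE]
  in_base <- rep(FALSE, nrow(monthly))
  for (i in seq_len(nrow(base_p))) {
    in_base <- in_base | (monthly$month >= base_p$start[i] &
                            monthly$month <= base_p$end[i])
  }
  baseline <- monthly[in_base, ] |>
    dplyr::group_by(mode = .data$mode, calmonth = .data$calmonth) |>
    dplyr::summarise(baseline = mean(.data$volume, na.rm = TRUE),
                     .groups = "drop")
  target_p <- periods[!periods$baseline, , drop = FALSE]
  res <- list()
  for (i in seq_len(nrow(target_p))) {
    sel <- monthly$month >= target_p$start[i] & monthly$month <= target_p$end[i]
    sub <- dplyr::inner_join(monthly[sel, ], baseline,
                             by = c("mode", "calmonth"))
    if (anyNA(sub$baseline) || nrow(sub) == 0) {
      abort(sprintf("Missing matched-month baseline for period '%s'.",
                    target_p$name[i]),
            class = "carbonsplit_baseline_error")
    }
    res[[i]] <- sub |>
      dplyr::group_by(mode = .data$mode) |>
      dplyr::summarise(
        period = target_p$name[i],
        percent_change = 100 * (mean(.data$volume / .data$baseline) - 1),
        n_months = dplyr::n(), .groups = "drop")
  }
  out <- dplyr::bind_rows(res)[, c("period", "mode", "percent_change", "n_months")]
  class(out) <- c("percent_change", class(out))
  out
}

#' Regime-wise regression of private-transport emission on public volume
#'
#' OLS of monthly transport-attributed black carbon on monthly
#' public-transport passenger volume, fit separately inside each named
#' period; no pooling across period boundaries. Months whose regime is
#' ambiguous can be reassigned (or excluded) via `overrides`.
#'
#' @param monthly Tibble with `month` (Date), `bc_private` (µg/m³) and
#'   `public_volume` (million passengers/month).
#' @param periods Period tibble with `name`, `start`, `end` (for example
#'   [default_regimes()]).
#' @param overrides Named character vector mapping "YYYY-MM" months to a
#'   period name, or to `"exclude"` to drop them.
#' @return A `segment_regression` tibble: one row per period with `slope`
#'   (µg/m³ per million passengers), `intercept`, `r_squared`, `p_value`,
#'   `conf_low`, `conf_high`, `n`.
#' @export
segment_regression <- function(monthly, periods = default_regimes(),
                               overrides = NULL) {
  stopifnot(all(c("month", "bc_private", "public_volume") %in% names(monthly)))
  df <- tibble::as_tibble(monthly)
  df$period <- period_of(df$month, periods)
  if (!is.null(overrides)) {
    key <- format(df$month, "%Y-%m")
    hit <- key %in% names(overrides)
    df$period[hit] <- unname(overrides[key[hit]])
    df <- df[is.na(df$period) | df$period != "exclude", ]
  }
  df <- df[!is.na(df$period) & !is.na(df$bc_private) &
             !is.na(df$public_volume), ]
  res <- list()
  for (nm in unique(periods$name)) {
    sub <- df[df$period == nm, ]
    if (nrow(sub) < 3) {
      warn(sprintf("Period '%s' has %d aligned months (< 3); skipped.",
                   nm, nrow(sub)))
      next
    }
    fit <- lm(bc_private ~ public_volume, data = sub)
    sm <- summary(fit)
    ci <- stats::confint(fit)
    res[[nm]] <- tibble::tibble(
      period = nm,
      slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
      r_squared = sm$r.squared,
      p_value = sm$coefficients[2, 4],
      conf_low = ci[2, 1], conf_high = ci[2, 2],
      n = nrow(sub))
  }
  empty <- tibble::tibble(
    period = character(), slope = numeric(), intercept = numeric(),
    r_squared = numeric(), p_value = numeric(), conf_low = numeric(),
    conf_high = numeric(), n = integer())
  out <- dplyr::bind_rows(c(list(empty), unname(res)))
  class(out) <- c("segment_regression", class(out))
  out
}
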