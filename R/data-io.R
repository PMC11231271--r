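#' Read and validate a daily pollutant table
#'
#' Expects a CSV with columns `date`, `BC`, `NO3`, `SO4`. Unparseable or
#' negative concentration cells become missing (with a message reporting
#' how many); duplicate or out-of-order dates are rejected rather than
#' silently repaired, because all downstream joins are by calendar date.
#'
#' @param path Path to a CSV file.
#' @return A tibble with `date` (Date) and numeric `BC`, `NO3`, `SO4`.
#' @export
read_pollutants <- function(path) {
  raw <- read_checked_csv(path, required = c("date", "BC", "NO3", "SO4"),
                          what = "pollutant table")
  out <- tibble::tibble(date = parse_iso_date(raw$date, path))
  check_dates(out$date, "pollutant table")
  n_bad <- 0L
  for (col in c("BC", "NO3", "SO4")) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- (!is.na(raw[[col]]) & is.na(v)) | (!is.na(v) & v < 0)
    v[bad] <- NA_real_
    n_bad <- n_bad + sum(bad)
    out[[col]] <- v
  }
  if (n_bad > 0) {
    inform(sprintf("read_pollutants: %d unparseable or negative cells set to missing.",
                   n_bad))
  }
  out
}

#' Write a pollutant table to CSV
#' @param x Pollutant tibble.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pollutants <- function(x, path) {
  utils::write.csv(x[, c("date", "BC", "NO3", "SO4")], path, row.names = FALSE)
  invisible(path)
}

MET_VARS <- c("U10", "V10", "D2M", "T2M", "BLH", "MBLD", "SP", "TP")

#' Read a daily meteorology table
#'
#' Two layouts are supported. `variant = "csv"` is a daily table with a
#' `date` column plus the eight meteorology variables, validated and passed
#' through. `variant = "grid"` is a long-format gridded table with `lon`,
#' `lat`, `date` and the same variables: cells falling inside `bbox` are
#' averaged per day, replacing shapefile-based spatial cropping with a
#' bounding-box reduction.
#'
#' @param path CSV path.
#' @param variant `"csv"` (daily) or `"grid"` (lon/lat/day long format).
#' @param bbox For the grid variant, numeric `c(lon_min, lon_max, lat_min,
#'   lat_max)`; `NULL` keeps every cell.
#' @return A tibble with `date` and columns U10, V10, D2M, T2M, BLH, MBLD,
#'   SP, TP.
#' @export
read_meteorology <- function(path, variant = c("csv", "grid"), bbox = NULL) {
  variant <- match.arg(variant)
  if (variant == "csv") {
    raw <- read_checked_csv(path, required = c("date", MET_VARS),
                            what = "meteorology table")
    out <- tibble::tibble(date = parse_iso_date(raw$date, path))
    for (v in MET_VARS) out[[v]] <- as.numeric(raw[[v]])
    check_dates(out$date, "meteorology table")
    validate_meteorology(out)
    return(out)
  }
  raw <- read_checked_csv(path, required = c("lon", "lat", "date", MET_VARS),
                          what = "gridded meteorology table")
  raw$date <- parse_iso_date(raw$date, path)
  if (!is.null(bbox)) {
    stopifnot(length(bbox) == 4)
    raw <- raw[raw$lon >= bbox[1] & raw$lon <= bbox[2] &
                 raw$lat >= bbox[3] & raw$lat <= bbox[4], ]
    if (nrow(raw) == 0) {
      abort("Bounding box selects no grid cells.",
            class = "carbonsplit_spatial_error")
    }
  }
  out <- raw |>
    dplyr::group_by(date = .data$date) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(MET_VARS), mean),
                     .groups = "drop") |>
    dplyr::arrange(.data$date)
  validate_meteorology(out)
  out
}

validate_meteorology <- function(met) {
  ok <- stats::complete.cases(met[, MET_VARS])
  if (any(met$BLH[ok] <= 0) || any(met$SP[ok] <= 0) || any(met$TP[ok] < 0)) {
    abort("Meteorology violates physical bounds (BLH > 0, SP > 0, TP >= 0).",
          class = "carbonsplit_integrity_error")
  }
  invisible(met)
}

#' Write a meteorology table to CSV
#' @param x Meteorology tibble.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_meteorology <- function(x, path) {
  utils::write.csv(x[, c("date", MET_VARS)], path, row.names = FALSE)
  invisible(path)
}

#' Read monthly transport volumes
#'
#' @param path CSV with columns `month` (first day of month, ISO) and one
#'   or more of `bus_volume`, `metro_volume`, `taxi_volume`,
#'   `public_volume` in million passengers per month.
#' @return A tibble keyed by `month`.
#' @export
read_monthly_volumes <- function(path) {
  raw <- read_checked_csv(path, required = "month", what = "monthly volumes")
  out <- tibble::as_tibble(raw)
  out$month <- parse_iso_date(out$month, path)
  if (anyDuplicated(out$month)) {
    abort("Duplicate months in monthly volume table.",
          class = "carbonsplit_integrity_error")
  }
  vol_cols <- setdiff(names(out), "month")
  for (v in vol_cols) {
    out[[v]] <- as.numeric(out[[v]])
    if (any(out[[v]] < 0, na.rm = TRUE)) {
      abort("Transport volumes must be nonnegative.",
            class = "carbonsplit_integrity_error")
    }
  }
  dplyr::arrange(out, .data$month)
}

#' Read daily metro volumes
#'
#' Accepts either a `date` column (weekday derived from it) or an explicit
#' `weekday` column (`Monday` ... `Sunday`), plus `volume` in million
#' passengers/day.
#'
#' @param path CSV path.
#' @return A tibble with `weekday` (and `date` when present) and `volume`.
#' @export
read_daily_metro <- function(path) {
  raw <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  if (!"volume" %in% names(raw)) {
    abort("Daily metro table must contain a `volume` column.",
          class = "carbonsplit_schema_error")
  }
  if (!("date" %in% names(raw) || "weekday" %in% names(raw))) {
    abort("Daily metro table must contain `date` or `weekday`.",
          class = "carbonsplit_schema_error")
  }
  if ("date" %in% names(raw)) raw$date <- parse_iso_date(raw$date, path)
  raw$volume <- as.numeric(raw$volume)
  if (any(raw$volume < 0, na.rm = TRUE)) {
    abort("Metro volumes must be nonnegative.",
          class = "carbonsplit_integrity_error")
  }
  raw
}

#' Read daily epidemic covariates
#' @param path CSV with `date`, `cases`, `transmission`, `fatality`,
#'   `period` (and optionally `variant`).
#' @return A validated tibble, one row per day.
#' @export
read_epidemic <- function(path) {
  raw <- read_checked_csv(path,
                          required = c("date", "cases", "transmission",
                                       "fatality", "period"),
                          what = "epidemic table")
  out <- tibble::as_tibble(raw)
  out$date <- parse_iso_date(out$date, path)
  check_dates(out$date, "epidemic table")
  out$cases <- as.numeric(out$cases)
  if (any(out$cases < 0, na.rm = TRUE)) {
    abort("Case counts must be nonnegative.",
          class = "carbonsplit_integrity_error")
  }
  out
}

#' Analysis period definitions
#'
#' Validates a set of named, non-overlapping calendar periods, at least one
#' of which is flagged as the pre-pandemic baseline. The default set covers
#' a 2018--2019 baseline, three outbreak windows (the first anchored at
#' February--May 2020), a recovery phase and a post period.
#'
#' @param periods A data frame (or path to a YAML file with a `periods`
#'   section) with columns `name`, `start`, `end`, `baseline`.
#' @return A validated tibble ordered by `start`.
#' @export
#' @examples
#' load_periods(default_periods())
load_periods <- function(periods = default_periods()) {
  if (is.character(periods) && length(periods) == 1) {
    cfg <- yaml::read_yaml(periods)
    periods <- dplyr::bind_rows(lapply(cfg$periods, tibble::as_tibble))
  }
  p <- tibble::as_tibble(periods)
  need <- c("name", "start", "end")
  miss <- setdiff(need, names(p))
  if (length(miss)) {
    abort(paste0("Period definition lacks column(s): ",
                 paste(miss, collapse = ", ")),
          class = "carbonsplit_config_error")
  }
  p$start <- as.Date(p$start)
  p$end <- as.Date(p$end)
  if (is.null(p$baseline)) p$baseline <- FALSE
  p$baseline <- as.logical(p$baseline)
  if (any(p$start > p$end)) {
    abort("Every period must have start <= end.",
          class = "carbonsplit_config_error")
  }
  p <- dplyr::arrange(p, .data$start)
  if (nrow(p) > 1) {
    for (i in seq_len(nrow(p) - 1)) {
      if (p$end[i] >= p$start[i + 1]) {
        abort(sprintf("Periods '%s' and '%s' overlap.",
                      p$name[i], p$name[i + 1]),
              class = "carbonsplit_config_error")
      }
    }
  }
  if (!any(p$baseline)) {
    abort("At least one baseline period is required.",
          class = "carbonsplit_config_error")
  }
  p
}

#' @rdname load_periods
#' @export
default_periods <- function() {
  tibble::tibble(
    name = c("pre", "alpha", "delta", "omicron", "recovery", "post"),
    start = as.Date(c("2018-01-01", "2020-02-01", "2021-07-01",
                      "2022-11-01", "2023-01-01", "2023-07-01")),
    end = as.Date(c("2019-12-31", "2020-05-31", "2021-08-31",
                    "2022-12-31", "2023-06-30", "2023-12-31")),
    baseline = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
}

#' Coupling-regime periods for segment regressions
#'
#' Pre / pandemic / post spans used when regressing private-transport
#' emission on public-transport volume. January 2020 (reported cases
#' elsewhere but none locally) sits in `pre` by default; move it with the
#' `overrides` argument of [segment_regression()].
#'
#' @return A tibble with `name`, `start`, `end`.
#' @export
default_regimes <- function() {
  tibble::tibble(
    name = c("pre", "pandemic", "post"),
    start = as.Date(c("2018-01-01", "2020-02-01", "2023-01-01")),
    end = as.Date(c("2020-01-31", "2022-12-31", "2023-12-31")),
    baseline = c(TRUE, FALSE, FALSE))
}

#' Assign each date to a named period
#' @param date Date vector.
#' @param periods Validated period tibble.
#' @return Character vector of period names (NA outside all periods).
#' @export
period_of <- function(date, periods) {
  out <- rep(NA_character_, length(date))
  for (i in seq_len(nrow(periods))) {
    out[date >= periods$start[i] & date <= periods$end[i]] <- periods$name[i]
  }
  out
}

## internal helpers -----------------------------------------------------

read_checked_csv <- function(path, required, what) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "carbonsplit_io_error")
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(required, names(raw))
  if (length(miss)) {
    abort(sprintf("%s at '%s' lacks required column(s): %s",
                  what, path, paste(miss, collapse = ", ")),
          class = "carbonsplit_schema_error")
  }
  tibble::as_tibble(raw)
}

parse_iso_date <- function(x, path) {
  d <- as.Date(x, format = "%Y-%m-%d")
  if (anyNA(d) && !anyNA(x)) {
    abort(sprintf("Unparseable ISO dates in '%s'.", path),
          class = "carbonsplit_schema_error")
  }
  d
}
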