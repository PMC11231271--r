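#' Fit the meteorology--emission regression forest for one pollutant
#'
#' Models a daily pollutant concentration as a non-linear function of time
#' features (`year`, `month`, and `whole`, the number of days since the
#' first observation, which jointly stand in for slowly varying local
#' emission) plus the eight meteorology variables. The forest is the
#' engine behind weather normalization: averaging its predictions over
#' resampled meteorology removes dispersion-driven variability while the
#' time features preserve the emission signal.
#'
#' @param pollutants Daily pollutant tibble (`date` plus concentration
#'   columns).
#' @param met Daily meteorology tibble (`date` plus U10 ... TP).
#' @param species Which pollutant column to model ("BC", "NO3" or "SO4").
#' @param seed Integer seed; fits are deterministic given it.
#' @param num_trees,min_node_size Forest size and leaf size. Defaults (300
#'   trees, leaves of 5) suit daily records of a few thousand rows.
#' @param use_dow Also include day-of-week as a feature (off by default:
#'   the time features are year, month and the continuous trend term).
#' @return An object of class `met_model` holding the fitted forest, the
#'   feature list, out-of-bag R² and RMSE, and the training table used as
#'   the meteorology resampling pool.
#' @export
#' @examples
#' scn <- simulate_scenario(synthetic_config(n_days = 730, outbreak_windows = NULL))
#' m <- fit_met_model(scn$pollutants, scn$met, "BC", seed = 1)
#' glance(m)
fit_met_model <- function(pollutants, met, species = "BC", seed = 1L,
                          num_trees = 300, min_node_size = 5,
                          use_dow = FALSE) {
  if (!species %in% names(pollutants)) {
    abort(sprintf("Pollutant column '%s' not found.", species),
          class = "carbonsplit_schema_error")
  }
  df <- dplyr::inner_join(
    pollutants[, c("date", species)], met[, c("date", MET_VARS)], by = "date")
  df <- df[stats::complete.cases(df), ]
  if (nrow(df) < 365) {
    abort(sprintf("Need at least 365 complete aligned rows, got %d.", nrow(df)),
          class = "carbonsplit_insufficient_data_error")
  }
  origin <- min(df$date)
  feats <- build_time_features(df$date, origin, use_dow)
  train <- dplyr::bind_cols(feats, df[, MET_VARS])
  train$.y <- df[[species]]
  feature_names <- setdiff(names(train), ".y")
  forest <- ranger::ranger(
    dependent.variable.name = ".y", data = as.data.frame(train),
    num.trees = num_trees, min.node.size = min_node_size,
    seed = substream_seed(seed, paste0("fit.", species)),
    num.threads = 1, oob.error = TRUE)
  oob_pred <- forest$predictions
  structure(list(
    forest = forest, species = species, features = feature_names,
    met_vars = MET_VARS, origin = origin, use_dow = use_dow, seed = seed,
    num_trees = num_trees, min_node_size = min_node_size,
    oob_r2 = forest$r.squared,
    oob_rmse = sqrt(mean((oob_pred - train$.y)^2)),
    training = dplyr::bind_cols(tibble::tibble(date = df$date), train)),
    class = "met_model")
}

build_time_features <- function(date, origin, use_dow = FALSE) {
  out <- tibble::tibble(
    year = as.numeric(format(date, "%Y")),
    month = as.numeric(format(date, "%m")),
    whole = as.numeric(date - origin))
  if (use_dow) out$dow <- lubridate::wday(date, week_start = 1)
  out
}

#' @export
print.met_model <- function(x, ...) {
  cat(sprintf("<met_model> %s: %d trees, OOB R^2 = %.3f, OOB RMSE = %.3f\n",
              x$species, x$num_trees, x$oob_r2, x$oob_rmse))
  invisible(x)
}

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics tidy
#' @export
generics::tidy

#' @export
glance.met_model <- function(x, ...) {
  tibble::tibble(species = x$species, oob_r2 = x$oob_r2,
                 oob_rmse = x$oob_rmse, num_trees = x$num_trees,
                 n = nrow(x$training))
}

#' Weather-normalize a pollutant series by meteorology resampling
#'
#' For every date, the meteorology columns are replaced `n_samples` times
#' by complete meteorology rows drawn uniformly with replacement from the
#' full training record (rows are resampled jointly to preserve
#' inter-variable covariance), the time features keep their observed
#' values, and the forest predicts each counterfactual. The normalized
#' value is the mean of those predictions and `mc_sd` their standard
#' deviation (zero when `n_samples` is 1).
#'
#' @param model A [fit_met_model()] result.
#' @param data Optional tibble with `date` plus the model's feature
#'   columns; defaults to the model's training table.
#' @param n_samples Number of meteorology resamples per date (>= 1).
#' @param seed Integer seed for the resampling stream.
#' @return A `normalization_result` tibble: `date`, `observed`,
#'   `normalized`, `mc_sd`, `n_samples`.
#' @export
normalize_pollutant <- function(model, data = NULL, n_samples = 200,
                                seed = 1L) {
  stopifnot(inherits(model, "met_model"))
  if (n_samples < 1) {
    abort("`n_samples` must be at least 1.", class = "carbonsplit_config_error")
  }
  if (is.null(data)) data <- model$training
  if (!"date" %in% names(data)) {
    abort("Data must carry a `date` column matching the model's features.",
          class = "carbonsplit_feature_error")
  }
  dates <- data$date
  n <- length(dates)
  feats <- build_time_features(dates, model$origin, model$use_dow)
  pool <- model$training[, model$met_vars]
  set.seed(substream_seed(seed, paste0("normalize.", model$species)))
  idx <- sample.int(nrow(pool), n * n_samples, replace = TRUE)
  big <- dplyr::bind_cols(
    feats[rep(seq_len(n), times = n_samples), ],
    pool[idx, ])
  pred <- predict(model$forest, data = as.data.frame(big),
                  num.threads = 1)$predictions
  pm <- matrix(pred, nrow = n, ncol = n_samples)
  observed <- if (model$species %in% names(data)) {
    data[[model$species]]
  } else if (".y" %in% names(data)) {
    data$.y
  } else {
    rep(NA_real_, n)
  }
  out <- tibble::tibble(
    date = dates,
    observed = observed,
    normalized = rowMeans(pm),
    mc_sd = if (n_samples > 1) apply(pm, 1, sd) else rep(0, n),
    n_samples = n_samples)
  class(out) <- c("normalization_result", class(out))
  out
}

#' Refit-level uncertainty of the normalization
#'
#' Repeats the fit + normalization with `n_repeats` distinct seeds and
#' returns a per-date envelope (min, max, sd across repeats), the
#' algorithmic uncertainty band drawn around normalized trends.
#'
#' @inheritParams fit_met_model
#' @param n_repeats Number of independent refits (>= 2).
#' @param n_samples Resamples per date in each repeat.
#' @param seed Master seed; repeat `i` uses the substream `uncert.i`.
#' @param seeds Optional explicit per-repeat seed vector overriding the
#'   substreams (repeats with equal seeds collapse to a zero-width band).
#' @return A tibble `date`, `mean`, `min`, `max`, `sd` plus a `repeats`
#'   attribute with the per-repeat normalized matrix.
#' @export
normalization_uncertainty <- function(pollutants, met, species = "BC",
                                      n_repeats = 10, n_samples = 200,
                                      seed = 1L, num_trees = 300,
                                      min_node_size = 5, seeds = NULL) {
  if (n_repeats < 2) {
    abort("`n_repeats` must be at least 2.", class = "carbonsplit_config_error")
  }
  if (!is.null(seeds) && length(seeds) != n_repeats) {
    abort("`seeds` must have length `n_repeats`.",
          class = "carbonsplit_config_error")
  }
  runs <- lapply(seq_len(n_repeats), function(i) {
    s <- if (is.null(seeds)) substream_seed(seed, paste0("uncert.", i)) else seeds[i]
    m <- fit_met_model(pollutants, met, species, seed = s,
                       num_trees = num_trees, min_node_size = min_node_size)
    normalize_pollutant(m, n_samples = n_samples, seed = s)
  })
  mat <- vapply(runs, function(r) r$normalized, numeric(nrow(runs[[1]])))
  out <- tibble::tibble(
    date = runs[[1]]$date,
    mean = rowMeans(mat),
    min = apply(mat, 1, min),
    max = apply(mat, 1, max),
    sd = apply(mat, 1, sd))
  attr(out, "repeats") <- mat
  out
}

#' Aggregate a daily series to weekly or monthly means
#'
#' @param data Tibble with a `date` column.
#' @param value Name of the value column to aggregate.
#' @param granularity `"monthly"` or `"weekly"`.
#' @return A tibble with `date` (period start) and the aggregated column.
#' @export
aggregate_series <- function(data, value, granularity = c("monthly", "weekly")) {
  granularity <- match.arg(granularity)
  key <- if (granularity == "monthly") month_start(data$date) else week_start(data$date)
  data |>
    dplyr::mutate(.key = key) |>
    dplyr::group_by(date = .data$.key) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(value),
                                   ~ mean(.x, na.rm = TRUE)),
                     .groups = "drop") |>
    dplyr::arrange(.data$date)
}
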