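#' Build the monthly panel joining emissions, volumes, weather and epidemic
#'
#' One row per month: meteorology summaries (means, except precipitation
#' which is summed -- totals drive travel behaviour, the rest are state
#' variables), the share of legal-vacation days, the month's maximum
#' ordinal transmission and fatality ranks (zero outside outbreaks),
#' summed case counts, mean transport-attributed black carbon and the
#' monthly transport volumes.
#'
#' @param source_split Daily [attribute_sources()] result (or any tibble
#'   with `date` and `bc_transport`).
#' @param monthly_volumes Tibble with `month` and volume columns.
#' @param met Daily meteorology tibble.
#' @param epidemic Daily epidemic covariate tibble.
#' @return A monthly panel tibble.
#' @export
build_monthly_panel <- function(source_split, monthly_volumes, met, epidemic) {
  bc_m <- source_split |>
    dplyr::group_by(month = month_start(.data$date)) |>
    dplyr::summarise(bc_private = mean(.data$bc_transport, na.rm = TRUE),
                     .groups = "drop")
  met_m <- met |>
    dplyr::group_by(month = month_start(.data$date)) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(setdiff(MET_VARS, "TP")), mean),
      TP = sum(.data$TP), .groups = "drop")
  epi_m <- epidemic |>
    dplyr::group_by(month = month_start(.data$date)) |>
    dplyr::summarise(
      period_share = mean(.data$period == "legal-vacation"),
      transmission = max(.data$transmission, 0),
      fatality = max(.data$fatality, 0),
      cases = sum(.data$cases), .groups = "drop")
  panel <- bc_m |>
    dplyr::inner_join(met_m, by = "month") |>
    dplyr::inner_join(epi_m, by = "month") |>
    dplyr::inner_join(monthly_volumes, by = "month") |>
    dplyr::arrange(.data$month)
  if (nrow(panel) == 0) {
    abort("Inputs share no overlapping months.",
          class = "carbonsplit_alignment_error")
  }
  panel
}

#' Default feature set of the epidemic-response model
#'
#' Monthly meteorology summaries plus the vacation-day share, ordinal
#' transmission/fatality ranks and summed case counts.
#' @export
RESPONSE_FEATURES <- c("U10", "V10", "D2M", "T2M", "BLH", "MBLD", "SP", "TP",
                       "period_share", "transmission", "fatality", "cases")

#' Fit the epidemic-response forest on the monthly panel
#'
#' Regression forest of a monthly response -- transport-attributed black
#' carbon (the private-transport proxy) or a public-transport volume --
#' on weather summaries, the vacation share, ordinal virus properties and
#' case counts.
#'
#' @param panel A [build_monthly_panel()] result.
#' @param target One of `"bc_private"`, `"bus_volume"`, `"metro_volume"`
#'   (any numeric panel column is accepted).
#' @param seed Integer seed.
#' @param num_trees,min_node_size,mtry Forest hyperparameters.
#' @param max_depth,splitrule,num_random_splits Tree regularization.
#'   Monthly panels are small (a few dozen rows), so the default is a
#'   shallow extremely-randomized forest (depth 3, one random split per
#'   candidate): it keeps partial-dependence curves from chasing
#'   idiosyncratic splits on weak features while preserving the strong
#'   epidemic signals.
#' @param features Feature columns; defaults to the met summaries plus
#'   `period_share`, `transmission`, `fatality`, `cases`.
#' @return A `response_model` with the forest and OOB diagnostics.
#' @export
fit_response_model <- function(panel, target = "bc_private", seed = 1L,
                               num_trees = 1000, min_node_size = 5,
                               mtry = NULL, max_depth = 3,
                               splitrule = "extratrees",
                               num_random_splits = 1,
                               features = RESPONSE_FEATURES) {
  if (!target %in% names(panel)) {
    abort(sprintf("Target '%s' not in panel.", target),
          class = "carbonsplit_feature_error")
  }
  miss <- setdiff(features, names(panel))
  if (length(miss)) {
    abort(paste0("Panel lacks feature column(s): ",
                 paste(miss, collapse = ", ")),
          class = "carbonsplit_feature_error")
  }
  df <- panel[stats::complete.cases(panel[, c(target, features)]), ]
  if (nrow(df) < 36) {
    abort(sprintf("Need at least 36 panel rows, got %d.", nrow(df)),
          class = "carbonsplit_insufficient_data_error")
  }
  train <- as.data.frame(df[, c(target, features)])
  names(train)[1] <- ".y"
  forest <- ranger::ranger(
    dependent.variable.name = ".y", data = train,
    num.trees = num_trees, min.node.size = min_node_size,
    mtry = mtry, max.depth = max_depth, splitrule = splitrule,
    num.random.splits = num_random_splits,
    seed = substream_seed(seed, paste0("respond.", target)),
    num.threads = 1, oob.error = TRUE)
  structure(list(
    forest = forest, predict_fn = NULL, target = target,
    features = features, panel = df, seed = seed,
    num_trees = num_trees, min_node_size = min_node_size, mtry = mtry,
    max_depth = max_depth, splitrule = splitrule,
    num_random_splits = num_random_splits,
    oob_r2 = forest$r.squared,
    oob_rmse = sqrt(forest$prediction.error)),
    class = "response_model")
}

# Stub constructor for tests: `fun(newdata)` plays the fitted forest.
new_response_stub <- function(fun, panel, features = RESPONSE_FEATURES,
                              target = "bc_private") {
  structure(list(forest = NULL, predict_fn = fun, target = target,
                 features = features, panel = panel, seed = NA_integer_,
                 num_trees = NA, min_node_size = NA, mtry = NULL,
                 max_depth = 0, splitrule = "variance",
                 num_random_splits = 1,
                 oob_r2 = NA_real_, oob_rmse = NA_real_),
            class = "response_model")
}

predict_response <- function(model, newdata) {
  if (!is.null(model$predict_fn)) return(model$predict_fn(newdata))
  predict(model$forest, data = as.data.frame(newdata),
          num.threads = 1)$predictions
}

#' @export
print.response_model <- function(x, ...) {
  cat(sprintf("<response_model> %s ~ %d features, OOB R^2 = %.3f\n",
              x$target, length(x$features), x$oob_r2))
  invisible(x)
}

#' @export
glance.response_model <- function(x, ...) {
  tibble::tibble(target = x$target, oob_r2 = x$oob_r2,
                 oob_rmse = x$oob_rmse, n = nrow(x$panel))
}

#' Partial dependence of a response-model feature
#'
#' Standard partial dependence: for each grid value, the feature is forced
#' to that value on every panel row, all other features keep their
#' observed values, and the model's predictions are averaged. The grid is
#' the set of `n_grid` interior quantiles of the observed feature (at
#' probabilities k/(n_grid + 1)), so it stays strictly inside the
#' observed range.
#'
#' @param model A [fit_response_model()] result.
#' @param feature Feature name.
#' @param n_grid Number of grid points (quantiles).
#' @return A `partial_dependence` tibble: `feature`, `value`, `pd`.
#' @export
partial_dependence <- function(model, feature, n_grid = 20) {
  if (!feature %in% model$features) {
    abort(sprintf("Feature '%s' is not in the model.", feature),
          class = "carbonsplit_feature_error")
  }
  obs <- model$panel[[feature]]
  grid <- unique(unname(quantile(obs, probs = seq_len(n_grid) / (n_grid + 1))))
  base <- as.data.frame(model$panel[, model$features])
  pd <- vapply(grid, function(v) {
    nd <- base
    nd[[feature]] <- v
    mean(predict_response(model, nd))
  }, numeric(1))
  out <- tibble::tibble(feature = feature, value = grid, pd = pd)
  class(out) <- c("partial_dependence", class(out))
  out
}

#' Permutation significance test for a response-model feature
#'
#' The observed statistic is the increase in out-of-bag error when the
#' feature's values are permuted (permutation importance). Its null
#' distribution comes from refitting the model `n_permutations` times
#' with the feature's column itself permuted, breaking any link with the
#' response while preserving the feature's marginal distribution. The
#' one-sided p-value is `(1 + #{null >= observed}) / (1 + n_permutations)`.
#'
#' @param model A [fit_response_model()] result.
#' @param feature Feature to test.
#' @param n_permutations Number of null refits (>= 99).
#' @param seed Integer seed.
#' @return A list with `p_value`, `observed`, `null` (the null statistics).
#' @export
feature_effect_test <- function(model, feature, n_permutations = 199,
                                seed = 1L) {
  if (!feature %in% model$features) {
    abort(sprintf("Feature '%s' is not in the model.", feature),
          class = "carbonsplit_feature_error")
  }
  if (n_permutations < 99) {
    abort("`n_permutations` must be at least 99.",
          class = "carbonsplit_config_error")
  }
  importance_of <- function(panel, fit_seed) {
    train <- as.data.frame(panel[, c(model$target, model$features)])
    names(train)[1] <- ".y"
    f <- ranger::ranger(
      dependent.variable.name = ".y", data = train,
      num.trees = model$num_trees, min.node.size = model$min_node_size,
      mtry = model$mtry, max.depth = model$max_depth,
      splitrule = model$splitrule,
      num.random.splits = model$num_random_splits,
      seed = fit_seed, num.threads = 1,
      importance = "permutation")
    unname(f$variable.importance[feature])
  }
  base_seed <- substream_seed(seed, paste0("efftest.", feature))
  observed <- importance_of(model$panel, base_seed)
  set.seed(base_seed)
  null_stats <- vapply(seq_len(n_permutations), function(b) {
    p <- model$panel
    p[[feature]] <- sample(p[[feature]])
    importance_of(p, base_seed + b)
  }, numeric(1))
  p <- (1 + sum(null_stats >= observed)) / (1 + n_permutations)
  list(p_value = p, observed = observed, null = null_stats,
       feature = feature, n_permutations = n_permutations)
}
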