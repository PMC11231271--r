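#' Fit the tracer-based black-carbon attribution model
#'
#' Learns the normalized black-carbon concentration as a non-linear
#' function of the two normalized tracer species: nitrate (co-emitted
#' with transport) and sulfate (co-emitted with factories). The fitted
#' surface is then queried at counterfactual tracer values to split the
#' prediction into transport- and factory-attributed components. The
#' reference value of each tracer is a low quantile of its training
#' record (5th percentile by default): real tracer records never reach
#' zero, and querying a forest far outside its hull is unreliable.
#'
#' @param data Tibble with columns `date`, `BC`, `NO3`, `SO4` holding the
#'   weather-normalized series.
#' @param reference_quantile Quantile of each tracer used as its
#'   "source off" reference value.
#' @param seed Integer seed.
#' @param num_trees,min_node_size Forest hyperparameters.
#' @param transport_tracer,factory_tracer Which column traces which
#'   source (the nitrate-to-transport, sulfate-to-factory mapping is the
#'   default but configurable).
#' @return An `attribution_model` with the forest, references `r_no3`,
#'   `r_so4`, and in-sample fit diagnostics (R², RMSE, best-fit slope).
#' @export
#' @examples
#' scn <- simulate_scenario(synthetic_config(n_days = 730, outbreak_windows = NULL))
#' norm <- scn$pollutants   # stands in for normalized series in examples
#' m <- fit_attribution_model(norm, seed = 1)
#' glance(m)
fit_attribution_model <- function(data, reference_quantile = 0.05, seed = 1L,
                                  num_trees = 300, min_node_size = 5,
                                  transport_tracer = "NO3",
                                  factory_tracer = "SO4") {
  need <- c("BC", transport_tracer, factory_tracer)
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    abort(paste0("Attribution input lacks column(s): ",
                 paste(miss, collapse = ", ")),
          class = "carbonsplit_schema_error")
  }
  df <- data[stats::complete.cases(data[, need]), ]
  if (nrow(df) < 365) {
    abort(sprintf("Need at least 365 aligned rows, got %d.", nrow(df)),
          class = "carbonsplit_insufficient_data_error")
  }
  train <- data.frame(.y = df$BC,
                      no3 = df[[transport_tracer]],
                      so4 = df[[factory_tracer]])
  forest <- ranger::ranger(
    dependent.variable.name = ".y", data = train,
    num.trees = num_trees, min.node.size = min_node_size,
    seed = substream_seed(seed, "attribute"), num.threads = 1,
    oob.error = TRUE)
  # out-of-bag predictions: an in-sample surface would overstate the fit
  diag <- evaluate_fit(forest$predictions, df$BC)
  structure(list(
    forest = forest, predict_fn = NULL,
    r_no3 = unname(quantile(train$no3, reference_quantile)),
    r_so4 = unname(quantile(train$so4, reference_quantile)),
    reference_quantile = reference_quantile,
    transport_tracer = transport_tracer, factory_tracer = factory_tracer,
    range_no3 = range(train$no3), range_so4 = range(train$so4),
    r_squared = diag$r_squared, rmse = diag$rmse, slope = diag$slope,
    seed = seed, n = nrow(df)),
    class = "attribution_model")
}

# Stub constructor used in tests and as an oracle: `fun(no3, so4)` plays
# the fitted surface.
new_attribution_stub <- function(fun, r_no3 = 0, r_so4 = 0) {
  structure(list(
    forest = NULL, predict_fn = fun, r_no3 = r_no3, r_so4 = r_so4,
    reference_quantile = NA_real_,
    transport_tracer = "NO3", factory_tracer = "SO4",
    range_no3 = c(-Inf, Inf), range_so4 = c(-Inf, Inf),
    r_squared = NA_real_, rmse = NA_real_, slope = NA_real_,
    seed = NA_integer_, n = NA_integer_),
    class = "attribution_model")
}

predict_attribution <- function(model, no3, so4) {
  if (!is.null(model$predict_fn)) return(model$predict_fn(no3, so4))
  nd <- data.frame(no3 = no3, so4 = so4)
  predict(model$forest, data = nd, num.threads = 1)$predictions
}

#' @export
print.attribution_model <- function(x, ...) {
  cat(sprintf(
    "<attribution_model> R^2 = %.3f, RMSE = %.3f, refs (%.3g, %.3g)\n",
    x$r_squared, x$rmse, x$r_no3, x$r_so4))
  invisible(x)
}

#' @export
glance.attribution_model <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, rmse = x$rmse, slope = x$slope,
                 r_no3 = x$r_no3, r_so4 = x$r_so4, n = x$n)
}

#' Decompose normalized black carbon into transport and factory components
#'
#' Two-sided counterfactual differences on the fitted surface `g`: the
#' transport component starts from `g(no3, so4) - g(r_no3, so4)` and the
#' factory component from `g(no3, so4) - g(no3, r_so4)`; the baseline
#' floor is `g(r_no3, r_so4)`. The interaction mass left over (prediction
#' minus floor minus both differences) is allocated proportionally to the
#' absolute component sizes (equally when both are zero), which makes the
#' decomposition exactly additive by construction:
#' `bc_transport + bc_factory + floor = bc_predicted` before clipping.
#' Components are then clipped at zero with the clipped mass logged as an
#' attribute; `unexplained` is observed minus predicted.
#'
#' @param model An [fit_attribution_model()] result.
#' @param data Tibble with the tracer columns (and optionally `BC` for the
#'   unexplained term and `date`).
#' @return A `source_split` tibble: `date`, `bc_transport`, `bc_factory`,
#'   `floor`, `bc_predicted`, `unexplained`, plus unclipped
#'   `bc_transport_raw`, `bc_factory_raw`; attribute `clipped_mass`.
#' @export
attribute_sources <- function(model, data) {
  stopifnot(inherits(model, "attribution_model"))
  no3 <- data[[model$transport_tracer]]
  so4 <- data[[model$factory_tracer]]
  if (is.null(no3) || is.null(so4)) {
    abort("Tracer columns missing from attribution input.",
          class = "carbonsplit_schema_error")
  }
  out_hull <- no3 < model$range_no3[1] | no3 > model$range_no3[2] |
    so4 < model$range_so4[1] | so4 > model$range_so4[2]
  if (any(out_hull, na.rm = TRUE)) {
    warn(sprintf("%d rows fall outside the training tracer hull; %s",
                 sum(out_hull, na.rm = TRUE),
                 "attribution extrapolates there."))
  }
  g <- predict_attribution(model, no3, so4)
  g_t0 <- predict_attribution(model, rep(model$r_no3, length(no3)), so4)
  g_f0 <- predict_attribution(model, no3, rep(model$r_so4, length(so4)))
  floor_v <- predict_attribution(model, model$r_no3, model$r_so4)[1]
  d_t <- g - g_t0
  d_f <- g - g_f0
  rho <- g - floor_v - d_t - d_f
  denom <- abs(d_t) + abs(d_f)
  w_t <- ifelse(denom > 0, abs(d_t) / denom, 0.5)
  t_adj <- d_t + w_t * rho
  f_adj <- d_f + (1 - w_t) * rho
  bc_transport <- pmax(0, t_adj)
  bc_factory <- pmax(0, f_adj)
  clipped <- sum(pmax(0, -t_adj)) + sum(pmax(0, -f_adj))
  observed <- if ("BC" %in% names(data)) data$BC else rep(NA_real_, length(g))
  out <- tibble::tibble(
    date = if ("date" %in% names(data)) data$date else seq_along(g),
    bc_transport = bc_transport, bc_factory = bc_factory,
    bc_transport_raw = t_adj, bc_factory_raw = f_adj,
    floor = floor_v, bc_predicted = g,
    unexplained = observed - g)
  attr(out, "clipped_mass") <- clipped
  class(out) <- c("source_split", class(out))
  out
}

#' Fit quality of predicted against observed values
#'
#' @param predicted,observed Equal-length numeric vectors (n >= 3).
#' @return A list with `r_squared` (squared Pearson correlation), `rmse`,
#'   and `slope` of the OLS best fit of observed on predicted.
#' @export
evaluate_fit <- function(predicted, observed) {
  ok <- !is.na(predicted) & !is.na(observed)
  predicted <- predicted[ok]; observed <- observed[ok]
  if (length(predicted) < 3) {
    abort("Need at least 3 paired values.",
          class = "carbonsplit_insufficient_data_error")
  }
  if (sd(predicted) == 0 || sd(observed) == 0) {
    abort("Zero variance in predicted or observed series.",
          class = "carbonsplit_degenerate_error")
  }
  list(r_squared = cor(predicted, observed)^2,
       rmse = sqrt(mean((predicted - observed)^2)),
       slope = unname(coef(lm(observed ~ predicted))[2]))
}
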