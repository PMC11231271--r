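#' Default configuration for the full analysis pipeline
#'
#' @param seed Master seed; every stage draws from a named substream so
#'   toggling one stage never shifts another's randomness.
#' @param n_samples Meteorology resamples per date in normalization.
#' @param n_permutations Permutations for the feature significance tests
#'   (0 skips them).
#' @return A nested configuration list.
#' @export
default_config <- function(seed = 1L, n_samples = 200, n_permutations = 0) {
  list(
    seed = as.integer(seed),
    simulate = list(enabled = TRUE),
    periods = default_periods(),
    regimes = default_regimes(),
    normalization = list(n_samples = n_samples, num_trees = 300,
                         min_node_size = 5),
    trend = list(observed_granularity = "weekly",
                 normalized_granularity = "monthly",
                 detrend_before_attribution = FALSE),
    attribution = list(enabled = TRUE, reference_quantile = 0.05,
                       num_trees = 300, min_node_size = 5),
    response = list(targets = c("bc_private", "bus_volume", "metro_volume"),
                    pd_features = c("transmission", "fatality", "cases"),
                    n_grid = 20, num_trees = 500,
                    test_features = "cases",
                    n_permutations = n_permutations),
    stats = list(dow_start = as.Date("2022-11-25"),
                 dow_end = as.Date("2023-01-08"),
                 overrides = NULL))
}

#' Run the full simulate -- normalize -- attribute -- analyse pipeline
#'
#' Executes the stages in dependency order on a synthetic scenario (or
#' user-supplied tables), collecting per-stage diagnostics into a single
#' machine-readable report: out-of-bag fit quality, trend slopes per
#' decade, attribution diagnostics, transport statistics, segment
#' regressions, percent changes, partial-dependence summaries and
#' permutation p-values. Reruns with the same configuration and seed are
#' bit-identical.
#'
#' @param config A [default_config()]-style list.
#' @param scenario Optional pre-built [simulate_scenario()]; built from
#'   `config` when `NULL` and `config$simulate$enabled` is TRUE.
#' @param out_dir Optional directory; when given, intermediate tables are
#'   written as CSV and the report as JSON. On a stage failure a
#'   `FAILED-<stage>` marker is left there.
#' @return A `carbonsplit_report` list with one block per stage.
#' @export
run_pipeline <- function(config = default_config(), scenario = NULL,
                         out_dir = NULL) {
  report <- list(config_echo = list(seed = config$seed),
                 provenance = list(
                   package = "carbonsplit",
                   version = as.character(utils::packageVersion("carbonsplit")),
                   seed = config$seed))
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(force(expr), error = function(e) {
      if (!is.null(out_dir)) {
        writeLines(conditionMessage(e), file.path(out_dir, paste0("FAILED-", name)))
      }
      abort(sprintf("Stage '%s' failed: %s", name, conditionMessage(e)),
            class = "carbonsplit_stage_error")
    })
    res$wall_time_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    res
  }
  seed <- config$seed

  ## -- simulate --------------------------------------------------------
  sim <- stage("simulate", {
    if (is.null(scenario)) {
      if (!isTRUE(config$simulate$enabled)) {
        abort("No scenario supplied and simulation disabled.")
      }
      cfg_args <- config$simulate
      cfg_args$enabled <- NULL
      cfg_args$seed <- substream_seed(seed, "simulate")
      scenario <- do.call(synthetic_config, cfg_args) |> simulate_scenario()
    }
    list(n_days = nrow(scenario$pollutants),
         start = format(min(scenario$pollutants$date)),
         end = format(max(scenario$pollutants$date)))
  })
  report$simulate <- sim
  if (!is.null(out_dir)) write_scenario(scenario, file.path(out_dir, "scenario"))

  ## -- normalize (three species) ---------------------------------------
  ncf <- config$normalization
  norm <- list(); models <- list()
  report$normalize <- stage("normalize", {
    diag <- list()
    for (sp in c("BC", "NO3", "SO4")) {
      m <- fit_met_model(scenario$pollutants, scenario$met, sp,
                         seed = substream_seed(seed, paste0("normalize.", sp)),
                         num_trees = ncf$num_trees,
                         min_node_size = ncf$min_node_size)
      r <- normalize_pollutant(m, n_samples = ncf$n_samples,
                               seed = substream_seed(seed, paste0("normalize.", sp)))
      models[[sp]] <- m
      norm[[sp]] <- r
      diag[[sp]] <- list(oob_r2 = m$oob_r2, oob_rmse = m$oob_rmse,
                         mean_mc_sd = mean(r$mc_sd))
    }
    diag
  })
  normalized <- tibble::tibble(
    date = norm$BC$date, BC = norm$BC$normalized,
    NO3 = norm$NO3$normalized, SO4 = norm$SO4$normalized)

  ## -- trend -----------------------------------------------------------
  tcf <- config$trend
  trend_env <- new.env()
  report$trend <- stage("trend", {
    obs_w <- aggregate_series(scenario$pollutants, "BC",
                              tcf$observed_granularity)
    fit_obs <- fit_linear_trend(obs_w, "BC")
    norm_m <- aggregate_series(
      dplyr::rename(norm$BC, value = "normalized"), "value",
      tcf$normalized_granularity)
    fit_norm <- fit_linear_trend(norm_m, "value")
    trend_env$fit_norm <- fit_norm
    trend_env$norm_monthly <- detrend(norm_m, "value", fit_norm)
    list(observed = as.list(glance(fit_obs)),
         normalized = as.list(glance(fit_norm)))
  })

  ## -- baseline --------------------------------------------------------
  report$baseline <- stage("baseline", {
    bl <- compute_baseline(trend_env$norm_monthly, config$periods, "value")
    list(overall = attr(bl, "overall"),
         monthly = stats::setNames(bl$baseline, month.abb[bl$month]))
  })

  ## -- attribute -------------------------------------------------------
  split <- NULL
  report$attribute <- stage("attribute", {
    if (!isTRUE(config$attribution$enabled)) {
      list(enabled = FALSE)
    } else {
      attr_input <- normalized
      if (isTRUE(tcf$detrend_before_attribution)) {
        d <- detrend(dplyr::rename(normalized, value = "BC"), "value")
        attr_input$BC <- d$recentered
      }
      am <- fit_attribution_model(
        attr_input,
        reference_quantile = config$attribution$reference_quantile,
        seed = substream_seed(seed, "attribute"),
        num_trees = config$attribution$num_trees,
        min_node_size = config$attribution$min_node_size)
      split <- attribute_sources(am, attr_input)
      c(as.list(glance(am)),
        list(clipped_mass = attr(split, "clipped_mass"),
             mean_bc_transport = mean(split$bc_transport),
             mean_bc_factory = mean(split$bc_factory)))
    }
  })
  if (!is.null(out_dir) && !is.null(split)) {
    utils::write.csv(split, file.path(out_dir, "source_split.csv"),
                     row.names = FALSE)
  }

  ## -- stats -----------------------------------------------------------
  scf <- config$stats
  report$stats <- stage("stats", {
    dow_in <- scenario$daily_volumes |>
      dplyr::filter(.data$date >= scf$dow_start, .data$date <= scf$dow_end) |>
      dplyr::transmute(date = .data$date, volume = .data$metro_volume)
    dw <- day_of_week_stats(dow_in)
    vol_long <- scenario$monthly_volumes |>
      tidyr::pivot_longer(cols = dplyr::ends_with("_volume"),
                          names_to = "mode", values_to = "volume") |>
      dplyr::mutate(mode = sub("_volume$", "", .data$mode))
    pc <- percent_change(vol_long, config$periods)
    seg <- NULL
    if (!is.null(split)) {
      bc_m <- split |>
        dplyr::group_by(month = month_start(.data$date)) |>
        dplyr::summarise(bc_private = mean(.data$bc_transport), .groups = "drop")
      seg_in <- dplyr::inner_join(
        bc_m, scenario$monthly_volumes[, c("month", "public_volume")],
        by = "month")
      seg <- segment_regression(seg_in, config$regimes,
                                overrides = scf$overrides)
    }
    list(day_of_week = list(table = tidy(dw), t = dw$t_statistic,
                            p_value = dw$p_value),
         percent_change = pc,
         segments = seg)
  })

  ## -- respond ---------------------------------------------------------
  rcf <- config$response
  report$respond <- stage("respond", {
    if (is.null(split)) {
      abort("Response stage needs `bc_transport` from the attribution stage; enable attribution.")
    }
    panel <- build_monthly_panel(split, scenario$monthly_volumes,
                                 scenario$met, scenario$epidemic)
    out <- list(n_months = nrow(panel), targets = list())
    for (tg in rcf$targets) {
      rm <- fit_response_model(panel, tg,
                               seed = substream_seed(seed, paste0("respond.", tg)),
                               num_trees = rcf$num_trees)
      blk <- list(oob_r2 = rm$oob_r2, pd = list(), tests = list())
      for (ft in rcf$pd_features) {
        pd <- partial_dependence(rm, ft, rcf$n_grid)
        blk$pd[[ft]] <- list(range = max(pd$pd) - min(pd$pd),
                             spearman_with_grid =
                               suppressWarnings(stats::cor(pd$value, pd$pd,
                                                           method = "spearman")))
      }
      if (rcf$n_permutations > 0) {
        for (ft in rcf$test_features) {
          tst <- feature_effect_test(rm, ft, rcf$n_permutations,
                                     seed = substream_seed(seed, paste0("respond.", tg)))
          blk$tests[[ft]] <- tst$p_value
        }
      }
      out$targets[[tg]] <- blk
    }
    out
  })

  class(report) <- "carbonsplit_report"
  if (!is.null(out_dir)) {
    jsonlite::write_json(report_to_json(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  }
  report
}

report_to_json <- function(report) {
  rapply(unclass(report), f = function(x) {
    if (inherits(x, "Date")) format(x) else x
  }, how = "replace")
}

#' @export
print.carbonsplit_report <- function(x, ...) {
  cat("<carbonsplit_report>\n")
  cat("  stages:", paste(setdiff(names(x), c("config_echo", "provenance")),
                         collapse = ", "), "\n")
  if (!is.null(x$trend$normalized$slope_per_decade)) {
    cat(sprintf("  normalized BC trend: %.2f ug/m3 per decade\n",
                x$trend$normalized$slope_per_decade))
  }
  invisible(x)
}
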