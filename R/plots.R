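#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_ribbon
#'   geom_col geom_smooth labs theme_minimal facet_wrap
NULL

#' @export
ggplot2::autoplot

#' Plot a weather-normalized series with its Monte-Carlo band
#'
#' @param object A [normalize_pollutant()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.normalization_result <- function(object, ...) {
  ggplot(object, aes(x = .data$date)) +
    geom_ribbon(aes(ymin = .data$normalized - 2 * .data$mc_sd,
                    ymax = .data$normalized + 2 * .data$mc_sd),
                fill = "grey80") +
    geom_line(aes(y = .data$observed), colour = "grey50", linewidth = 0.2) +
    geom_line(aes(y = .data$normalized), colour = "navy") +
    labs(x = NULL, y = expression(paste("concentration (", mu, "g ", m^-3, ")")),
         title = "Observed (grey) and weather-normalized (navy) series") +
    theme_minimal()
}

#' Plot a source split as stacked transport/factory components
#'
#' @param object An [attribute_sources()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.source_split <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object[, c("date", "bc_transport", "bc_factory")],
    cols = c("bc_transport", "bc_factory"),
    names_to = "source", values_to = "value")
  ggplot(long, aes(x = .data$date, y = .data$value, fill = .data$source)) +
    geom_col(position = "stack", width = 1) +
    labs(x = NULL, y = expression(paste("BC (", mu, "g ", m^-3, ")")),
         fill = NULL) +
    theme_minimal()
}

#' Plot partial-dependence curves
#'
#' @param object A [partial_dependence()] result (rows from several
#'   features may be bound together; the plot facets by feature).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.partial_dependence <- function(object, ...) {
  ggplot(object, aes(x = .data$value, y = .data$pd)) +
    geom_line(colour = "navy") + geom_point(size = 0.8) +
    facet_wrap(~feature, scales = "free_x") +
    labs(x = "feature value", y = "mean predicted response") +
    theme_minimal()
}

#' Plot regime-wise private-vs-public transport regressions
#'
#' @param object A [segment_regression()] result.
#' @param data The monthly tibble the segments were fitted on (with
#'   `month`, `bc_private`, `public_volume`).
#' @param periods The period tibble used for the fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.segment_regression <- function(object, data = NULL,
                                        periods = default_regimes(), ...) {
  if (is.null(data)) {
    ggplot(object, aes(x = .data$period, y = .data$slope)) +
      geom_point() +
      ggplot2::geom_errorbar(aes(ymin = .data$conf_low, ymax = .data$conf_high),
                             width = 0.2) +
      labs(x = NULL, y = "slope (ug/m3 per million passengers)") +
      theme_minimal()
  } else {
    df <- dplyr::mutate(data, period = period_of(.data$month, periods))
    df <- df[!is.na(df$period), ]
    ggplot(df, aes(x = .data$public_volume, y = .data$bc_private,
                   colour = .data$period)) +
      geom_point() +
      geom_smooth(method = "lm", se = FALSE, formula = y ~ x) +
      labs(x = "public transport volume (million passengers/month)",
           y = expression(paste("private-transport BC (", mu, "g ", m^-3, ")")),
           colour = NULL) +
      theme_minimal()
  }
}
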