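# ggplot2 views of an experiment result: utilisation by facility type,
# catastrophic expenditure by wealth quintile, distance/readiness shifts,
# and a headline-contrast overview as autoplot().

scenario_levels <- function(result) unique(result$runs$scenario)

#' Delivery utilisation by facility type
#'
#' Mean share of deliveries done in each facility type per scenario, with
#' 95% posterior credible interval error bars.
#'
#' @param result A `regiosim_result`.
#' @return A ggplot object.
#' @export
plot_utilisation <- function(result) {
  df <- result$utilisation %>%
    group_by(.data$scenario, .data$ftype) %>%
    summarise(mean = mean(.data$share_pct),
              lower = unname(quantile(.data$share_pct, 0.025)),
              upper = unname(quantile(.data$share_pct, 0.975)), .groups = "drop") %>%
    mutate(scenario = factor(.data$scenario, levels = scenario_levels(result)),
           ftype = factor(.data$ftype, levels = FACILITY_TYPES))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ftype, y = .data$mean,
                                   fill = .data$scenario)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.85), width = 0.8) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                           position = ggplot2::position_dodge(width = 0.85), width = 0.25) +
    ggplot2::labs(x = NULL, y = "share of deliveries (%)", fill = NULL,
                  title = "Use of delivery services under each scenario") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Catastrophic expenditure risk by wealth quintile
#'
#' @param result A `regiosim_result`.
#' @return A ggplot object.
#' @export
plot_catastrophic_by_quintile <- function(result) {
  df <- result$catastrophic_by_quintile %>%
    mutate(scenario = factor(.data$scenario, levels = scenario_levels(result)),
           wealth_quintile = factor(.data$wealth_quintile, levels = 1:5,
                                    labels = c("poorest", "q2", "q3", "q4", "richest")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$wealth_quintile,
                                   y = .data$catastrophic_pct,
                                   fill = .data$scenario)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = "wealth quintile", y = "catastrophic expenditure risk (%)",
                  fill = NULL,
                  title = "Risk of catastrophic expenditure by wealth quintile") +
    ggplot2::theme_minimal()
}

#' Travel distance and accessed readiness per scenario
#'
#' Box plots of the per-run mean travel distance and mean obstetric
#' readiness of accessed facilities.
#'
#' @param result A `regiosim_result`.
#' @return A ggplot object (facetted).
#' @export
plot_distance_readiness <- function(result) {
  df <- result$runs %>%
    select("scenario", "run", distance_km = "mean_distance_km",
           readiness = "mean_readiness") %>%
    tidyr::pivot_longer(c("distance_km", "readiness"),
                        names_to = "metric", values_to = "value") %>%
    mutate(scenario = factor(.data$scenario, levels = scenario_levels(result)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$scenario, y = .data$value)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Travel distance and readiness of accessed facilities") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Headline contrasts against the baseline scenario
#'
#' Point estimates with 95% posterior credible intervals for every metric's
#' paired per-run difference against the baseline scenario.
#'
#' @param object A `regiosim_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot regiosim_result
#' @export
autoplot.regiosim_result <- function(object, ...) {
  df <- object$contrasts %>%
    mutate(scenario = factor(.data$scenario, levels = scenario_levels(object)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$scenario)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lower, xmax = .data$upper)) +
    ggplot2::facet_wrap(~metric, scales = "free_x") +
    ggplot2::labs(x = sprintf("difference vs %s (mean, 95%% PCI)", object$baseline),
                  y = NULL) +
    ggplot2::theme_minimal()
}
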