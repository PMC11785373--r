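#' Observed-versus-expected summation curves
#'
#' Plots the scaled near-synchronous response against the scaled
#' arithmetic-sum expectation for each measure, with the line of identity;
#' supralinear dendrites bow above the identity line.
#'
#' @param series Long-format series tibble from [analyze_dendrite()] /
#'   [tidy()] (columns `dendrite_id`, `k`, `measure`, `scaled_observed`,
#'   `scaled_expected`).
#' @return A ggplot object.
#' @export
plot_summation <- function(series) {
  ggplot2::ggplot(series,
                  ggplot2::aes(x = .data$scaled_expected,
                               y = .data$scaled_observed,
                               group = .data$dendrite_id)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~measure) +
    ggplot2::labs(x = "scaled arithmetic sum",
                  y = "scaled near-synchronous response") +
    ggplot2::theme_minimal()
}

#' Calcium transient amplitude versus number of locations
#'
#' Plots the measured peak delta-F/A against the cumulative number of
#' near-synchronously uncaged locations, with the interpolated linear
#' expectation as a reference line; an abrupt jump above the line marks
#' regenerative (store-amplified) calcium signalling.
#'
#' @param calcium Per-k calcium tibble from [analyze_dendrite()] (columns
#'   `dendrite_id`, `k`, `dfa`, `expected`).
#' @return A ggplot object.
#' @export
plot_calcium <- function(calcium) {
  ggplot2::ggplot(calcium, ggplot2::aes(x = .data$k,
                                        group = .data$dendrite_id)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$expected), colour = "grey60") +
    ggplot2::geom_line(ggplot2::aes(y = .data$dfa)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$dfa), size = 1) +
    ggplot2::labs(x = "number of uncaging locations",
                  y = expression(Delta * "F/A")) +
    ggplot2::theme_minimal()
}

#' Slopegraph of paired nonlinearity values
#'
#' Connects each experimental unit's values across two conditions with a
#' line, the standard display for paired estimation statistics.
#'
#' @param data Data frame with one row per unit and condition.
#' @param value,group,unit Tidy-eval columns: the measured value, the
#'   condition label (two levels) and the unit id.
#' @return A ggplot object.
#' @export
plot_slopegraph <- function(data, value, group, unit) {
  ggplot2::ggplot(data,
                  ggplot2::aes(x = {{ group }}, y = {{ value }},
                               group = {{ unit }})) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::geom_point() +
    ggplot2::labs(x = NULL) +
    ggplot2::theme_minimal()
}

#' Gardner-Altman-style estimation plot for a group summary
#'
#' Shows each contrast's mean difference with its BCa 95% confidence
#' interval against a zero reference line.
#'
#' @param object A `pipeline_result` or the `stats` tibble from one.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.pipeline_result <- function(object, ...) {
  stats_tbl <- if (inherits(object, "pipeline_result")) object$stats else object
  ggplot2::ggplot(stats_tbl,
                  ggplot2::aes(x = .data$contrast, y = .data$estimate)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high)) +
    ggplot2::labs(x = NULL, y = "mean difference (% nonlinearity)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
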