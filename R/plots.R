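#' Plot the diversity profile along the chromosome
#'
#' Within-patch diversity of neutral loci against map distance from the
#' selected locus (log10 x-axis), one line per patch, at one sampling
#' generation.
#'
#' @param metrics Tidy metric tibble (`tidy(sim)` or bound replicates).
#' @param metric Metric to plot (default `"pi_w"`).
#' @param generation Sampling generation (default: latest).
#' @return A ggplot object.
#' @export
plot_diversity_profile <- function(metrics, metric = "pi_w",
                                   generation = NULL) {
  generation <- generation %||% max(metrics$generation)
  df <- dplyr::filter(metrics, .data$generation == !!generation,
                      .data$kind == "neutral", .data$metric == !!metric,
                      .data$distance_cM > 0)
  df <- dplyr::summarise(
    dplyr::group_by(df, .data$patch, .data$distance_cM),
    value = mean(.data$value, na.rm = TRUE), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$distance_cM, y = .data$value,
                                   colour = .data$patch)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "distance from selected locus (cM)", y = metric,
                  colour = "patch") +
    ggplot2::theme_minimal()
}

#' Plot a regime map: diversity-distance slope against migration rate
#'
#' @param signatures Tibble with columns `m` and `dd_slope` (e.g. bound
#'   [signature_report()] rows, optionally pre-averaged over replicates).
#' @param slope Column holding the slope (tidy-selected).
#' @return A ggplot object.
#' @export
plot_regime_map <- function(signatures, slope = dd_slope) {
  df <- dplyr::filter(signatures, .data$m > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = log10(.data$m), y = {{ slope }})) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::stat_summary(fun = mean, geom = "line") +
    ggplot2::stat_summary(fun = mean, geom = "point") +
    ggplot2::labs(x = "log10 migration rate",
                  y = "diversity-distance slope") +
    ggplot2::theme_minimal()
}

#' @describeIn plot_diversity_profile Autoplot method for `wf_sim`.
#' @param object A `wf_sim`.
#' @param ... Passed to [plot_diversity_profile()].
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.wf_sim <- function(object, ...) {
  stopifnot(!is.null(object$metrics))
  plot_diversity_profile(object$metrics, ...)
}
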