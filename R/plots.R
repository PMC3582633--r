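#' Posterior histograms of the population-level coefficients
#'
#' @param object A `moonbird_fit`.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot object, one facet per coefficient, with the 95%
#'   credible interval marked.
#' @method autoplot moonbird_fit
#' @export
autoplot.moonbird_fit <- function(object, bins = 40, ...) {
  draws <- tibble::as_tibble(object$mu) |>
    tidyr::pivot_longer(dplyr::everything(),
                        names_to = "parameter", values_to = "value")
  ci <- summarize_population(object)
  ggplot2::ggplot(draws, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35") +
    ggplot2::geom_vline(data = ci,
                        ggplot2::aes(xintercept = .data$ci_low),
                        linetype = 2) +
    ggplot2::geom_vline(data = ci,
                        ggplot2::aes(xintercept = .data$ci_high),
                        linetype = 2) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = "posterior draw", y = "count") +
    ggplot2::theme_minimal()
}

#' Plot posterior predictive bands for the nightly wet probability
#'
#' @param bands Output of [posterior_predictive_p()].
#' @return A ggplot object: predictive mean line with the 95% ribbon.
#' @export
plot_predictive_bands <- function(bands) {
  ggplot2::ggplot(bands, ggplot2::aes(x = .data$night_date)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lower_p,
                                      ymax = .data$ci_upper_p),
                         fill = "grey70") +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean_p)) +
    ggplot2::labs(x = NULL, y = "P(wet)") +
    ggplot2::theme_minimal()
}

#' Actogram heat map
#'
#' @param acto Output of [actogram_matrix()].
#' @return A ggplot object: nights on the y axis, block-of-night on the x
#'   axis, darker cells wetter.
#' @export
plot_actogram <- function(acto) {
  ggplot2::ggplot(acto, ggplot2::aes(x = .data$block_index,
                                     y = .data$night_date,
                                     fill = .data$mean_wet)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "black",
                                 limits = c(0, 1), name = "mean wet") +
    ggplot2::labs(x = "block of night", y = NULL) +
    ggplot2::theme_minimal()
}
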