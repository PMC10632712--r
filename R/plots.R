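#' Caterpillar plot of ordered effect sizes
#'
#' Displays one parameter's per-effect estimates (with CIs) ordered by size,
#' plus the pooled estimate as a highlighted diamond when present.
#'
#' @param data Output of [caterpillar_data()].
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_caterpillar <- function(data, title = NULL) {
  ggplot2::ggplot(data, ggplot2::aes(x = .data$rank, y = .data$estimate)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$ci_low,
                                         ymax = .data$ci_high,
                                         colour = .data$pooled),
                            show.legend = FALSE) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$pooled,
                                     shape = .data$pooled),
                        size = 1.6, show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "firebrick")) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 18)) +
    ggplot2::labs(x = "ordered effects", y = "estimate (95% CI)",
                  title = title) +
    ggplot2::theme_minimal()
}

#' Forest-style display of the six pooled parameters
#'
#' @param table The `table` element returned by [run_reanalysis()] (or the
#'   output of [meta_report()]).
#' @return A ggplot object.
#' @export
plot_report <- function(table) {
  tab <- dplyr::mutate(table,
                       parameter = factor(.data$parameter,
                                          levels = rev(meta_parameters())))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$estimate,
                                    y = .data$parameter)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "pooled estimate (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a pooled fit
#'
#' Draws the back-transformed pooled estimate and its confidence interval.
#'
#' @param object A `meta_pool` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot meta_pool
#' @export
autoplot.meta_pool <- function(object, ...) {
  d <- tibble::tibble(estimate = object$estimate,
                      ci_low = object$ci95[1], ci_high = object$ci95[2],
                      label = sprintf("pooled (k = %d)", object$k))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.1) +
    ggplot2::geom_point(shape = 18, size = 3) +
    ggplot2::labs(x = "pooled estimate (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}
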