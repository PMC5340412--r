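# ggplot2 views of the main result types

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @exportS3Method ggplot2::autoplot
autoplot.correlogram <- function(object, ...) {
  hw <- attr(object, "ci_halfwidth")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lag, y = .data$acf)) +
    ggplot2::geom_hline(yintercept = 0, colour = "orange", linetype = 2) +
    ggplot2::geom_hline(yintercept = c(-hw, hw), colour = "grey60",
                        linetype = 3) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$lag, yend = 0)) +
    ggplot2::labs(x = "lag (days)", y = "autocorrelation") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.coherence_result <- function(object, ...) {
  ggplot2::ggplot(object$bins,
                  ggplot2::aes(x = (.data$bin_low + .data$bin_high) / 2,
                               y = .data$mean_coefficient,
                               size = .data$n_pairs)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60", linetype = 2) +
    ggplot2::geom_point(colour = "firebrick") +
    ggplot2::labs(x = "phylogenetic distance (bin midpoint)",
                  y = "mean coefficient", size = "pairs") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.state_decay <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$stride, y = .data$best_k)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = object$curve$stride) +
    ggplot2::labs(x = "sampling stride (days)",
                  y = "selected number of states") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.crt_report <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$b,
                                       y = .data$peak_abundance,
                                       colour = .data$is_crt)) +
    ggplot2::geom_vline(xintercept = attr(object, "b_min"),
                        linetype = 2, colour = "grey50") +
    ggplot2::geom_hline(yintercept = attr(object, "peak_min"),
                        linetype = 2, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "bimodality coefficient", y = "peak abundance",
                  colour = "CRT") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.svar_fit <- function(object, ...) {
  df <- variance_explained(object)
  df$taxon_id <- factor(df$taxon_id,
                        levels = df$taxon_id[order(-df$r_squared)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$taxon_id,
                                   y = .data$r_squared)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = expression(R^2 ~ "(autoregressive)")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 6))
}
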