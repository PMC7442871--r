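#' Plot the cost-effectiveness plane
#'
#' @param ensemble A `vn_ensemble`.
#' @return A ggplot object (requires the ggplot2 package).
#' @export
plot_ce_plane <- function(ensemble) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  df <- ce_plane(ensemble)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta_qaly, y = .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.4, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost (EUR)",
                  title = "Cost-effectiveness plane")
}

#' Plot the cost-effectiveness acceptability curve
#'
#' @param ensemble A `vn_ensemble`.
#' @param thresholds Willingness-to-pay grid, EUR/QALY.
#' @return A ggplot object (requires the ggplot2 package).
#' @export
plot_ceac <- function(ensemble, thresholds = seq(0, 500000, by = 10000)) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  df <- ceac(ensemble, thresholds)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$threshold,
                                   y = .data$fraction_cost_effective)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (EUR/QALY)",
                  y = "Fraction cost effective",
                  title = "Cost-effectiveness acceptability curve")
}
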