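#' Plot power curves
#'
#' One line per scenario, with gray reference lines at the Type I error rate
#' (a lower limit for power) and at 0.9, a common target power for clinical
#' trial design.
#'
#' @param curves A `power_curve` data frame, or several row-bound together.
#' @param alpha Type I error reference line.
#' @param target Target power reference line.
#' @return A ggplot object.
#' @export
plot_power_curves <- function(curves, alpha = 0.05, target = 0.9) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_power_curves requires ggplot2")
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = effect, y = power, colour = scenario)) +
    ggplot2::geom_hline(yintercept = c(alpha, target),
                        colour = "gray60", linewidth = 0.4) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Effect size (SD of one outcome)", y = "Power",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
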