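# ggplot2 figures for the standard CEA graphics: tornado diagram, CEAC,
# and the incremental cost-effectiveness scatter with its 95% normal
# ellipse and WTP line.

#' Tornado diagram of a one-way sensitivity analysis
#'
#' @param owsa A [run_owsa()] result.
#' @param top Number of widest bars to show (default all).
#' @return A ggplot object.
#' @export
plot_tornado <- function(owsa, top = nrow(owsa)) {
  stopifnot(inherits(owsa, "owsa_result"))
  d <- utils::head(owsa, top)
  d$parameter <- factor(d$parameter, levels = rev(d$parameter))
  base_icer <- attr(owsa, "base_icer")
  ggplot2::ggplot(d) +
    ggplot2::geom_segment(ggplot2::aes(
      x = .data$icer_low, xend = .data$icer_high,
      y = .data$parameter, yend = .data$parameter), linewidth = 4) +
    ggplot2::geom_vline(xintercept = base_icer, linetype = 2) +
    ggplot2::labs(x = "ICER (USD/QALY)", y = NULL,
                  title = "One-way sensitivity analysis") +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness acceptability curve plot
#'
#' @param psa A [run_psa()] result (or a `ceac` data frame).
#' @param wtp Optional WTP to mark with a vertical line.
#' @return A ggplot object.
#' @export
plot_ceac <- function(psa, wtp = NULL) {
  d <- if (inherits(psa, "psa_result")) psa$ceac else psa
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$wtp, .data$prob_ce)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness-to-pay (USD/QALY)",
                  y = "Probability cost-effective",
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
  if (!is.null(wtp)) p <- p + ggplot2::geom_vline(xintercept = wtp, linetype = 2)
  p
}

#' Incremental cost-effectiveness scatter plot
#'
#' One point per Monte-Carlo draw on the incremental cost-effectiveness
#' plane, a bivariate-normal 95% ellipse, and the WTP line through the
#' origin; draws below the line are cost-effective at that WTP.
#'
#' @param psa A [run_psa()] result.
#' @param wtp WTP (USD/QALY); default the one used by the PSA.
#' @return A ggplot object.
#' @export
plot_psa_scatter <- function(psa, wtp = NULL) {
  stopifnot(inherits(psa, "psa_result"))
  if (is.null(wtp)) wtp <- psa$summary$wtp
  d <- psa$draws
  ggplot2::ggplot(d, ggplot2::aes(.data$delta_qaly, .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.5) +
    ggplot2::stat_ellipse(type = "norm", level = 0.95, colour = "red") +
    ggplot2::geom_abline(slope = wtp, intercept = 0, linetype = 2) +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost (USD)",
                  title = "Probabilistic sensitivity scatter") +
    ggplot2::theme_minimal()
}
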