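# Optional plot renderings of the sensitivity-analysis tables. All plots
# are drawn from the same data frames the CSV outputs contain; ggplot2 is
# suggested, not required.

need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting; install it or use the CSV outputs",
         call. = FALSE)
  }
}

#' Cost-effectiveness plane of the PSA draws
#'
#' @param psa A `cyto_psa` object.
#' @return A ggplot object (incremental QALYs vs incremental cost per
#'   person, one point per draw, threshold line overlaid).
#' @export
plot_ce_plane <- function(psa) {
  need_ggplot()
  d <- psa$draws
  ggplot2::ggplot(d, ggplot2::aes(x = delta_qaly,
                                  y = delta_cost)) +
    ggplot2::geom_point(alpha = 0.4, shape = 18, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::geom_abline(slope = psa$threshold, intercept = 0,
                         linetype = "dashed") +
    ggplot2::labs(x = "Incremental QALYs per person",
                  y = "Incremental cost per person (GBP)",
                  title = "Cost-effectiveness plane")
}

#' Cost-effectiveness acceptability curve
#'
#' @param psa A `cyto_psa` object.
#' @return A ggplot object (probability cost-effective vs willingness to
#'   pay).
#' @export
plot_ceac <- function(psa) {
  need_ggplot()
  ggplot2::ggplot(psa$ceac, ggplot2::aes(x = threshold,
                                         y = probability)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Willingness to pay (GBP/QALY)",
                  y = "Probability cost-effective",
                  title = "Cost-effectiveness acceptability curve")
}

#' Tornado plot of the one-way sensitivity analysis
#'
#' @param dsa A `cyto_dsa` object.
#' @param n Number of top-ranked parameters to show.
#' @return A ggplot object with parameters ordered by induced ICER range.
#' @export
plot_tornado <- function(dsa, n = 12) {
  need_ggplot()
  d <- as.data.frame(dsa)[seq_len(min(n, nrow(dsa))), ]
  d$parameter <- factor(d$parameter, levels = rev(d$parameter))
  base <- attr(dsa, "icer_base")
  ggplot2::ggplot(d) +
    ggplot2::geom_segment(ggplot2::aes(x = icer_low,
                                       xend = icer_high,
                                       y = parameter,
                                       yend = parameter),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = base, linetype = "dashed") +
    ggplot2::labs(x = "ICER (GBP/QALY)", y = NULL,
                  title = "One-way sensitivity (tornado)")
}
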