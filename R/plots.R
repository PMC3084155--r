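#' Cost-effectiveness plane scatter of PSA iterations
#'
#' Each point is one iteration's incremental effectiveness and incremental
#' cost (programme minus usual care); the dashed diagonal is the
#' willingness-to-pay threshold.
#'
#' @param psa a `psa_result`.
#' @param wtp threshold drawn as a diagonal (default from the result).
#' @param rate discount rate to plot when several were evaluated.
#' @return a ggplot object.
#' @export
plot_ce_plane <- function(psa, wtp = psa$wtp_threshold, rate = NULL) {
  it <- psa_at_rate(psa, rate %||% psa$rates[1])
  ggplot2::ggplot(it, ggplot2::aes(x = .data$delta_effect,
                                   y = .data$delta_cost / 1000)) +
    ggplot2::geom_point(alpha = 0.15, size = 0.4, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::geom_abline(slope = wtp / 1000, intercept = 0,
                         linetype = "dashed") +
    ggplot2::labs(x = "Incremental effectiveness (LYG)",
                  y = "Incremental cost (K Int$)",
                  title = "Programme vs usual care: CE plane") +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness acceptability curves
#'
#' @param ceac_df output of [ceac()].
#' @return a ggplot object.
#' @export
plot_ceac <- function(ceac_df) {
  long <- data.frame(
    wtp = rep(ceac_df$wtp, 2),
    strategy = rep(c("Usual care", "Hypertension programme"),
                   each = nrow(ceac_df)),
    p = c(ceac_df$p_usual, ceac_df$p_programme))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$wtp / 1000, y = .data$p,
                                     colour = .data$strategy)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (K Int$/LYG)",
                  y = "Probability most cost-effective",
                  colour = NULL, title = "Acceptability curves") +
    ggplot2::theme_minimal()
}

#' Tornado diagram of one-way sensitivity results
#'
#' Horizontal bars span the incremental net monetary benefit between each
#' parameter's bounds, widest on top.
#'
#' @param entries output of [tornado()].
#' @param top number of parameters to show (default 12).
#' @return a ggplot object.
#' @export
plot_tornado <- function(entries, top = 12L) {
  e <- utils::head(entries[order(-entries$spread), ], top)
  e$parameter <- factor(e$parameter, levels = rev(e$parameter))
  ggplot2::ggplot(e, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$nmb_low,
                                       xend = .data$nmb_high,
                                       yend = .data$parameter),
                          linewidth = 4, colour = "grey40") +
    ggplot2::labs(x = "Incremental NMB at threshold (Int$)", y = NULL,
                  title = "Tornado: one-way sensitivity") +
    ggplot2::theme_minimal()
}
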