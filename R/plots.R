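need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
}

#' Scatter the PSA draws on the cost-effectiveness plane
#'
#' @param draws A `psa_draws` object.
#' @param wtp Optional willingness-to-pay threshold; drawn as a line through
#'   the origin with slope `wtp`.
#' @param max_points Subsample cap for plotting (default 20,000).
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(draws, wtp = NULL, max_points = 20000L) {
  need_ggplot()
  d <- draws$results
  if (nrow(d) > max_points) d <- d[seq_len(max_points), ]
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$delta_effect,
                                       y = .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.15, size = 0.4) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "incremental effectiveness (months)",
                  y = "incremental cost")
  if (!is.null(wtp))
    p <- p + ggplot2::geom_abline(slope = wtp, intercept = 0,
                                  linetype = "dashed")
  p
}

#' Plot a cost-effectiveness acceptability curve
#'
#' @param curve A `ceac_curve` from [ceac()].
#' @return A ggplot object.
#' @export
plot_ceac <- function(curve) {
  need_ggplot()
  strategies <- attr(curve, "strategies")
  long <- data.frame(
    lambda = rep(curve$lambda, 2L),
    probability = c(curve[[2L]], curve[[3L]]),
    strategy = rep(strategies, each = nrow(curve)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$lambda,
                                     y = .data$probability,
                                     colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "willingness to pay per month",
                  y = "probability cost-effective")
}

#' Plot a tornado diagram
#'
#' @param result A `tornado_result` from [tornado()].
#' @param top Number of widest parameters to show (default 15).
#' @return A ggplot object.
#' @export
plot_tornado <- function(result, top = 15L) {
  need_ggplot()
  d <- utils::head(as.data.frame(result), top)
  d$parameter_id <- factor(d$parameter_id, levels = rev(d$parameter_id))
  base <- attr(result, "base_icer")
  ggplot2::ggplot(d, ggplot2::aes(y = .data$parameter_id)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$icer_at_low,
                                       xend = .data$icer_at_high,
                                       yend = .data$parameter_id),
                          linewidth = 3, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = base, linetype = "dashed") +
    ggplot2::labs(x = "ICER", y = NULL)
}
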