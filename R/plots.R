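# ggplot2 presentations of the result objects.

#' @method autoplot effect_summary
#' @export
autoplot.effect_summary <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$factor <- factor(df$factor, levels = rev(df$factor))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_effect, y = .data$factor)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey40") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$hdi_low,
                                          xmax = .data$hdi_high)) +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f, P=%.0f%%", .data$mean_effect,
                      100 * .data$prob_direction)),
      vjust = -0.9, size = 3) +
    ggplot2::labs(x = "multiplicative effect on mark count (exp scale)",
                  y = NULL,
                  title = "Species-level effects with 95% HDIs") +
    ggplot2::theme_minimal()
}

#' @method autoplot interaction_surface
#' @export
autoplot.interaction_surface <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$horizontal <- factor(df$horizontal, levels = c("A", "C", "P"))
  df$vertical <- factor(df$vertical, levels = c("D", "M", "V"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$horizontal,
                                   y = .data$mean_count,
                                   group = .data$vertical,
                                   colour = .data$vertical,
                                   fill = .data$vertical)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$hdi_low,
                                      ymax = .data$hdi_high),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "horizontal position", y = "expected marks",
                  colour = "vertical", fill = "vertical",
                  title = "Expected mark count across body areas") +
    ggplot2::theme_minimal()
}

#' Energy diagnostic plot
#'
#' Overlaid histograms of the centred marginal energy and the energy
#' transitions (successive differences), pooled over chains. Heavy
#' marginal tails relative to the transition distribution (low E-BFMI)
#' indicate the sampler cannot refresh energy fast enough.
#'
#' @param fit A `scale_fit`.
#' @return A ggplot object.
#' @export
plot_energy <- function(fit) {
  stopifnot(inherits(fit, "scale_fit"))
  e <- fit$sampler$energy
  df <- dplyr::bind_rows(
    tibble::tibble(what = "marginal energy",
                   value = as.vector(e - rowMeans(e))),
    tibble::tibble(what = "energy transition",
                   value = as.vector(t(apply(e, 1, function(ch)
                     c(NA, diff(ch)))))))
  df <- df[!is.na(df$value), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, fill = .data$what)) +
    ggplot2::geom_histogram(position = "identity", alpha = 0.5, bins = 60) +
    ggplot2::labs(x = "centred energy", y = NULL, fill = NULL,
                  title = sprintf("Energy diagnostic (min E-BFMI = %.2f)",
                                  min(ebfmi(fit)))) +
    ggplot2::theme_minimal()
}
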