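#' Plot a resistance trajectory
#'
#' Allele-frequency trajectories for both loci (sex-averaged) against
#' generation, with the deployment phase shown by line colour and the
#' resistance threshold as a horizontal reference.
#'
#' @param outcome A `strategy_outcome`.
#' @param path Optional file path; when given the figure is saved there
#'   (format from the extension) and the path returned invisibly.
#' @return A ggplot object (or `path` invisibly when saving).
#' @export
plot_trajectory <- function(outcome, path = NULL) {
  traj <- outcome$trajectory
  df <- rbind(
    data.frame(generation = traj$generation, locus = "locus 1",
               freq = (traj$freq_R1_m + traj$freq_R1_f) / 2,
               deployment = traj$deployment),
    data.frame(generation = traj$generation, locus = "locus 2",
               freq = (traj$freq_R2_m + traj$freq_R2_f) / 2,
               deployment = traj$deployment)
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$generation, y = .data$freq,
                                        linetype = .data$locus,
                                        colour = .data$deployment)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = outcome$threshold, linetype = "dotted") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Generation", y = "Resistance allele frequency",
                  colour = "Deployment", linetype = "Locus",
                  title = sprintf("Strategy: %s", outcome$strategy)) +
    ggplot2::theme_minimal()
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = 7, height = 4.5, dpi = 150)
    return(invisible(path))
  }
  p
}

#' Plot the effectiveness-exposure decision plane
#'
#' Scatter of sensitivity runs in the (exposure, summed effectiveness)
#' plane coloured by the difference in times to resistance between the
#' mixture-type strategy and sequential use, with boundary (equal-time)
#' runs highlighted and the fitted decision line overlaid. Purely
#' presentational: all plotted quantities are computed by
#' [compare_strategies()] and [fit_decision_line()].
#'
#' @param labelled Data frame from [compare_strategies()].
#' @param line Optional `decision_line` to overlay (omitted if `NULL`).
#' @param path Optional file path to save to.
#' @return A ggplot object (or `path` invisibly when saving).
#' @export
plot_decision_plane <- function(labelled, line = NULL, path = NULL) {
  df <- labelled[!is.na(labelled$time_diff), , drop = FALSE]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$exposure,
                                        y = .data$effectiveness_sum,
                                        colour = .data$time_diff)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_gradient2(
      low = "darkgreen", mid = "grey85", high = "firebrick", midpoint = 0,
      name = "mixture - sequential\n(generations)"
    ) +
    ggplot2::scale_x_continuous(limits = range(df$exposure)) +
    ggplot2::scale_y_continuous(limits = range(df$effectiveness_sum)) +
    ggplot2::labs(x = "Exposure (proportion of females)",
                  y = "Summed insecticide effectiveness") +
    ggplot2::theme_minimal()
  if (!is.null(line)) {
    p <- p + ggplot2::geom_abline(intercept = line$intercept,
                                  slope = line$slope, colour = "red")
    eq <- df$time_diff == 0
    if (any(eq)) {
      p <- p + ggplot2::geom_point(data = df[eq, , drop = FALSE],
                                   colour = "red", shape = 17, size = 1.6)
    }
  }
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = 7, height = 5, dpi = 150)
    return(invisible(path))
  }
  p
}
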