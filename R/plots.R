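#' Plot a two-group comparison (box plots and Q^(1/3) histograms)
#'
#' Box plots of per-cell medians for each characteristic (whiskers to the
#' extremes, per the reporting convention) and histograms of per-spike
#' cube-root quantal size with the fitted Gaussian overlaid. Requires
#' ggplot2.
#'
#' @param report A `group_comparison` from [group_report()].
#' @param which `"box"` or `"cuberoot"`.
#' @return A ggplot object.
#' @export
plot_group_comparison <- function(report, which = c("box", "cuberoot")) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  which <- match.arg(which)
  cs <- report$cell_summaries
  if (which == "box") {
    med_cols <- grep("^median_", names(cs$control), value = TRUE)
    df <- do.call(rbind, lapply(c("control", "treated"), function(g) {
      do.call(rbind, lapply(med_cols, function(m) {
        data.frame(group = g, metric = sub("^median_", "", m),
                   value = cs[[g]][[m]])
      }))
    }))
    ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$value)) +
      ggplot2::geom_boxplot(coef = Inf) +
      ggplot2::facet_wrap(~metric, scales = "free_y") +
      ggplot2::labs(x = NULL, y = "per-cell median")
  } else {
    fits <- report$cuberoot_fit
    dens <- do.call(rbind, lapply(c("control", "treated"), function(g) {
      f <- fits[[g]]
      if (is.null(f)) return(NULL)
      x <- seq(f$mean - 4 * f$sd, f$mean + 4 * f$sd, length.out = 200)
      data.frame(group = g, x = x, y = stats::dnorm(x, f$mean, f$sd))
    }))
    ggplot2::ggplot(dens, ggplot2::aes(x = .data$x, y = .data$y,
                                       colour = .data$group)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = expression(Q^{1/3} ~ (attomole^{1/3})),
                    y = "fitted Gaussian density")
  }
}
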