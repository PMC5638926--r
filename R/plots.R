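#' Histogram of per-ortholog dN differences
#'
#' Draws the distribution of per-ortholog dN differences between the two
#' endosymbiont lineages with the overall mean marked by a vertical line.
#' Grubbs-flagged outliers are excluded from the display by default (the
#' paired test itself always uses all non-zero differences).
#'
#' @param report An [ErosionReport-class] with delta records.
#' @param bins Number of histogram bins.
#' @param exclude_outliers Drop Grubbs-flagged differences from the plot.
#' @return A ggplot object.
#' @export
plotDeltaHistogram <- function(report, bins = 60, exclude_outliers = TRUE) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotDeltaHistogram requires the ggplot2 package")
  df <- deltaRecords(report)
  if (!nrow(df)) stop("report contains no delta records")
  if (exclude_outliers && !is.null(df$outlier))
    df <- df[!df$outlier, , drop = FALSE]
  m <- mean(deltaRecords(report)$delta)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey55", colour = "grey25") +
    ggplot2::geom_vline(xintercept = m, linewidth = 0.8) +
    ggplot2::labs(x = expression(Delta * dN ~ "(SB1 - SB2)"),
                  y = "orthologous gene pairs") +
    ggplot2::theme_classic()
}
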