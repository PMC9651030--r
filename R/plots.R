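# Optional figures; ggplot2 is only suggested, so each plot checks for it.

utils::globalVariables(c("midpoint", "ratio", "smoothed_log2", "class_"))

#' Plot the male:female coverage-ratio track
#'
#' One panel per chromosome with per-window M:F ratios and, when present,
#' the LOESS-smoothed curve; horizontal guides at 1 (autosomal
#' expectation) and 0.5 (single-copy X expectation).
#'
#' @param track A `ratio_track`, ideally after [loess_smooth()].
#' @return A ggplot object.
#' @export
plot_ratio_track <- function(track) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  p <- ggplot2::ggplot(track, ggplot2::aes(x = midpoint / 1e6, y = ratio)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.5) +
    ggplot2::geom_hline(yintercept = c(0.5, 1), linetype = "dashed",
                        colour = c("firebrick", "grey40")) +
    ggplot2::facet_wrap(~chrom) +
    ggplot2::labs(x = "position (Mb)", y = "male:female depth ratio")
  if ("smoothed_log2" %in% names(track)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(y = 2^smoothed_log2),
                                colour = "steelblue")
  }
  p
}

#' Boxplots of per-gene F:M expression ratios by chromosome class
#'
#' @param fm Result of [fm_ratio_distribution()].
#' @return A ggplot object.
#' @export
plot_fm_ratios <- function(fm) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  df <- fm$ratios
  names(df)[names(df) == "class"] <- "class_"
  ggplot2::ggplot(df, ggplot2::aes(x = class_, y = log2(ratio))) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::geom_hline(yintercept = c(0, 1), linetype = "dashed",
                        colour = c("grey40", "firebrick")) +
    ggplot2::labs(x = NULL, y = "log2 F:M expression ratio")
}
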