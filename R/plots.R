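#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot ROH counts by size class
#'
#' Bar chart of per-sample ROH counts stacked by size class (small, medium,
#' large), the standard way to compare homozygosity landscapes across
#' individuals.
#'
#' @param object A `roh_scan` from [scan_all()].
#' @param small_max_bp,large_min_bp Size-class bounds; see [classify_sizes()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot roh_scan
#' @export
autoplot.roh_scan <- function(object, small_max_bp = 59000,
                              large_min_bp = 400000, ...) {
  segs <- classify_sizes(object$segments, small_max_bp, large_min_bp)
  counts <- dplyr::count(segs, .data$sample, .data$size_class)
  ggplot2::ggplot(counts,
                  ggplot2::aes(x = .data$sample, y = .data$n,
                               fill = .data$size_class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Number of ROH", fill = "Size class") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot Tajima's D along a chromosome
#'
#' Line of windowed Tajima's D with the flagging threshold and, when given,
#' the ROH intervals shaded -- the classic view of a selective-sweep
#' candidate region where D drops inside a consensus ROH.
#'
#' @param windows Tibble from [neutrality_scan()] (optionally through
#'   [flag_roh_windows()]).
#' @param intervals Optional interval tibble to shade.
#' @param threshold Horizontal reference line.
#' @return A ggplot object.
#' @export
plot_tajima_d <- function(windows, intervals = NULL, threshold = -1.2) {
  windows <- dplyr::mutate(windows, mid = (.data$start + .data$end) / 2)
  p <- ggplot2::ggplot(windows,
                       ggplot2::aes(x = .data$mid / 1e6, y = .data$tajima_D))
  if (!is.null(intervals) && nrow(intervals) > 0) {
    p <- p + ggplot2::geom_rect(
      data = intervals,
      ggplot2::aes(xmin = .data$start / 1e6, xmax = .data$end / 1e6),
      ymin = -Inf, ymax = Inf, fill = "grey85", inherit.aes = FALSE)
  }
  p +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2,
                        colour = "firebrick") +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(size = 0.6, na.rm = TRUE) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "Position (Mb)", y = "Tajima's D") +
    ggplot2::theme_minimal()
}
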