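#' Plot excised-length distributions
#'
#' Reference IES lengths against alternatively excised (internal/external)
#' and cryptic lengths, 1-bp bins, free y scales. The suppressed "forbidden"
#' window can be shaded.
#'
#' @param histograms tibble from [excision_length_histograms()].
#' @param forbidden_window optional inclusive window to shade.
#' @param max_length x-axis limit (bp).
#' @return a ggplot object.
#' @export
plot_length_histograms <- function(histograms, forbidden_window = c(32, 38),
                                   max_length = 120) {
  d <- histograms[histograms$length <= max_length, ]
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$length, y = .data$count)) +
    ggplot2::geom_col(width = 1, fill = "grey25") +
    ggplot2::facet_wrap(~component, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "excised length (bp)", y = "reads") +
    ggplot2::theme_bw()
  if (!is.null(forbidden_window)) {
    p <- p + ggplot2::annotate("rect", xmin = forbidden_window[1] - 0.5,
                               xmax = forbidden_window[2] + 0.5,
                               ymin = -Inf, ymax = Inf, alpha = 0.15,
                               fill = "red")
  }
  p
}

#' Plot the boundary-offset distribution of alternative excision
#'
#' @param offsets list from [boundary_offset_distribution()].
#' @param max_abs_offset x-axis limit.
#' @return a ggplot object.
#' @export
plot_boundary_offsets <- function(offsets, max_abs_offset = 40) {
  d <- offsets$length_offset
  d <- d[abs(d$offset) <= max_abs_offset, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$offset, y = .data$count)) +
    ggplot2::geom_col(width = 1, fill = "grey25") +
    ggplot2::labs(x = "excised length - reference IES length (bp)",
                  y = "reads") +
    ggplot2::theme_bw()
}

#' Plot retention-stratified nucleosome-density distributions
#'
#' @param strata list from [stratified_density_distributions()].
#' @param bins histogram bin count.
#' @return a ggplot object.
#' @export
plot_density_strata <- function(strata, bins = 40) {
  ggplot2::ggplot(strata$values,
                  ggplot2::aes(x = .data$r, fill = .data$group)) +
    ggplot2::geom_histogram(bins = bins, alpha = 0.6,
                            position = "identity") +
    ggplot2::facet_wrap(~stratum, scales = "free") +
    ggplot2::labs(x = "normalized nucleosome density r", y = "IESs",
                  fill = "retention") +
    ggplot2::theme_bw()
}

#' Plot the paired-end outer-distance histogram
#'
#' @param hist tibble from [fragment_length_histogram()].
#' @param bounds optional vertical guides (e.g., the mononucleosome filter).
#' @return a ggplot object.
#' @export
plot_fragment_lengths <- function(hist, bounds = c(100, 175)) {
  p <- ggplot2::ggplot(hist, ggplot2::aes(x = .data$outer,
                                          y = .data$density)) +
    ggplot2::geom_col(width = 1, fill = "grey25") +
    ggplot2::labs(x = "outer distance (bp)", y = "density") +
    ggplot2::theme_bw()
  if (!is.null(bounds)) {
    p <- p + ggplot2::geom_vline(xintercept = bounds, linetype = "dashed",
                                 colour = "red")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot an analysis: excised-length distributions
#'
#' @param object an `ies_analysis`.
#' @param ... passed to [plot_length_histograms()].
#' @return a ggplot object.
#' @export
autoplot.ies_analysis <- function(object, ...) {
  plot_length_histograms(object$excision$histograms, ...)
}
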