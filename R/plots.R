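# ggplot2 views of the main result types.

#' Plot a windowed density profile
#'
#' @param profile A `density_profile` from [window_density()].
#' @param log_y Use a log10 y scale (small-density windows stay visible).
#' @return A ggplot.
#' @export
plot_density_profile <- function(profile, log_y = FALSE) {
  p <- ggplot2::ggplot(profile,
                       ggplot2::aes(x = (.data$start + .data$end) / 2e6,
                                    y = .data$density)) +
    ggplot2::geom_col(width = (profile$end[1] - profile$start[1]) / 1e6,
                      fill = "grey30") +
    ggplot2::labs(x = "position (Mbp)", y = "variants / Kbp",
                  title = "Windowed polymorphism density") +
    ggplot2::facet_wrap(~chrom, ncol = 1)
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' @exportS3Method ggplot2::autoplot
autoplot.density_profile <- function(object, ...) {
  plot_density_profile(object, ...)
}

#' Plot a methylation profile
#'
#' Recovered fraction of in-silico predicted restriction sites per window;
#' high recovery marks unmethylated (typically genic, euchromatic) DNA.
#'
#' @param profile A `methylation_profile`.
#' @return A ggplot.
#' @export
plot_methylation_profile <- function(profile) {
  ggplot2::ggplot(dplyr::filter(profile, !is.na(.data$fraction)),
                  ggplot2::aes(x = (.data$start + .data$end) / 2e6,
                               y = 100 * .data$fraction)) +
    ggplot2::geom_line(color = "firebrick") +
    ggplot2::labs(x = "position (Mbp)", y = "% predicted sites recovered",
                  title = "Tag recovery (inverse methylation) profile") +
    ggplot2::facet_wrap(~chrom, ncol = 1)
}

#' @exportS3Method ggplot2::autoplot
autoplot.methylation_profile <- function(object, ...) {
  plot_methylation_profile(object)
}

#' Plot haplotype blocks as colored mosaics
#'
#' @param blocks Block tibble from [segment_blocks()] (optionally with a
#'   `line` column for multiple lines).
#' @return A ggplot.
#' @export
plot_haplotype_blocks <- function(blocks) {
  if (!"line" %in% names(blocks)) blocks$line <- "line"
  ggplot2::ggplot(blocks) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$boundary_start / 1e6, xmax = .data$boundary_end / 1e6,
      ymin = 0, ymax = 1, fill = .data$founder)) +
    ggplot2::facet_grid(line ~ chrom) +
    ggplot2::labs(x = "position (Mbp)", y = NULL,
                  title = "Haplotype origin mosaic") +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.ticks.y = ggplot2::element_blank())
}

#' Marey-style plot of a genetic map
#'
#' Cumulative genetic position against physical position per chromosome; the
#' flat stretch marks the recombination-suppressed pericentromere.
#'
#' @param object A `genetic_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.genetic_map <- function(object, ...) {
  ggplot2::ggplot(object$markers,
                  ggplot2::aes(x = .data$pos / 1e6, y = .data$cM)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::facet_wrap(~chrom, scales = "free") +
    ggplot2::labs(x = "physical position (Mbp)", y = "genetic position (cM)",
                  title = "Genetic vs physical marker positions")
}

#' Plot an UPGMA tree (with bootstrap supports if present)
#'
#' @param x An `upgma_tree`.
#' @param ... Passed to [ape::plot.phylo].
#' @return Invisibly, the `phylo` object plotted.
#' @export
plot.upgma_tree <- function(x, ...) {
  ph <- x$phylo
  ape::plot.phylo(ph, ...)
  if (!is.null(ph$node.label)) {
    ape::nodelabels(ph$node.label, frame = "none", adj = c(1.2, -0.3),
                    cex = 0.8)
  }
  invisible(ph)
}
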