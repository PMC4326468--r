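#' Plot a genome-wide copy-number profile
#'
#' Scatter of per-bin copy-number ratios along a concatenated genome
#' coordinate, chromosomes in alternating shades, with guide lines at copy
#' numbers 1, 2 and 3 — the digital-karyotype view of one embryo. For an
#' `embryo_result`, segment means and the dynamic calling thresholds are
#' overlaid.
#'
#' @param object A [bin_profile] or `embryo_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @name plot-profiles
NULL

genome_axis <- function(genome) {
  chroms <- genome$chromosomes
  offsets <- cumsum(c(0, head(chroms$length, -1)))
  tibble(chrom = chroms$chrom, offset = offsets,
         mid = offsets + chroms$length / 2)
}

#' @rdname plot-profiles
#' @export
autoplot.bin_profile <- function(object, ...) {
  ax <- genome_axis(object$genome)
  bins <- dplyr::left_join(object$bins, ax, by = "chrom")
  bins$pos <- bins$start + bins$offset
  bins$shade <- factor(match(bins$chrom, ax$chrom) %% 2)
  ggplot2::ggplot(bins, ggplot2::aes(x = .data$pos, y = .data$cn_ratio)) +
    ggplot2::geom_hline(yintercept = c(1, 2, 3), linetype = "dotted",
                        colour = "grey55") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$shade), size = 0.6,
                        show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c("grey35", "steelblue4")) +
    ggplot2::scale_x_continuous(breaks = ax$mid,
                                labels = strip_chr(ax$chrom),
                                expand = c(0.01, 0)) +
    ggplot2::coord_cartesian(ylim = c(0, 4)) +
    ggplot2::labs(x = NULL, y = "copy-number ratio",
                  title = object$sample_id) +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.grid.major.x = ggplot2::element_blank(),
                   panel.grid.minor = ggplot2::element_blank())
}

#' @rdname plot-profiles
#' @export
autoplot.embryo_result <- function(object, ...) {
  p <- autoplot(object$profile)
  ax <- genome_axis(object$profile$genome)
  seg <- dplyr::left_join(object$segments, ax, by = "chrom")
  p +
    ggplot2::geom_hline(yintercept = c(object$thresholds$gain_cut,
                                       object$thresholds$loss_cut),
                        linetype = "dashed", colour = "darkred",
                        linewidth = 0.3) +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$start_bp + .data$offset,
                   xend = .data$end_bp + .data$offset,
                   y = .data$mean_cn, yend = .data$mean_cn),
      colour = "orange", linewidth = 1.1, inherit.aes = FALSE) +
    ggplot2::labs(subtitle = paste0(object$classification,
                                    if (length(object$karyotype_strings))
                                      paste0(": ",
                                             paste(object$karyotype_strings,
                                                   collapse = "; "))
                                    else ""))
}
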