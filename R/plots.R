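#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Graphical genotype of the population
#'
#' Draws every line's donor introgression segments along the physical
#' map, one row per line, faceted by chromosome — the standard
#' graphical-genotype view of an introgression population.
#'
#' @param segments Segment tibble from [call_introgressions()].
#' @param chrom_lengths Chromosome-length tibble (sets panel extents).
#' @return A ggplot object.
#' @export
plot_introgressions <- function(segments, chrom_lengths) {
  seg <- dplyr::mutate(segments,
                       line = factor(.data$line_id, levels = rev(unique(.data$line_id))))
  frame <- dplyr::mutate(chrom_lengths, line = seg$line[1])
  ggplot2::ggplot(seg) +
    ggplot2::geom_blank(data = frame,
                        ggplot2::aes(x = .data$length_bp / 1e6, y = .data$line)) +
    ggplot2::geom_segment(ggplot2::aes(
      x = .data$start_bp / 1e6, xend = .data$end_bp / 1e6,
      y = .data$line, yend = .data$line, colour = .data$zygosity),
      linewidth = 1.5) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (Mbp)", y = NULL, colour = "zygosity") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 5))
}

#' LOD curves of a QTL scan
#'
#' @param object A `bil_scan` object.
#' @param traits Optional subset of trait ids to draw.
#' @param ... Unused.
#' @return A ggplot object: LOD against physical position, one facet
#'   row per trait, colour by chromosome; detected peaks are marked.
#' @export
autoplot.bil_scan <- function(object, traits = NULL, ...) {
  cv <- scan_curves(object)
  if (!is.null(traits)) cv <- cv[cv$trait_id %in% traits, ]
  xcol <- if ("pos_bp" %in% names(cv)) cv$pos_bp else (cv$start_bp + cv$end_bp) / 2
  cv$x_mb <- xcol / 1e6
  qt <- tidy(object)
  if (!is.null(traits)) qt <- qt[qt$trait_id %in% traits, ]
  ggplot2::ggplot(cv, ggplot2::aes(x = .data$x_mb, y = .data$lod)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$chrom), na.rm = TRUE) +
    ggplot2::geom_point(data = qt,
                        ggplot2::aes(x = .data$peak_bp / 1e6, y = .data$lod),
                        colour = "red", size = 1.5) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$trait_id),
                        cols = ggplot2::vars(.data$chrom),
                        scales = "free", space = "free_x") +
    ggplot2::labs(x = "position (Mbp)", y = "LOD") +
    ggplot2::theme_minimal(base_size = 9)
}

#' Metabolite fold-change heat map
#'
#' Lines by metabolites, log2 colour scale centred on the control
#' (fold change 1 = 0).
#'
#' @param foldchanges A `bil_foldchange` tibble from
#'   [normalize_to_control()].
#' @return A ggplot object.
#' @export
plot_metabolite_heatmap <- function(foldchanges) {
  wide <- heatmap_matrix(foldchanges)
  long <- tidyr::pivot_longer(wide, -"line_id",
                              names_to = "trait_id", values_to = "log2_fc")
  long$line <- factor(long$line_id, levels = rev(unique(wide$line_id)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$trait_id, y = .data$line,
                                     fill = .data$log2_fc)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  midpoint = 0, name = "log2 fold") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal(base_size = 8) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1,
                                                       vjust = 0.5),
                   axis.text.y = ggplot2::element_text(size = 5))
}
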