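#' Inter-mutation distances for a rainfall plot
#'
#' For every SNV except the first on each chromosome, the distance to the
#' previous SNV (in the pooled set) and its log2. Duplicated pooled
#' positions give distance 0; their log2 is clamped to the plot floor of -1
#' and flagged.
#'
#' @param pooled An [snv_set], sorted by (chrom, pos).
#' @return A tibble with `chrom`, `pos`, `dist_prev`, `log2_dist`, `mclass`,
#'   `zero_distance`.
#' @examples
#' s <- snv_set("chrI", c(100, 228), c("C", "C"), c("T", "T"))
#' rainfall_points(s)$log2_dist  # 7
#' @export
rainfall_points <- function(pooled) {
  df <- dplyr::arrange(tibble::as_tibble(pooled), .data$chrom, .data$pos)
  df <- dplyr::mutate(
    dplyr::group_by(df, .data$chrom),
    dist_prev = .data$pos - dplyr::lag(.data$pos)
  )
  df <- dplyr::filter(dplyr::ungroup(df), !is.na(.data$dist_prev))
  df$zero_distance <- df$dist_prev == 0
  df$log2_dist <- ifelse(df$zero_distance, -1, log2(df$dist_prev))
  df[, c("chrom", "pos", "dist_prev", "log2_dist", "mclass", "zero_distance")]
}

#' Render a modified rainfall plot
#'
#' One panel per chromosome: X is the chromosomal coordinate, Y the log2
#' distance to the previous mutation; points are colored by mutation class
#' (C->T red, G->A blue, other grey). Horizontal guide lines mark the 10,
#' 100, 500 (magenta) and 1000 bp distances; masked regions and assembly
#' gaps can be drawn as vertical bands, and regions of interest highlighted.
#'
#' @param points A tibble from [rainfall_points()].
#' @param path Output image path (`.pdf`, `.png` or `.svg`).
#' @param masks,gaps Optional `GRanges` drawn as light/dark grey bands.
#' @param highlights Optional `GRanges` (or "chr:start-end" strings) drawn
#'   as gold bands.
#' @param guide_lines Distances (bp) for the horizontal guides.
#' @param width,height Device size in inches.
#' @return `path`, invisibly.
#' @export
render_rainfall <- function(points, path, masks = NULL, gaps = NULL,
                            highlights = NULL,
                            guide_lines = c(10, 100, 500, 1000),
                            width = 10, height = 6) {
  band_df <- function(gr, fill) {
    if (is.null(gr)) return(NULL)
    if (is.character(gr)) gr <- GenomicRanges::GRanges(gr)
    if (!length(gr)) return(NULL)
    data.frame(
      chrom = as.character(GenomeInfoDb::seqnames(gr)),
      xmin = GenomicRanges::start(gr), xmax = GenomicRanges::end(gr),
      fill = fill
    )
  }
  p <- ggplot2::ggplot()
  for (b in list(band_df(masks, "grey80"), band_df(gaps, "grey40"),
                 band_df(highlights, "gold"))) {
    if (!is.null(b) && nrow(b)) {
      p <- p + ggplot2::geom_rect(
        data = b,
        ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax),
        ymin = -Inf, ymax = Inf, fill = b$fill, alpha = 0.5
      )
    }
  }
  guides_col <- ifelse(guide_lines == 500, "magenta", "grey30")
  p <- p + ggplot2::geom_hline(yintercept = log2(guide_lines),
                               colour = guides_col, linewidth = 0.3)
  if (nrow(points)) {
    p <- p +
      ggplot2::geom_point(
        data = points,
        ggplot2::aes(x = .data$pos, y = .data$log2_dist, colour = .data$mclass),
        size = 0.6, alpha = 0.8
      ) +
      ggplot2::facet_wrap(~chrom, scales = "free_x") +
      ggplot2::scale_colour_manual(
        values = c(CT = "red", GA = "blue", OTHER = "grey50"),
        name = "class",
        labels = c(CT = "C>T", GA = "G>A", OTHER = "other")
      )
  }
  p <- p +
    ggplot2::labs(x = "chromosomal coordinate (bp)",
                  y = "log2 distance to previous SNV (bp)") +
    ggplot2::theme_bw()
  suppressMessages(ggplot2::ggsave(path, p, width = width, height = height))
  invisible(path)
}
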