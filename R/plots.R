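#' @importFrom ggplot2 autoplot ggplot aes geom_step geom_segment geom_point
#'   geom_rect geom_col geom_errorbar labs theme_minimal facet_wrap
NULL

#' @export
ggplot2::autoplot

#' Plot a window track (GC content or similarity scores)
#'
#' @param object A `window_track` from [gc_windows()] or
#'   [window_similarity()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.window_track <- function(object, ...) {
  df <- as_tibble(object)[!object$partial, ]
  ggplot(df, aes(x = (.data$start + .data$end) / 2, y = .data$value)) +
    geom_step() +
    labs(x = "position (bp)", y = "window value") +
    theme_minimal()
}

#' Plot synteny blocks and their anchors
#'
#' Anchors are drawn as segments from A to B coordinates, coloured by
#' relative orientation; block extents are shaded along the A axis.
#'
#' @param object A `synteny_blocks` from [detect_blocks()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.synteny_blocks <- function(object, ...) {
  anchors <- object$anchors
  blocks <- object$blocks
  p <- ggplot(anchors) +
    geom_segment(aes(x = .data$pos_a, xend = .data$pos_b, y = 1, yend = 0,
                     colour = .data$rel_orientation)) +
    labs(x = "position (bp)", y = NULL, colour = "orientation") +
    theme_minimal()
  if (nrow(blocks)) {
    p <- p + geom_rect(data = blocks,
                       aes(xmin = .data$a_start, xmax = .data$a_end,
                           ymin = 1.02, ymax = 1.08,
                           fill = .data$orientation),
                       inherit.aes = FALSE, alpha = 0.6)
  }
  p
}

#' Plot per-gene dS estimates with bootstrap standard errors
#'
#' @param ds_table A tibble from [trio_divergence()] (`ds_table` element).
#' @return A ggplot; undefined estimates are omitted.
#' @export
plot_ds_estimates <- function(ds_table) {
  df <- ds_table[ds_table$status == "ok", ]
  ggplot(df, aes(x = .data$gene, y = .data$dS, fill = .data$comparison)) +
    geom_col(position = "dodge") +
    geom_errorbar(aes(ymin = .data$dS - .data$SE_dS,
                      ymax = .data$dS + .data$SE_dS),
                  position = "dodge", width = 0.3, na.rm = TRUE) +
    labs(x = NULL, y = "dS (NG86 + JC)") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot per-CDS GC against the genome mean
#'
#' @param cds_gc_tbl A tibble from [cds_gc()].
#' @return A ggplot with a dashed line at the genome-wide GC.
#' @export
plot_cds_gc <- function(cds_gc_tbl) {
  gmean <- attr(cds_gc_tbl, "genome_gc")
  ggplot(cds_gc_tbl, aes(x = seq_len(nrow(cds_gc_tbl)), y = .data$gc,
                         colour = .data$contig)) +
    geom_point() +
    ggplot2::geom_hline(yintercept = gmean, linetype = "dashed",
                        colour = "red") +
    labs(x = "gene index", y = "CDS GC (%)") +
    theme_minimal()
}
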