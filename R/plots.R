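# ggplot2 helpers for the main result types.

#' Scatter plot comparing two expression tables
#'
#' @param a,b `expression_table` tibbles (e.g. gene-level vs transcript-
#'   direct quantification, or two samples).
#' @param cell cell id shared by both tables (default: first shared cell).
#' @param value column to plot (`"rpg10k"` or `"count"`).
#' @return a ggplot.
#' @export
plot_expression_correlation <- function(a, b, cell = NULL, value = "rpg10k") {
  cell <- cell %||% intersect(unique(a$cell_id), unique(b$cell_id))[1]
  j <- inner_join(a |> filter(.data$cell_id == cell),
                  b |> filter(.data$cell_id == cell),
                  by = "feature_id", suffix = c("_a", "_b"))
  r <- cor(j[[paste0(value, "_a")]], j[[paste0(value, "_b")]])
  ggplot2::ggplot(j, ggplot2::aes(x = .data[[paste0(value, "_a")]],
                                  y = .data[[paste0(value, "_b")]])) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey50") +
    ggplot2::labs(title = sprintf("%s: Pearson r = %.3f", cell, r),
                  x = paste(value, "(A)"), y = paste(value, "(B)")) +
    ggplot2::theme_minimal()
}

#' Feature bins along a locus
#'
#' TSS/TES and splice-site bins drawn as ticks along the genomic axis,
#' optionally over the annotated exon structure.
#'
#' @param end_bins,splice_bins bin tibbles from the detection steps.
#' @param annotation optional `toy_annotation` for exon tracks.
#' @param chrom chromosome to draw (default: first seen).
#' @return a ggplot.
#' @export
plot_locus_features <- function(end_bins, splice_bins = NULL,
                                annotation = NULL, chrom = NULL) {
  bins <- bind_rows(
    end_bins |> select(any_of(c("chrom", "start", "end", "type", "support"))),
    if (!is.null(splice_bins) && nrow(splice_bins) > 0)
      splice_bins |> select(any_of(c("chrom", "start", "end", "type",
                                     "support")))
  )
  chrom <- chrom %||% bins$chrom[1]
  bins <- bins |> filter(.data$chrom == !!chrom)
  p <- ggplot2::ggplot(bins) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$start, xmax = .data$end,
                                    ymin = 1, ymax = 1 + .data$support,
                                    fill = .data$type)) +
    ggplot2::labs(x = paste(chrom, "(bp)"), y = "read support",
                  fill = "feature") +
    ggplot2::theme_minimal()
  if (!is.null(annotation)) {
    tx <- annotation$transcripts |> filter(.data$chrom == !!chrom)
    ex <- bind_rows(lapply(seq_len(nrow(tx)), function(i) {
      e <- tx$exons[[i]]
      tibble(start = e[, 1], end = e[, 2], tx = tx$transcript_id[i],
             y = -i)
    }))
    p <- p + ggplot2::geom_segment(
      data = ex, ggplot2::aes(x = .data$start, xend = .data$end,
                              y = .data$y, yend = .data$y),
      linewidth = 2, colour = "grey40")
  }
  p
}

#' Per-cell isoform usage for one gene
#'
#' @param iso_counts long tibble from [quantify_isoforms()].
#' @param locus locus/gene id to draw (default: first).
#' @return a stacked proportion bar chart (ggplot).
#' @export
plot_isoform_usage <- function(iso_counts, locus = NULL) {
  locus <- locus %||% iso_counts$locus[1]
  d <- iso_counts |> filter(.data$locus == !!locus)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$cell_id, y = .data$count,
                                  fill = .data$group_id)) +
    ggplot2::geom_col(position = "fill") +
    ggplot2::labs(title = locus, x = NULL, y = "isoform fraction",
                  fill = "isoform group") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1),
                   legend.position = "bottom")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot method for differential-usage results
#'
#' Volcano-style view: chi-square statistic against -log10 adjusted p, the
#' significance threshold drawn at alpha.
#'
#' @param object an `iso_usage_test`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.iso_usage_test <- function(object, ...) {
  alpha <- attr(object, "alpha") %||% 0.001
  d <- as_tibble(object) |>
    mutate(mlogp = -log10(pmax(.data$adj_p, 1e-300)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$statistic, y = .data$mlogp,
                                  colour = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::labs(x = "chi-square statistic", y = "-log10 adjusted p",
                  colour = paste("adj p <=", alpha)) +
    ggplot2::theme_minimal()
}
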