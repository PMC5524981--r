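# Complex-isoform genes and differential isoform usage across cells.
#
# A gene expresses complex isoforms when it has alternative TSS/TES (>= 2 TSS
# bins or >= 2 TES bins) as well as at least one alternative splicing event.
# Differential usage is tested per gene with a Pearson chi-square contingency
# test on the cells x isoforms count table (Yates continuity correction on
# 2x2 tables, as in the reference implementation), with Holm-Sidak step-down
# correction across genes at alpha = 0.001.

#' Identify genes expressing complex isoforms
#'
#' @param feature_genes output of [assign_features_to_genes()] on classified
#'   end bins (needs `type` and `gene_id`).
#' @param event_genes tibble (gene_id, event_id) linking alternative-splicing
#'   events to genes (see [events_to_genes()]).
#' @return tibble (gene_id, n_tss, n_tes, n_events, complex).
#' @export
find_complex_isoform_genes <- function(feature_genes, event_genes) {
  ends <- feature_genes |>
    filter(!is.na(.data$gene_id), .data$type %in% c("TSS", "TES")) |>
    count(.data$gene_id, .data$type) |>
    tidyr::pivot_wider(names_from = "type", values_from = "n",
                       values_fill = 0L)
  for (col in c("TSS", "TES")) if (!col %in% names(ends)) ends[[col]] <- 0L
  ev <- event_genes |> filter(!is.na(.data$gene_id)) |>
    count(.data$gene_id, name = "n_events")
  ends |>
    rename(n_tss = "TSS", n_tes = "TES") |>
    full_join(ev, by = "gene_id") |>
    mutate(across(c("n_tss", "n_tes", "n_events"), ~ tidyr::replace_na(.x, 0L)),
           complex = (.data$n_tss >= 2 | .data$n_tes >= 2) &
             .data$n_events >= 1)
}

#' Assign alternative-splicing events to genes
#'
#' An event belongs to the gene(s) whose slopped span contains its
#' representative position (the shared splice-site anchor, the intron
#' midpoint, or the skipped-exon midpoint).
#'
#' @param events event tibble from [call_alt_events()].
#' @param splice_bins splice bins (for anchor lookup of shared bins).
#' @param models gene models.
#' @param params a [pipeline_params()] object.
#' @return tibble (gene_id, event_id, type).
#' @export
events_to_genes <- function(events, splice_bins, models,
                            params = pipeline_params()) {
  if (nrow(events) == 0) {
    return(tibble(gene_id = character(), event_id = character(),
                  type = character()))
  }
  anchors <- setNames(splice_bins$anchor, splice_bins$bin_id)
  slop <- params$gene_slop
  spans <- models |> mutate(
    span_start = vapply(.data$exons, function(e) min(e[, 1]), numeric(1)) - slop,
    span_end = vapply(.data$exons, function(e) max(e[, 2]), numeric(1)) + slop)
  out <- lapply(seq_len(nrow(events)), function(i) {
    ev <- events[i, ]
    pos <- switch(ev$type,
                  alt5 = , alt3 = unname(anchors[ev$shared_bin]),
                  intron_retention = (ev$intron_start + ev$intron_end) %/% 2,
                  exon_skipping = (ev$exon_start + ev$exon_end) %/% 2)
    g <- spans |> filter(.data$chrom == ev$chrom, .data$span_start <= pos,
                         .data$span_end > pos)
    if (nrow(g) == 0) {
      return(tibble(gene_id = NA_character_, event_id = ev$event_id,
                    type = ev$type))
    }
    tibble(gene_id = g$gene_id, event_id = ev$event_id, type = ev$type)
  })
  bind_rows(out)
}

#' Chi-square contingency test
#'
#' Pearson chi-square on a counts matrix with expected values from the
#' row/column marginals; 2x2 tables use the Yates continuity correction by
#' default. Degenerate tables (an all-zero row or column) raise an error
#' naming the offender.
#'
#' @param tab integer matrix (>= 2 rows and >= 2 columns).
#' @param correct apply continuity correction on 2x2 tables?
#' @return list (statistic, dof, p_value, expected).
#' @export
chi2_contingency <- function(tab, correct = TRUE) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2) abort("table must be at least 2x2")
  if (any(tab < 0)) abort("counts must be non-negative")
  zr <- which(rowSums(tab) == 0); zc <- which(colSums(tab) == 0)
  if (length(zr)) abort(sprintf("row %d has zero marginal total", zr[1]))
  if (length(zc)) abort(sprintf("column %d has zero marginal total", zc[1]))
  res <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = unname(res$statistic), dof = unname(res$parameter),
       p_value = unname(res$p.value), expected = res$expected)
}

#' Holm-Sidak step-down multiple-testing correction
#'
#' P values are sorted ascending; the i-th smallest is adjusted to
#' `1 - (1 - p)^(m - i + 1)`, enforced monotone non-decreasing, and declared
#' significant while adjusted values stay at or below `alpha` (step-down
#' stopping).
#'
#' @param p numeric vector of p values in `[0, 1]`.
#' @param alpha family-wise error rate.
#' @return tibble (p, adj_p, significant) in the input order.
#' @export
holm_sidak <- function(p, alpha = 0.001) {
  if (length(p) == 0) {
    return(tibble(p = numeric(), adj_p = numeric(), significant = logical()))
  }
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p values must lie in [0, 1]")
  if (alpha <= 0 || alpha >= 1) abort("alpha must lie in (0, 1)")
  m <- length(p)
  ord <- order(p)
  adj_sorted <- 1 - (1 - p[ord])^(m - seq_len(m) + 1)
  adj_sorted <- pmin(1, cummax(adj_sorted))
  adj <- numeric(m); adj[ord] <- adj_sorted
  sig_sorted <- cumall(adj_sorted <= alpha)
  sig <- logical(m); sig[ord] <- sig_sorted
  tibble(p = p, adj_p = adj, significant = sig)
}

cumall <- function(x) cumprod(as.integer(x)) > 0

#' Test differential isoform usage across cells
#'
#' One chi-square contingency test per gene on its cells x isoforms count
#' table (all-zero rows/columns dropped first), Holm-Sidak corrected across
#' all testable genes. Genes whose table collapses below 2x2 are skipped
#' with a reason.
#'
#' @param iso_counts long tibble (locus, group_id, cell_id, count) from
#'   [quantify_isoforms()]; `locus` is treated as the gene.
#' @param genes optional character vector restricting the tested loci (e.g.
#'   complex-isoform genes).
#' @param alpha family-wise error rate (default 0.001).
#' @param correct Yates correction on 2x2 tables?
#' @return `iso_usage_test` tibble (gene_id, statistic, dof, p_value, adj_p,
#'   significant), sorted by adjusted p, with attributes `skipped` (tibble of
#'   untestable genes and reasons) and `alpha`.
#' @export
test_differential_usage <- function(iso_counts, genes = NULL, alpha = 0.001,
                                    correct = TRUE) {
  if (!is.null(genes)) iso_counts <- iso_counts |>
      filter(.data$locus %in% genes)
  loci <- unique(iso_counts$locus)
  rows <- list(); skipped <- list()
  for (g in loci) {
    tab <- iso_counts |> filter(.data$locus == g) |>
      tidyr::pivot_wider(names_from = "group_id", values_from = "count",
                         values_fill = 0L) |>
      select(-"locus")
    m <- as.matrix(tab[, -1, drop = FALSE])
    rownames(m) <- tab$cell_id
    m <- m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
    if (nrow(m) < 2 || ncol(m) < 2) {
      skipped[[length(skipped) + 1L]] <- tibble(
        gene_id = g,
        reason = if (ncol(m) < 2) "fewer than 2 isoforms with counts"
        else "fewer than 2 cells with counts")
      next
    }
    ct <- chi2_contingency(m, correct = correct)
    rows[[length(rows) + 1L]] <- tibble(
      gene_id = g, statistic = ct$statistic, dof = ct$dof,
      p_value = ct$p_value,
      min_expected = min(ct$expected))
  }
  res <- if (length(rows)) bind_rows(rows) else
    tibble(gene_id = character(), statistic = numeric(), dof = numeric(),
           p_value = numeric(), min_expected = numeric())
  hs <- holm_sidak(res$p_value, alpha)
  res <- res |> mutate(adj_p = hs$adj_p, significant = hs$significant) |>
    arrange(.data$adj_p, .data$gene_id)
  if (any(res$min_expected < 5)) {
    warn(sprintf("%d gene(s) have expected counts < 5; chi-square p values are approximate",
                 sum(res$min_expected < 5)))
  }
  structure(res, class = c("iso_usage_test", class(res)),
            skipped = bind_rows(skipped), alpha = alpha)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a differential-usage result
#' @param x an `iso_usage_test`.
#' @param ... unused.
#' @return the underlying tibble (one row per tested gene).
#' @export
tidy.iso_usage_test <- function(x, ...) {
  as_tibble(x)
}

#' One-row summary of a differential-usage run
#' @param x an `iso_usage_test`.
#' @param ... unused.
#' @return tibble (n_tested, n_significant, n_skipped, alpha).
#' @export
glance.iso_usage_test <- function(x, ...) {
  tibble(n_tested = nrow(x),
         n_significant = sum(x$significant),
         n_skipped = nrow(attr(x, "skipped") %||% tibble()),
         alpha = attr(x, "alpha"))
}
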