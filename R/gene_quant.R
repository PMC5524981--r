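# Gene-level and transcript-direct expression quantification.
#
# A read counts for a gene when at least one of its alignment blocks overlaps
# at least one exon base of that gene; values are normalized as Reads Per
# Gene per 10,000 aligned reads (RPG10K = gene reads / aligned reads x 1e4).
# No gene-length normalization is performed anywhere: full-length reads make
# counts length-free.

#' Gene models from a toy annotation
#'
#' @param annotation a `toy_annotation`.
#' @return tibble (gene_id, chrom, strand, exons) with merged exon intervals
#'   (0-based half-open matrices).
#' @export
gene_models <- function(annotation) {
  annotation$transcripts |>
    group_by(.data$gene_id, .data$chrom, .data$strand) |>
    summarise(exons = list(merge_intervals(do.call(rbind, .data$exons))),
              .groups = "drop")
}

merge_intervals <- function(ex) {
  ex <- ex[order(ex[, 1]), , drop = FALSE]
  ir <- IRanges::reduce(IRanges::IRanges(start = ex[, 1] + 1L, end = ex[, 2]))
  cbind(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

#' Gene models from a GTF file
#'
#' @param path GTF file with exon features carrying `gene_id`.
#' @return tibble as from [gene_models()].
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0) abort("annotation contains no exon features")
  tibble(
    gene_id = gr$gene_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  ) |>
    group_by(.data$gene_id, .data$chrom, .data$strand) |>
    summarise(exons = list(merge_intervals(cbind(.data$start, .data$end))),
              .groups = "drop")
}

gene_exons_granges <- function(models) {
  n <- vapply(models$exons, nrow, integer(1))
  ex <- do.call(rbind, models$exons)
  gr <- GenomicRanges::GRanges(
    seqnames = rep(models$chrom, n),
    ranges = IRanges::IRanges(start = ex[, 1] + 1L, end = ex[, 2]))
  S4Vectors::mcols(gr)$gene_id <- rep(models$gene_id, n)
  gr
}

#' Count reads overlapping gene exons
#'
#' A read is counted for every gene whose merged exons overlap one of its
#' alignment blocks by at least one base (strand is ignored: reads are
#' unstranded before trimming). With `unique_gene = TRUE` reads touching the
#' exons of more than one gene are discarded instead.
#'
#' @param aln filtered alignment tibble (one alignment per read).
#' @param models gene models from [gene_models()] or [read_gene_models()].
#' @param read_cells optional tibble (read_id, cell_id) for per-cell counts;
#'   reads without a cell fall into sample `"all"`.
#' @param unique_gene drop reads overlapping several genes?
#' @return tibble (gene_id, cell_id, count), complete over genes x cells.
#' @export
count_reads_per_gene <- function(aln, models, read_cells = NULL,
                                 unique_gene = FALSE) {
  if (nrow(models) == 0) abort("empty annotation")
  blocks <- blocks_granges(aln)
  exons <- gene_exons_granges(models)
  hits <- GenomicRanges::findOverlaps(blocks, exons, minoverlap = 1L)
  pairs <- tibble(
    read_id = S4Vectors::mcols(blocks)$read[S4Vectors::queryHits(hits)],
    gene_id = S4Vectors::mcols(exons)$gene_id[S4Vectors::subjectHits(hits)]
  ) |> distinct()
  if (unique_gene) {
    multi <- pairs |> count(.data$read_id) |> filter(.data$n > 1)
    pairs <- pairs |> anti_join(multi, by = "read_id")
  }
  cells <- read_cell_table(aln, read_cells)
  pairs |>
    left_join(cells, by = "read_id") |>
    count(.data$gene_id, .data$cell_id, name = "count") |>
    tidyr::complete(gene_id = models$gene_id,
                    cell_id = unique(cells$cell_id),
                    fill = list(count = 0L))
}

read_cell_table <- function(aln, read_cells) {
  if (is.null(read_cells)) {
    return(tibble(read_id = unique(aln$qname), cell_id = "all"))
  }
  tibble(read_id = unique(aln$qname)) |>
    left_join(read_cells |> select("read_id", "cell_id"), by = "read_id") |>
    mutate(cell_id = ifelse(is.na(.data$cell_id), "unassigned", .data$cell_id))
}

#' RPG10K normalization
#'
#' `RPG10K = (reads aligned to the gene's exons / total reads aligned in the
#' sample) x 10,000`. A gene is flagged expressed when its RPG10K exceeds 0.
#'
#' @param counts tibble (gene_id, cell_id, count) from
#'   [count_reads_per_gene()] (or transcript_id in place of gene_id).
#' @param total_aligned named numeric vector, cell id -> total aligned reads
#'   in that sample (> 0).
#' @return expression tibble (feature_id, cell_id, count, rpg10k, expressed)
#'   of class `expression_table`.
#' @export
rpg10k <- function(counts, total_aligned) {
  id_col <- intersect(c("gene_id", "transcript_id", "feature_id"),
                      names(counts))[1]
  if (is.na(id_col)) abort("counts must have a gene_id/transcript_id column")
  cells <- unique(counts$cell_id)
  missing <- setdiff(cells, names(total_aligned))
  if (length(missing)) {
    abort(paste("no total aligned reads for:", paste(missing, collapse = ", ")))
  }
  if (any(total_aligned[cells] <= 0)) abort("total aligned reads must be > 0")
  out <- counts |>
    rename(feature_id = all_of(id_col)) |>
    mutate(rpg10k = .data$count / unname(total_aligned[.data$cell_id]) * 1e4,
           expressed = .data$rpg10k > 0)
  class(out) <- c("expression_table", class(out))
  out
}

#' Transcript-direct quantification
#'
#' Counts reads from alignments made directly against a spliced
#' transcriptome (one target per transcript), after the usual one-alignment-
#' per-read filtering, normalized per 10,000 aligned reads.
#'
#' @param aln transcriptome alignment tibble (already filtered, or raw - the
#'   per-read filter is applied when `filter = TRUE`).
#' @param read_cells optional (read_id, cell_id) table.
#' @param params a [pipeline_params()] object.
#' @param filter apply [filter_best_alignment()] first?
#' @return `expression_table` over transcripts.
#' @export
quantify_transcript_direct <- function(aln, read_cells = NULL,
                                       params = pipeline_params(),
                                       filter = TRUE) {
  if (filter) aln <- filter_best_alignment(aln, params)
  cells <- read_cell_table(aln, read_cells)
  counts <- aln |>
    left_join(cells, by = c(qname = "read_id")) |>
    count(transcript_id = .data$tname, .data$cell_id, name = "count") |>
    tidyr::complete(transcript_id = unique(aln$tname),
                    cell_id = unique(cells$cell_id),
                    fill = list(count = 0L))
  totals <- counts |> group_by(.data$cell_id) |>
    summarise(n = sum(.data$count)) |>
    (\(d) setNames(d$n, d$cell_id))()
  rpg10k(counts, totals)
}

#' Pearson correlation between two expression tables
#'
#' @param a,b `expression_table` tibbles sharing a feature universe.
#' @param pairing tibble (cell_a, cell_b) of sample pairs to compare;
#'   defaults to matching identical cell ids.
#' @param value column to correlate (`"rpg10k"` or `"count"`).
#' @return tibble (cell_a, cell_b, n_features, pearson_r).
#' @export
compare_expression <- function(a, b, pairing = NULL, value = "rpg10k") {
  if (is.null(pairing)) {
    shared <- intersect(unique(a$cell_id), unique(b$cell_id))
    pairing <- tibble(cell_a = shared, cell_b = shared)
  }
  out <- lapply(seq_len(nrow(pairing)), function(i) {
    xa <- a |> filter(.data$cell_id == pairing$cell_a[i])
    xb <- b |> filter(.data$cell_id == pairing$cell_b[i])
    j <- inner_join(xa, xb, by = "feature_id", suffix = c("_a", "_b"))
    if (nrow(j) < 2) abort("need at least two shared features to correlate")
    tibble(cell_a = pairing$cell_a[i], cell_b = pairing$cell_b[i],
           n_features = nrow(j),
           pearson_r = cor(j[[paste0(value, "_a")]], j[[paste0(value, "_b")]]))
  })
  bind_rows(out)
}
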