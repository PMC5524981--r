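# Isoform groups: reads sharing a TSS bin, a TES bin and an
# alternative-splice-site signature at one locus, with partial-order-
# alignment consensus sequences and per-cell quantification.

#' Partial-order-alignment consensus
#'
#' Reads are aligned progressively (longest first) into a partial-order
#' graph: matching bases fuse into shared nodes, mismatches and insertions
#' branch, and every edge is weighted by the number of reads traversing it.
#' Gaps cost twice a mismatch so that column-wise alignments are strictly
#' preferred over slipped ones near short repeats.
#' The consensus is the heaviest source-to-sink path (maximum total edge
#' weight, computed by dynamic programming over the DAG; ties resolved
#' toward the lexicographically smaller base then the older node, so the
#' result is deterministic).
#'
#' @param seqs character vector of reads, orientation-normalized.
#' @param match,mismatch,gap alignment scores (defaults +2/-2/-4).
#' @return consensus sequence (single string).
#' @export
poa_consensus <- function(seqs, match = 2L, mismatch = -2L, gap = -4L) {
  seqs <- seqs[nzchar(seqs)]
  if (length(seqs) == 0) abort("poa_consensus() needs at least one sequence")
  ord <- order(-nchar(seqs), seq_along(seqs))
  cpp_poa_consensus(seqs[ord], as.integer(match), as.integer(mismatch),
                    as.integer(gap))
}

# read-level junction usage against splice bins, for signatures
read_junction_bins <- function(aln, splice_bins, params) {
  gaps <- gap_events(aln, params$min_intron)
  if (nrow(gaps) == 0) {
    return(tibble(read_id = character(), ss5 = character(),
                  ss3 = character()))
  }
  ss5_bins <- splice_bins |> filter(.data$type == "SS5")
  ss3_bins <- splice_bins |> filter(.data$type == "SS3")
  gaps |> mutate(
    donor_pos = ifelse(.data$strand == "+", .data$open, .data$close),
    acceptor_pos = ifelse(.data$strand == "+", .data$close, .data$open),
    ss5 = match_pos_to_bins(.data$chrom, .data$donor_pos, ss5_bins),
    ss3 = match_pos_to_bins(.data$chrom, .data$acceptor_pos, ss3_bins)
  ) |>
    filter(!is.na(.data$ss5), !is.na(.data$ss3)) |>
    select("read_id", "ss5", "ss3", "open", "close")
}

#' Group reads into isoforms
#'
#' Reads whose alignment ends lie within `isoform_end_tolerance` (60 bp) of
#' a TSS bin anchor and of a TES bin anchor are partitioned by (nearest TSS,
#' nearest TES, alternative-splice signature). The signature records, for
#' every alternative donor/acceptor event at the locus, which member site
#' the read uses, and for every retained intron whether the read splices it
#' or reads through it. Groups holding at least `isoform_min_fraction` (1%,
#' boundary inclusive) of all reads at the locus are retained.
#'
#' @param aln filtered alignments.
#' @param end_bins classified end bins (types TSS/TES used).
#' @param splice_bins splice bins.
#' @param events event tibble from [call_alt_events()].
#' @param read_cells optional (read_id, cell_id) table.
#' @param models optional gene models; when `NULL`, loci are maximal
#'   intervals of overlapping read alignments (annotation-independent mode).
#' @param params a [pipeline_params()] object.
#' @return tibble of retained groups (locus, chrom, tss_anchor, tes_anchor,
#'   signature, n_reads, fraction, read_ids, direction) with attribute
#'   `unassigned` (read ids lacking a TSS or TES within tolerance).
#' @export
group_reads_into_isoforms <- function(aln, end_bins, splice_bins, events,
                                      read_cells = NULL, models = NULL,
                                      params = pipeline_params()) {
  tol <- params$isoform_end_tolerance
  tss <- end_bins |> filter(.data$type == "TSS")
  tes <- end_bins |> filter(.data$type == "TES")
  loci <- define_loci(aln, models, params)
  cells <- read_cell_table(aln, read_cells)
  junc <- read_junction_bins(aln, splice_bins, params)
  ret_events <- events |> filter(.data$type == "intron_retention")
  alt_events <- events |> filter(.data$type %in% c("alt5", "alt3"))
  blocks <- alignment_blocks(aln)
  read_span <- blocks |> group_by(.data$qname, .data$tname) |>
    summarise(lo = min(.data$tstart), hi = max(.data$tend), .groups = "drop")

  out <- list(); unassigned <- character(0)
  for (li in seq_len(nrow(loci))) {
    lc <- loci[li, ]
    la <- aln |> filter(.data$tname == lc$chrom,
                        .data$tstart < lc$end, .data$tend > lc$start)
    if (nrow(la) == 0) next
    total <- nrow(la)
    end5 <- ifelse(la$strand == "+", la$tstart, la$tend)
    end3 <- ifelse(la$strand == "+", la$tend, la$tstart)
    tssb <- tss |> filter(.data$chrom == lc$chrom)
    tesb <- tes |> filter(.data$chrom == lc$chrom)
    tss_hit <- nearest_anchor(end5, tssb$anchor, tol)
    tes_hit <- nearest_anchor(end3, tesb$anchor, tol)
    ok <- !is.na(tss_hit) & !is.na(tes_hit)
    unassigned <- c(unassigned, la$qname[!ok])
    if (!any(ok)) next
    keyed <- tibble(read_id = la$qname[ok], strand = la$strand[ok],
                    tss_anchor = tssb$anchor[tss_hit[ok]],
                    tes_anchor = tesb$anchor[tes_hit[ok]])
    sig <- isoform_signatures(keyed$read_id, lc, alt_events, ret_events,
                              junc, read_span, blocks, params)
    keyed <- keyed |> left_join(sig, by = "read_id")
    groups <- keyed |>
      group_by(.data$tss_anchor, .data$tes_anchor, .data$signature) |>
      summarise(n_reads = n(), read_ids = list(.data$read_id),
                direction = majority_strand(.data$strand), .groups = "drop") |>
      mutate(fraction = .data$n_reads / total) |>
      filter(.data$fraction >= params$isoform_min_fraction)
    if (nrow(groups) == 0) next
    out[[length(out) + 1L]] <- groups |>
      mutate(locus = lc$locus, chrom = lc$chrom, locus_reads = total) |>
      relocate("locus", "chrom")
  }
  res <- if (length(out)) bind_rows(out) else
    tibble(locus = character(), chrom = character(), tss_anchor = integer(),
           tes_anchor = integer(), signature = character(),
           n_reads = integer(), read_ids = list(), direction = character(),
           fraction = numeric(), locus_reads = integer())
  res <- res |> mutate(group_id = sprintf("%s|%d-%d|%s", .data$locus,
                                          .data$tss_anchor, .data$tes_anchor,
                                          .data$signature))
  attr(res, "unassigned") <- unique(unassigned)
  res
}

define_loci <- function(aln, models, params) {
  if (!is.null(models)) {
    return(models |> mutate(
      locus = .data$gene_id,
      start = vapply(.data$exons, function(e) min(e[, 1]), numeric(1)) -
        params$gene_slop,
      end = vapply(.data$exons, function(e) max(e[, 2]), numeric(1)) +
        params$gene_slop) |>
        select("locus", "chrom", "start", "end"))
  }
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    seqnames = aln$tname,
    ranges = IRanges::IRanges(start = aln$tstart + 1L, end = aln$tend)))
  tibble(locus = sprintf("locus_%s_%d_%d",
                         as.character(GenomicRanges::seqnames(gr)),
                         GenomicRanges::start(gr) - 1L,
                         GenomicRanges::end(gr)),
         chrom = as.character(GenomicRanges::seqnames(gr)),
         start = GenomicRanges::start(gr) - 1L,
         end = GenomicRanges::end(gr))
}

nearest_anchor <- function(pos, anchors, tol) {
  if (length(anchors) == 0) return(rep(NA_integer_, length(pos)))
  d <- abs(outer(pos, anchors, "-"))
  j <- apply(d, 1, which.min)
  ok <- d[cbind(seq_along(pos), j)] <= tol
  ifelse(ok, j, NA_integer_)
}

isoform_signatures <- function(read_ids, locus, alt_events, ret_events,
                               junc, read_span, blocks, params) {
  ids <- unique(read_ids)
  sig <- setNames(rep("", length(ids)), ids)
  loc_alt <- alt_events |> filter(.data$chrom == locus$chrom)
  for (e in seq_len(nrow(loc_alt))) {
    ev <- loc_alt[e, ]
    members <- ev$member_bins[[1]]
    col <- if (ev$type == "alt5") "ss5" else "ss3"
    use <- junc |> filter(.data$read_id %in% ids,
                          .data[[col]] %in% members) |>
      distinct(.data$read_id, .keep_all = TRUE)
    code <- setNames(rep(".", length(ids)), ids)
    code[use$read_id] <- use[[col]]
    sig <- paste0(sig, ";", ev$event_id, "=", code[ids])
  }
  loc_ret <- ret_events |> filter(.data$chrom == locus$chrom)
  for (e in seq_len(nrow(loc_ret))) {
    ev <- loc_ret[e, ]
    code <- setNames(rep(".", length(ids)), ids)
    # spliced: read uses the intron's junction
    spl <- junc |> filter(.data$read_id %in% ids,
                          .data$ss5 == ev$ss5, .data$ss3 == ev$ss3)
    code[unique(spl$read_id)] <- "S"
    # retained: read covers >= 70% of the intron
    b <- blocks |> filter(.data$tname == ev$chrom, .data$qname %in% ids,
                          .data$tend > ev$intron_start,
                          .data$tstart < ev$intron_end)
    if (nrow(b) > 0) {
      covered <- b |> group_by(.data$qname) |>
        summarise(cv = sum(interval_overlap(.data$tstart, .data$tend,
                                            ev$intron_start, ev$intron_end)),
                  .groups = "drop") |>
        filter(.data$cv >= params$retention_coverage *
                 (ev$intron_end - ev$intron_start))
      code[covered$qname] <- "R"
    }
    sig <- paste0(sig, ";", ev$event_id, "=", code[ids])
  }
  tibble(read_id = ids, signature = sub("^;", "", sig))
}

#' Consensus sequences for isoform groups
#'
#' Builds one POA consensus per retained group from the aligned spans of up
#' to `poa_max_reads` member reads (longest aligned spans first; soft-clipped
#' primer residues are excluded so the consensus represents the transcript).
#'
#' @param groups from [group_reads_into_isoforms()].
#' @param aln filtered alignments.
#' @param trimmed trimmed reads (provides cDNA-sense sequences).
#' @param params a [pipeline_params()] object.
#' @return groups with a `consensus` column.
#' @export
consensus_for_groups <- function(groups, aln, trimmed,
                                 params = pipeline_params()) {
  seqmap <- setNames(trimmed$sequence, trimmed$read_id)
  alnmap <- aln |> select("qname", "qstart", "qend")
  cons <- vapply(seq_len(nrow(groups)), function(i) {
    ids <- groups$read_ids[[i]]
    a <- alnmap |> filter(.data$qname %in% ids)
    seqs <- substr(seqmap[a$qname], a$qstart + 1L, a$qend)
    ord <- order(-nchar(seqs), a$qname)
    seqs <- seqs[ord][seq_len(min(length(seqs), params$poa_max_reads))]
    poa_consensus(seqs, params$poa_match, params$poa_mismatch, params$poa_gap)
  }, character(1))
  groups |> mutate(consensus = cons)
}

#' Per-cell isoform count table
#'
#' @param groups from [group_reads_into_isoforms()].
#' @param read_cells (read_id, cell_id) table.
#' @return long tibble (locus, group_id, cell_id, count), complete over the
#'   cells observed.
#' @export
quantify_isoforms <- function(groups, read_cells = NULL) {
  if (nrow(groups) == 0) {
    return(tibble(locus = character(), group_id = character(),
                  cell_id = character(), count = integer()))
  }
  long <- groups |>
    select("locus", "group_id", "read_ids") |>
    tidyr::unnest_longer("read_ids", values_to = "read_id")
  cells <- if (is.null(read_cells)) {
    tibble(read_id = unique(long$read_id), cell_id = "all")
  } else {
    read_cells |> select("read_id", "cell_id")
  }
  long |>
    left_join(cells, by = "read_id") |>
    mutate(cell_id = ifelse(is.na(.data$cell_id), "unassigned", .data$cell_id)) |>
    count(.data$locus, .data$group_id, .data$cell_id, name = "count") |>
    tidyr::complete(tidyr::nesting(locus, group_id), cell_id,
                    fill = list(count = 0L))
}

#' Match consensus sequences to reference transcripts
#'
#' Overlap (free-end-gap) alignment of each consensus against every
#' reference and its reverse complement; identity is
#' `matches / alignment columns x 100`. The best reference and its strand
#' are reported.
#'
#' @param consensus named character vector (or `groups` tibble with
#'   `group_id` + `consensus`).
#' @param references named character vector of transcript sequences.
#' @return tibble (consensus_id, reference, identity, direction).
#' @export
match_consensus_to_transcripts <- function(consensus, references) {
  if (length(references) == 0) abort("references must be non-empty")
  if (is.data.frame(consensus)) {
    consensus <- setNames(consensus$consensus, consensus$group_id)
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -2)
  refs <- Biostrings::DNAStringSet(references)
  refs_rc <- Biostrings::reverseComplement(refs)
  out <- lapply(seq_along(consensus), function(i) {
    cs <- Biostrings::DNAString(consensus[[i]])
    score_one <- function(ref) {
      al <- Biostrings::pairwiseAlignment(cs, ref, type = "overlap",
                                          substitutionMatrix = mat,
                                          gapOpening = 0, gapExtension = 2)
      Biostrings::nmatch(al) / Biostrings::nchar(al) * 100
    }
    fwd <- vapply(seq_along(refs), function(j) score_one(refs[[j]]), numeric(1))
    rev <- vapply(seq_along(refs), function(j) score_one(refs_rc[[j]]),
                  numeric(1))
    best <- which.max(pmax(fwd, rev))
    tibble(consensus_id = names(consensus)[i] %||% as.character(i),
           reference = names(references)[best],
           identity = max(fwd[best], rev[best]),
           direction = if (fwd[best] >= rev[best]) "forward" else "reverse")
  })
  bind_rows(out)
}

#' Write consensus sequences as FASTA
#' @param groups groups tibble with `group_id` and `consensus`.
#' @param path output FASTA.
#' @export
write_consensus_fasta <- function(groups, path) {
  x <- Biostrings::DNAStringSet(setNames(groups$consensus, groups$group_id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
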