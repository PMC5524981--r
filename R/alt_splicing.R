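# Junction-combination counting and alternative-splicing event calls.
#
# A junction observation is an alignment gap > 50 bp (in a read with
# aligned/read ratio > 0.85) whose open and close positions fall inside an
# SS5 and an SS3 bin; combinations present in >= 2 reads are retained.
# Alternative usage is scored when one donor splices to two acceptors (alt3)
# or one acceptor to two donors (alt5); intron retention when a single read
# covers >= 70% of a retained combination's intron while overlapping both
# flanking exons; exon skipping when a retained combination's intron fully
# spans an internal exon included by >= 2 other reads.

#' Count donor-acceptor junction combinations
#'
#' @param aln filtered alignments.
#' @param splice_bins from [detect_splice_bins()].
#' @param read_cells optional (read_id, cell_id) table.
#' @param params a [pipeline_params()] object.
#' @return tibble (chrom, ss5, ss3, ss5_anchor, ss3_anchor, n_reads,
#'   read_ids, cells) with `n_reads >= combo_min_reads`.
#' @export
count_junction_combinations <- function(aln, splice_bins, read_cells = NULL,
                                        params = pipeline_params()) {
  hi <- aln |> filter(.data$aligned_bases / .data$qsize > params$combo_read_ratio)
  gaps <- gap_events(hi, params$min_intron)
  empty <- tibble(chrom = character(), ss5 = character(), ss3 = character(),
                  ss5_anchor = integer(), ss3_anchor = integer(),
                  n_reads = integer(), read_ids = list(), cells = list())
  if (nrow(gaps) == 0 || nrow(splice_bins) == 0) return(empty)
  ss5_bins <- splice_bins |> filter(.data$type == "SS5")
  ss3_bins <- splice_bins |> filter(.data$type == "SS3")
  # the genomic side holding the donor depends on read direction
  gaps <- gaps |> mutate(
    donor_pos = ifelse(.data$strand == "+", .data$open, .data$close),
    acceptor_pos = ifelse(.data$strand == "+", .data$close, .data$open),
    ss5 = match_pos_to_bins(.data$chrom, .data$donor_pos, ss5_bins),
    ss3 = match_pos_to_bins(.data$chrom, .data$acceptor_pos, ss3_bins)
  ) |> filter(!is.na(.data$ss5), !is.na(.data$ss3))
  if (nrow(gaps) == 0) return(empty)
  cells <- read_cell_table(aln, read_cells)
  anchors <- setNames(splice_bins$anchor, splice_bins$bin_id)
  gaps |>
    left_join(cells, by = "read_id") |>
    group_by(.data$chrom, .data$ss5, .data$ss3) |>
    summarise(n_reads = n_distinct(.data$read_id),
              read_ids = list(unique(.data$read_id)),
              cells = list(table(.data$cell_id)),
              .groups = "drop") |>
    filter(.data$n_reads >= params$combo_min_reads) |>
    mutate(ss5_anchor = unname(anchors[.data$ss5]),
           ss3_anchor = unname(anchors[.data$ss3]))
}

#' Score alternative donor/acceptor usage
#'
#' An SS5 spliced to two or more distinct SS3 partners yields an `alt3`
#' event; an SS3 with two or more distinct SS5 partners an `alt5` event.
#'
#' @param combos retained combinations from [count_junction_combinations()].
#' @return event tibble (event_id, type, chrom, shared_bin, member_bins,
#'   member_anchors, n_reads).
#' @export
detect_alternative_sites <- function(combos) {
  empty <- tibble(event_id = character(), type = character(),
                  chrom = character(), shared_bin = character(),
                  member_bins = list(), member_anchors = list(),
                  n_reads = integer())
  if (nrow(combos) == 0) return(empty)
  alt3 <- combos |> group_by(.data$chrom, .data$ss5) |>
    filter(n_distinct(.data$ss3) >= 2) |>
    summarise(type = "alt3", shared_bin = .data$ss5[1],
              member_bins = list(sort(unique(.data$ss3))),
              member_anchors = list(sort(unique(.data$ss3_anchor))),
              n_reads = sum(.data$n_reads), .groups = "drop")
  alt5 <- combos |> group_by(.data$chrom, .data$ss3) |>
    filter(n_distinct(.data$ss5) >= 2) |>
    summarise(type = "alt5", shared_bin = .data$ss3[1],
              member_bins = list(sort(unique(.data$ss5))),
              member_anchors = list(sort(unique(.data$ss5_anchor))),
              n_reads = sum(.data$n_reads), .groups = "drop")
  bind_rows(alt3 |> select(-"ss5"), alt5 |> select(-"ss3")) |>
    mutate(event_id = paste(.data$type, .data$shared_bin, sep = "@")) |>
    relocate("event_id", "type")
}

# per-intron coverage by single reads; intron = inner span between anchors
intron_span <- function(combos) {
  combos |> mutate(
    intron_start = pmin(.data$ss5_anchor, .data$ss3_anchor),
    intron_end = pmax(.data$ss5_anchor, .data$ss3_anchor))
}

#' Detect intron retention
#'
#' An intron (the span between the donor and acceptor anchors of a retained
#' combination) is called retained when at least one single read covers at
#' least `retention_coverage` (70%) of its bases while also overlapping both
#' flanking exons by at least one base (distinguishing retention from
#' truncated fragments).
#'
#' @param combos retained combinations.
#' @param aln filtered alignments.
#' @param read_cells optional (read_id, cell_id) table.
#' @param params a [pipeline_params()] object.
#' @return event tibble (event_id, type = "intron_retention", chrom,
#'   intron_start, intron_end, ss5, ss3, n_reads, read_ids).
#' @export
detect_intron_retention <- function(combos, aln, read_cells = NULL,
                                    params = pipeline_params()) {
  empty <- tibble(event_id = character(), type = character(),
                  chrom = character(), intron_start = integer(),
                  intron_end = integer(), ss5 = character(),
                  ss3 = character(), n_reads = integer(), read_ids = list())
  if (nrow(combos) == 0) return(empty)
  spans <- intron_span(combos)
  blocks <- alignment_blocks(aln)
  # flanking-exon overlap uses all blocks of the read, not just intronic ones
  span_by_chrom <- blocks |>
    group_by(.data$tname, .data$qname) |>
    summarise(lo = min(.data$tstart), hi = max(.data$tend), .groups = "drop")
  out <- list()
  for (i in seq_len(nrow(spans))) {
    l <- spans$intron_start[i]; r <- spans$intron_end[i]
    ilen <- r - l
    if (ilen <= 0) next
    b <- blocks |> filter(.data$tname == spans$chrom[i],
                          .data$tend > l, .data$tstart < r)
    if (nrow(b) == 0) next
    per_read <- b |>
      group_by(.data$qname) |>
      summarise(covered = sum(interval_overlap(.data$tstart, .data$tend, l, r)),
                .groups = "drop")
    span_all <- span_by_chrom |> filter(.data$tname == spans$chrom[i]) |>
      select(-"tname")
    supp <- per_read |>
      left_join(span_all, by = "qname") |>
      filter(.data$covered >= params$retention_coverage * ilen,
             .data$lo < l, .data$hi > r)
    if (nrow(supp) == 0) next
    out[[length(out) + 1L]] <- tibble(
      event_id = sprintf("ir@%s:%d-%d", spans$chrom[i], l, r),
      type = "intron_retention", chrom = spans$chrom[i],
      intron_start = l, intron_end = r,
      ss5 = spans$ss5[i], ss3 = spans$ss3[i],
      n_reads = nrow(supp), read_ids = list(supp$qname))
  }
  if (length(out) == 0) return(empty)
  bind_rows(out) |> distinct(.data$event_id, .keep_all = TRUE)
}

#' Detect exon skipping
#'
#' Internal exons are spans between the acceptor of one junction and the
#' donor of the next junction used together in a read (each such exon
#' needing two or more supporting reads). Skipping is called when a retained combination's
#' intron fully spans such an exon. This operationalization is a stated
#' heuristic: run it via `call_alt_events(..., skipping = TRUE)`.
#'
#' @param combos retained combinations.
#' @param aln filtered alignments.
#' @param params a [pipeline_params()] object.
#' @return event tibble (event_id, type = "exon_skipping", chrom, exon_start,
#'   exon_end, spanning_ss5, spanning_ss3, n_reads).
#' @export
detect_exon_skipping <- function(combos, aln, params = pipeline_params()) {
  empty <- tibble(event_id = character(), type = character(),
                  chrom = character(), exon_start = integer(),
                  exon_end = integer(), spanning_ss5 = character(),
                  spanning_ss3 = character(), n_reads = integer())
  if (nrow(combos) == 0) return(empty)
  hi <- aln |> filter(.data$aligned_bases / .data$qsize > params$combo_read_ratio)
  gaps <- gap_events(hi, params$min_intron)
  if (nrow(gaps) == 0) return(empty)
  # internal exons: between consecutive gaps of one read
  exons <- gaps |>
    arrange(.data$read_id, .data$open) |>
    group_by(.data$read_id, .data$chrom) |>
    reframe(exon_start = head(.data$close, -1), exon_end = tail(.data$open, -1)) |>
    count(.data$chrom, .data$exon_start, .data$exon_end, name = "n_inclusion") |>
    filter(.data$n_inclusion >= 2, .data$exon_end > .data$exon_start)
  if (nrow(exons) == 0) return(empty)
  spans <- intron_span(combos)
  out <- list()
  for (i in seq_len(nrow(spans))) {
    hit <- exons |> filter(.data$chrom == spans$chrom[i],
                           .data$exon_start >= spans$intron_start[i],
                           .data$exon_end <= spans$intron_end[i])
    if (nrow(hit) == 0) next
    out[[length(out) + 1L]] <- hit |> mutate(
      event_id = sprintf("skip@%s:%d-%d", .data$chrom, .data$exon_start,
                         .data$exon_end),
      type = "exon_skipping",
      spanning_ss5 = spans$ss5[i], spanning_ss3 = spans$ss3[i],
      n_reads = spans$n_reads[i]) |>
      select(-"n_inclusion")
  }
  if (length(out) == 0) return(empty)
  bind_rows(out) |> distinct(.data$event_id, .keep_all = TRUE)
}

#' Call all alternative-splicing events
#'
#' @param aln filtered alignments.
#' @param splice_bins from [detect_splice_bins()].
#' @param read_cells optional (read_id, cell_id) table.
#' @param params a [pipeline_params()] object.
#' @param skipping include the exon-skipping heuristic?
#' @return list with `combinations` and `events` (bound rows of all event
#'   types).
#' @export
call_alt_events <- function(aln, splice_bins, read_cells = NULL,
                            params = pipeline_params(), skipping = TRUE) {
  combos <- count_junction_combinations(aln, splice_bins, read_cells, params)
  ev <- list(
    detect_alternative_sites(combos),
    detect_intron_retention(combos, aln, read_cells, params)
  )
  if (skipping) ev <- c(ev, list(detect_exon_skipping(combos, aln, params)))
  list(combinations = combos, events = bind_rows(ev))
}
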