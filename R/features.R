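# TSS/TES and splice-site detection as 20-bp genomic bins.
#
# Transcript ends: positions where >= 2 complete-read alignments end, with a
# clipped-base profile matching untrimmed primer residue (median 6-15, 75th
# percentile <= 20), binned into the 20-bp window holding the most alignment
# ends, kept when supported by >= 2% of the reads in the next 50 read-covered
# bases and >= 60 read-covered bases from any other retained end (plain 60 bp
# genomic in SIRV mode). Bins are typed by the median Levenshtein distance of
# their end clips to the TSO motif (ATGG -> TSS) or the oligodT motif
# (TTTT -> TES); because reads are unstranded the clip and its reverse
# complement are both compared and the smaller distance used.
#
# Splice sites: positions where >= 2 alignments of high-identity reads
# (aligned/read ratio > 0.9) open or close a gap > 50 bp, binned the same
# way, kept when supported by >= 2% of reads in the adjacent 40 read-covered
# bases (on the exon side of the gap) and >= 30 bp from any other splice bin.

# --- end events --------------------------------------------------------------

clip_adjacent <- function(seqs, qstart, qend, strand, side, k) {
  # bases of the soft clip nearest the alignment, in stored (cDNA sense)
  # coordinates; side is the *target* side ("left"/"right")
  inner <- (side == "left") == (strand == "+")
  # inner TRUE: clip precedes qstart; FALSE: clip follows qend
  out <- character(length(seqs))
  kk <- pmin(k, ifelse(inner, qstart, nchar(seqs) - qend))
  pre <- substr(seqs, pmax(1L, qstart - kk + 1L), qstart)
  post <- substr(seqs, qend + 1L, qend + kk)
  ifelse(inner, pre, post)
}

# one row per alignment end: genomic position, clip length/sequence, side
end_events <- function(aln, trimmed, params = pipeline_params()) {
  k <- params$end_clip_k
  meta <- trimmed |> select("read_id", "cell_id", "sequence", "complete")
  x <- aln |> left_join(meta, by = c(qname = "read_id"))
  if (anyNA(x$sequence)) abort("trimmed sequences missing for some aligned reads")
  mk <- function(ws) {
    tibble(
      chrom = x$tname,
      pos = if (ws == "left") x$tstart else x$tend,
      side = ws,
      clip_len = if (ws == "left") x$clip_tleft else x$clip_tright,
      clip_seq = clip_adjacent(x$sequence, x$qstart, x$qend, x$strand, ws, k),
      read_id = x$qname, strand = x$strand,
      cell_id = x$cell_id, complete = x$complete
    )
  }
  bind_rows(mk("left"), mk("right"))
}

#' Candidate transcript-end positions
#'
#' Positions where at least `min_end_support` complete-read alignments end
#' and the clipped (unaligned) bases at that end have a median length within
#' `clip_median_range` and a 75th percentile of at most `clip_p75_max` -
#' the footprint of untrimmed TSO/oligodT primer bases.
#'
#' @param events end-event tibble (internal; built from filtered alignments
#'   and trimmed reads).
#' @param params a [pipeline_params()] object.
#' @return tibble (chrom, pos, side, n, clip_median, clip_p75).
#' @keywords internal
find_end_candidates <- function(events, params = pipeline_params()) {
  rng <- params$clip_median_range
  events |>
    filter(.data$complete) |>
    group_by(.data$chrom, .data$pos, .data$side) |>
    summarise(n = n(), clip_median = median(.data$clip_len),
              clip_p75 = quantile(.data$clip_len, 0.75, names = FALSE),
              .groups = "drop") |>
    filter(.data$n >= params$min_end_support,
           .data$clip_median >= rng[1], .data$clip_median <= rng[2],
           .data$clip_p75 <= params$clip_p75_max)
}

# For each candidate, the width-bp window overlapping it that contains the
# most events; overlapping windows collapse onto the best one (greedy by
# support, then leftmost).
place_bins <- function(candidates, events, width, group_cols) {
  if (nrow(candidates) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  anchor = integer(), support = integer(),
                  members = list()) |>
             bind_cols(candidates[0, setdiff(group_cols, "chrom"), drop = FALSE]))
  }
  out <- list()
  keys <- candidates |> distinct(across(all_of(group_cols)))
  for (ki in seq_len(nrow(keys))) {
    key <- keys[ki, ]
    cand <- candidates |> semi_join(key, by = group_cols)
    ev <- events |> semi_join(key, by = group_cols)
    pos <- sort(ev$pos)
    wins <- lapply(cand$pos, function(p) {
      starts <- (p - width + 1L):p
      cnt <- findInterval(starts + width - 0.5, pos) -
        findInterval(starts - 0.5, pos)
      best <- which(cnt == max(cnt))[1]
      c(start = starts[best], count = cnt[best], anchor = p)
    })
    wins <- as_tibble(do.call(rbind, wins)) |>
      arrange(desc(.data$count), .data$start)
    taken <- integer(0)
    for (i in seq_len(nrow(wins))) {
      s <- wins$start[i]
      if (any(abs(taken - s) < width)) next
      taken <- c(taken, s)
      members <- ev |> filter(.data$pos >= s, .data$pos < s + width)
      out[[length(out) + 1L]] <- bind_cols(
        key,
        tibble(start = s, end = s + width, anchor = wins$anchor[i],
               support = nrow(members), members = list(members)))
    }
  }
  bind_rows(out) |> arrange(.data$chrom, .data$start)
}

#' Place 20-bp bins around candidate end positions
#'
#' @param candidates from [find_end_candidates()].
#' @param events end events of complete reads.
#' @param params a [pipeline_params()] object.
#' @return bin tibble with `members` list column.
#' @keywords internal
place_end_bins <- function(candidates, events, params = pipeline_params()) {
  place_bins(candidates, events |> filter(.data$complete),
             params$bin_width, c("chrom", "side"))
}

#' Filter end bins by local support and mutual separation
#'
#' Keeps a bin when (i) its alignment-end support is at least
#' `end_filter_fraction` of the reads overlapping the next
#' `end_filter_window` read-covered bases (walked into the transcript body,
#' i.e. away from the clip side) and (ii) it is at least `end_separation`
#' read-covered bases (genomic bases in SIRV mode) from every other retained
#' end, conflicts resolved greedily by descending support then coordinate.
#'
#' @param bins from [place_end_bins()].
#' @param cov a [coverage_mask()] over all filtered alignments.
#' @param bgr blocks `GRanges` of all filtered alignments (internal).
#' @param params a [pipeline_params()] object.
#' @return retained bin tibble with `window_reads` column.
#' @keywords internal
filter_end_bins <- function(bins, cov, bgr, params = pipeline_params()) {
  if (nrow(bins) == 0) return(bins |> mutate(window_reads = integer(0)))
  wr <- vapply(seq_len(nrow(bins)), function(i) {
    dir <- if (bins$side[i] == "left") 1L else -1L
    from <- if (dir > 0) bins$end[i] else bins$start[i]
    walk <- covered_distance(cov, bins$chrom[i], from,
                             params$end_filter_window, dir)
    reads_in_window(bgr, bins$chrom[i], min(from, walk$end),
                    max(from, walk$end))
  }, integer(1))
  bins <- bins |> mutate(window_reads = wr) |>
    filter(.data$support >= params$end_filter_fraction * .data$window_reads)
  separate_bins(bins, cov, params$end_separation,
                genomic = params$sirv_mode)
}

# greedy separation: keep by descending support (tie: coordinate); a bin
# conflicts when closer than min_sep (covered or genomic bases) to a keeper
separate_bins <- function(bins, cov, min_sep, genomic = FALSE) {
  if (nrow(bins) <= 1) return(bins)
  ord <- order(-bins$support, bins$chrom, bins$anchor)
  keep <- logical(nrow(bins))
  for (i in ord) {
    prior <- which(keep & bins$chrom == bins$chrom[i])
    ok <- TRUE
    for (j in prior) {
      d <- if (genomic) abs(bins$anchor[i] - bins$anchor[j])
      else covered_between(cov, bins$chrom[i], bins$anchor[i], bins$anchor[j])
      if (d < min_sep) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  bins[keep, , drop = FALSE] |> arrange(.data$chrom, .data$start)
}

#' Classify end bins as TSS or TES
#'
#' Median Levenshtein distance of the clip bases adjacent to the member
#' alignment ends (each compared in both orientations, smaller distance
#' taken) to the TSO motif `ATGG` and the oligodT motif `TTTT`; a median
#' of at most `clip_distance_max` declares the type, and ambiguous evidence
#' (both medians pass, or no clip sequence) leaves the bin unclassified.
#' Direction is the majority alignment strand of the member reads.
#'
#' @param bins retained end bins.
#' @param params a [pipeline_params()] object.
#' @return bins with `type`, `direction`, `dist_tss`, `dist_tes` columns.
#' @export
classify_tss_tes <- function(bins, params = pipeline_params()) {
  if (nrow(bins) == 0) {
    return(bins |> mutate(type = character(0), direction = character(0),
                          dist_tss = numeric(0), dist_tes = numeric(0)))
  }
  stats <- lapply(bins$members, function(m) {
    clips <- m$clip_seq[nzchar(m$clip_seq)]
    if (length(clips) == 0) {
      return(list(d_tss = Inf, d_tes = Inf, dir = majority_strand(m$strand)))
    }
    rc <- seq_revcomp(clips)
    d_tss <- median(pmin(levenshtein(clips, params$tss_motif),
                         levenshtein(rc, params$tss_motif)))
    d_tes <- median(pmin(levenshtein(clips, params$tes_motif),
                         levenshtein(rc, params$tes_motif)))
    list(d_tss = d_tss, d_tes = d_tes, dir = majority_strand(m$strand))
  })
  d_tss <- vapply(stats, `[[`, numeric(1), "d_tss")
  d_tes <- vapply(stats, `[[`, numeric(1), "d_tes")
  is_tss <- d_tss <= params$clip_distance_max
  is_tes <- d_tes <= params$clip_distance_max
  bins |> mutate(
    dist_tss = d_tss, dist_tes = d_tes,
    type = case_when(is_tss & !is_tes ~ "TSS",
                     is_tes & !is_tss ~ "TES",
                     .default = "unclassified"),
    direction = vapply(stats, `[[`, character(1), "dir"),
    bin_id = paste(.data$chrom, .data$anchor, .data$type, sep = ":")
  )
}

majority_strand <- function(s) {
  if (sum(s == "+") >= sum(s == "-")) "+" else "-"
}

#' Detect transcript-end bins
#'
#' Runs the full end-detection chain: candidate positions from complete-read
#' alignment ends, 20-bp binning, local-support and separation filters, and
#' TSS/TES classification.
#'
#' @param aln filtered alignments (one per read).
#' @param trimmed trimmed-read tibble from [preprocess_reads()].
#' @param cov coverage mask over `aln`; built on demand when `NULL`.
#' @param params a [pipeline_params()] object.
#' @return classified end-bin tibble.
#' @export
detect_end_bins <- function(aln, trimmed, cov = NULL,
                            params = pipeline_params()) {
  cov <- cov %||% coverage_mask(aln)
  bgr <- blocks_granges(aln)
  events <- end_events(aln, trimmed, params)
  cands <- find_end_candidates(events, params)
  bins <- place_end_bins(cands, events, params)
  bins <- filter_end_bins(bins, cov, bgr, params)
  classify_tss_tes(bins, params)
}

# --- splice sites ------------------------------------------------------------

# gap events: one row per alignment gap > min gap, with open/close positions
gap_events <- function(aln, min_gap) {
  nb <- lengths(aln$t_starts)
  ts <- unlist(aln$t_starts, use.names = FALSE)
  bs <- unlist(aln$block_sizes, use.names = FALSE)
  row <- rep(seq_len(nrow(aln)), nb)
  within_row <- sequence(nb)
  # pair block i with block i+1 of the same alignment
  lead_ok <- which(within_row < nb[row])
  open <- (ts + bs)[lead_ok]
  close <- ts[lead_ok + 1L]
  keep <- (close - open) >= min_gap
  i <- row[lead_ok[keep]]
  tibble(chrom = aln$tname[i], open = open[keep], close = close[keep],
         read_id = aln$qname[i], strand = aln$strand[i])
}

#' Detect splice-site bins
#'
#' Gap-open and gap-close positions of alignment gaps larger than 50 bp in
#' reads with aligned/read ratio > 0.9 are typed as donor (SS5) or acceptor
#' (SS3) by read direction, binned (20 bp), filtered by the 2%-of-reads rule
#' over the adjacent 40 read-covered exonic bases, and separated by at least
#' 30 bp.
#'
#' @param aln filtered alignments.
#' @param cov coverage mask; built on demand when `NULL`.
#' @param params a [pipeline_params()] object.
#' @return splice-bin tibble (chrom, start, end, anchor, type, support,
#'   direction, bin_id).
#' @export
detect_splice_bins <- function(aln, cov = NULL, params = pipeline_params()) {
  cov <- cov %||% coverage_mask(aln)
  bgr <- blocks_granges(aln)
  hi <- aln |> filter(.data$aligned_bases / .data$qsize > params$splice_read_ratio)
  gaps <- gap_events(hi, params$min_intron)
  if (nrow(gaps) == 0) {
    return(tibble(chrom = character(), type = character(), start = integer(),
                  end = integer(), anchor = integer(), support = integer(),
                  members = list(), direction = character(),
                  bin_id = character()))
  }
  events <- bind_rows(
    gaps |> mutate(pos = .data$open, role = "open"),
    gaps |> mutate(pos = .data$close, role = "close")
  ) |> mutate(type = case_when(
    .data$role == "open" & .data$strand == "+" ~ "SS5",
    .data$role == "open" ~ "SS3",
    .data$strand == "+" ~ "SS3",
    .default = "SS5"))
  cands <- events |>
    group_by(.data$chrom, .data$pos, .data$type) |>
    summarise(n = n_distinct(.data$read_id), .groups = "drop") |>
    filter(.data$n >= params$min_splice_support)
  bins <- place_bins(cands, events, params$bin_width, c("chrom", "type"))
  if (nrow(bins) == 0) return(bins |> mutate(direction = character(0),
                                             bin_id = character(0)))
  # 2%-of-reads filter over the adjacent exonic window
  wr <- vapply(seq_len(nrow(bins)), function(i) {
    m <- bins$members[[i]]
    dir <- if (mean(m$role == "open") >= 0.5) -1L else 1L # exon side
    from <- if (dir > 0) bins$end[i] else bins$start[i]
    walk <- covered_distance(cov, bins$chrom[i], from,
                             params$splice_filter_window, dir)
    reads_in_window(bgr, bins$chrom[i], min(from, walk$end),
                    max(from, walk$end))
  }, integer(1))
  bins <- bins |> mutate(window_reads = wr) |>
    filter(.data$support >= params$splice_filter_fraction * .data$window_reads)
  bins <- separate_bins(bins, cov, params$splice_separation, genomic = TRUE)
  bins |> mutate(
    direction = vapply(.data$members, function(m) majority_strand(m$strand),
                       character(1)),
    bin_id = paste(.data$chrom, .data$anchor, .data$type, sep = ":"))
}

# map genomic positions to containing bins (bins are disjoint per chromosome)
match_pos_to_bins <- function(chrom, pos, bins) {
  out <- rep(NA_character_, length(pos))
  for (ch in unique(chrom)) {
    b <- bins[bins$chrom == ch, ]
    if (nrow(b) == 0) next
    b <- b[order(b$start), ]
    sel <- which(chrom == ch)
    j <- findInterval(pos[sel], b$start)
    ok <- j >= 1 & pos[sel] < b$end[pmax(j, 1L)]
    out[sel[ok]] <- b$bin_id[j[ok]]
  }
  out
}

# --- validation --------------------------------------------------------------

#' Flag TSS/TES bins overlapping CAGE peaks
#'
#' A bin overlaps a peak when its anchor lies within `cage_max_distance`
#' (default 10 bp, boundary inclusive) of the peak interval.
#'
#' @param bins classified end bins.
#' @param cage BED path or tibble (chrom, start, end), 0-based half-open.
#' @param params a [pipeline_params()] object.
#' @return bins with `cage_distance` and `cage_overlap` columns.
#' @export
validate_cage_overlap <- function(bins, cage, params = pipeline_params()) {
  if (is.character(cage)) {
    gr <- rtracklayer::import(cage, format = "BED")
    cage <- tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr))
  }
  if (!all(c("chrom", "start", "end") %in% names(cage)) ||
      any(cage$end <= cage$start)) {
    abort("malformed CAGE peak table")
  }
  dist <- vapply(seq_len(nrow(bins)), function(i) {
    p <- cage[cage$chrom == bins$chrom[i], ]
    if (nrow(p) == 0) return(Inf)
    a <- bins$anchor[i]
    min(pmax(0, pmax(p$start - a, a - (p$end - 1L))))
  }, numeric(1))
  bins |> mutate(cage_distance = dist,
                 cage_overlap = dist <= params$cage_max_distance)
}

#' PolyA signal motifs near end bins
#'
#' Exact string matches to the polyadenylation motifs (`AATAAA`, `ATTAAA`)
#' in a window around each bin anchor, on the strand given by the bin
#' direction. Offsets are transcript-oriented: negative = upstream of the
#' anchor.
#'
#' @param bins classified end bins (needs `direction`).
#' @param genome named character vector of chromosome sequences.
#' @param params a [pipeline_params()] object (`polya_motifs`,
#'   `polya_window`).
#' @return tibble (bin_id, chrom, anchor, type, motif, offset), one row per
#'   hit.
#' @export
find_polya_signal <- function(bins, genome, params = pipeline_params()) {
  w <- params$polya_window
  out <- list()
  for (i in seq_len(nrow(bins))) {
    ch <- bins$chrom[i]
    if (is.null(genome[[ch]])) abort(paste("chromosome missing:", ch))
    len <- nchar(genome[[ch]])
    a <- bins$anchor[i]
    if (a < 0 || a > len) abort("bin anchor outside chromosome")
    lo <- max(0L, a - w); hi <- min(len, a + w)
    s <- substr(genome[[ch]], lo + 1L, hi)
    a0 <- a - lo
    if (bins$direction[i] == "-") {
      s <- seq_revcomp(s)
      a0 <- hi - a
    }
    for (motif in params$polya_motifs) {
      m <- Biostrings::matchPattern(motif, Biostrings::DNAString(s))
      if (length(m) == 0) next
      out[[length(out) + 1L]] <- tibble(
        bin_id = bins$bin_id[i], chrom = ch, anchor = a,
        type = bins$type[i], motif = motif,
        offset = Biostrings::start(m) - 1L - a0)
    }
  }
  if (length(out) == 0) {
    return(tibble(bin_id = character(), chrom = character(),
                  anchor = integer(), type = character(),
                  motif = character(), offset = integer()))
  }
  bind_rows(out)
}

#' Assign feature bins to genes
#'
#' A bin belongs to every gene whose span (first exon start to last exon
#' end, widened by `gene_slop` bases) contains the bin anchor; bins outside
#' all spans are reported with `gene_id = NA`.
#'
#' @param bins feature bins (end and/or splice).
#' @param models gene models.
#' @param params a [pipeline_params()] object.
#' @return tibble of bins with a `gene_id` column (possibly several rows per
#'   bin).
#' @export
assign_features_to_genes <- function(bins, models, params = pipeline_params()) {
  slop <- params$gene_slop
  spans <- models |> mutate(
    span_start = vapply(.data$exons, function(e) min(e[, 1]), numeric(1)) - slop,
    span_end = vapply(.data$exons, function(e) max(e[, 2]), numeric(1)) + slop)
  out <- lapply(seq_len(nrow(bins)), function(i) {
    g <- spans |> filter(.data$chrom == bins$chrom[i],
                         .data$span_start <= bins$anchor[i],
                         .data$span_end > bins$anchor[i])
    gene <- if (nrow(g) == 0) NA_character_ else g$gene_id
    bind_cols(bins[rep(i, length(gene)), , drop = FALSE], tibble(gene_id = gene))
  })
  bind_rows(out)
}
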