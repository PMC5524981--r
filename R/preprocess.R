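# Demultiplexing by 60-nt cell indexes and ISPCR adaptor trimming.
#
# Index search: Smith-Waterman local alignment (+1 match, -1 mismatch,
# -1 gap) of each index and its reverse complement against both terminal
# windows of the read; an assignment needs exactly one index reaching the
# minimum score (default 20, mirroring an aligner run at -minScore=20).
# Adaptor search: semi-global edit-distance location of the TSO-side adaptor
# in the 5' window and the oligodT-side adaptor in the 3' window, on both
# read orientations; a read is "complete" when both adaptors are found within
# the distance cutoff. Trimmed reads are orientation-normalized to the cDNA
# sense (TSO end first).

#' Levenshtein edit distance
#'
#' Unit-cost substitution/insertion/deletion distance between nucleotide
#' strings; vectorized with recycling.
#'
#' @param a,b character vectors over A/C/G/T/N (empty strings allowed).
#' @return integer vector of edit distances.
#' @export
levenshtein <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) return(integer(0))
  cpp_levenshtein(as.character(a), as.character(b))
}

#' Demultiplex reads by cell index sequences
#'
#' @param reads tibble (read_id, sequence).
#' @param indexes named character vector, cell id -> index sequence; duplicate
#'   sequences are a configuration error.
#' @param params a [pipeline_params()] object (uses `index_min_score`,
#'   `sw_match`, `sw_mismatch`, `sw_gap`).
#' @param window terminal window searched at each read end (defaults to
#'   2 x index length + 80 bases).
#' @return tibble (read_id, cell_id, index_score, n_hits, sequence) where
#'   `cell_id` is `NA` for reads matching zero or more than one index and
#'   `sequence` has the matched index region removed.
#' @export
demultiplex <- function(reads, indexes, params = pipeline_params(),
                        window = NULL) {
  if (anyDuplicated(indexes)) abort("duplicate index sequences in index set")
  if (is.null(names(indexes)) || any(!nzchar(names(indexes)))) {
    abort("indexes must be a named vector (cell id -> sequence)")
  }
  window <- window %||% (2L * max(nchar(indexes)) + 80L)
  scan <- cpp_demux_scan(reads$sequence, unname(indexes),
                         params$sw_match, params$sw_mismatch, params$sw_gap,
                         window, params$index_min_score)
  assigned <- scan$n_hits == 1L & scan$best_score >= params$index_min_score
  cell <- ifelse(assigned, names(indexes)[scan$best_index], NA_character_)
  seqs <- reads$sequence
  for (i in which(assigned)) {
    seqs[i] <- paste0(substr(seqs[i], 1L, scan$trim_start[i]),
                      substr(seqs[i], scan$trim_end[i] + 1L, nchar(seqs[i])))
  }
  tibble(read_id = reads$read_id, cell_id = cell,
         index_score = scan$best_score, n_hits = scan$n_hits,
         sequence = seqs)
}

#' Identify and trim ISPCR adaptors
#'
#' Searches the terminal windows of each read (and of its reverse complement)
#' for the TSO-side adaptor at the 5' end and the oligodT-side adaptor at the
#' 3' end, minimizing Levenshtein distance. The best occurrences are trimmed;
#' a read is marked complete when both adaptors are found within
#' `max_distance` edits. The returned sequence is oriented to the cDNA sense
#' (the end holding the TSO adaptor becomes the 5' end).
#'
#' @param reads tibble (read_id, sequence), optionally with a `cell_id`
#'   column from [demultiplex()].
#' @param tso TSO-side (ISPCR) adaptor sequence searched at the 5' end.
#' @param oligodt oligodT-side pattern searched at the 3' end *in cDNA
#'   sense*, i.e. the reverse complement of the oligodT primer.
#' @param params a [pipeline_params()] object (`adaptor_window`,
#'   `max_adaptor_distance`).
#' @return tibble (read_id, cell_id, sequence, complete, dist5, dist3,
#'   found5, found3, direction) where `direction` is `"5to3"` when the TSO
#'   end was at the start of the raw read and `"3to5"` otherwise; trimming
#'   yields a contiguous substring of the raw read or of its reverse
#'   complement.
#' @export
trim_ispcr <- function(reads, tso = ISPCR,
                       oligodt = seq_revcomp(paste0(ISPCR, "AC", strrep("T", 20))),
                       params = pipeline_params()) {
  max5 <- default_adaptor_distance(tso, params$max_adaptor_distance)
  max3 <- default_adaptor_distance(oligodt, params$max_adaptor_distance)
  lens <- nchar(reads$sequence)
  too_short <- lens < 2L * max(nchar(tso), nchar(oligodt))
  if (any(too_short)) {
    warn(sprintf("%d read(s) shorter than twice the adaptor length left untrimmed",
                 sum(too_short)))
  }
  scan <- cpp_adaptor_scan(reads$sequence, tso, oligodt,
                           params$adaptor_window, max(max5, max3))
  found5 <- scan$d5 <= max5 & !too_short
  found3 <- scan$d3 <= max3 & !too_short
  oriented <- ifelse(scan$orient == 1L & !too_short,
                     seq_revcomp(reads$sequence), reads$sequence)
  from <- ifelse(found5, scan$e5 + 1L, 1L)
  to <- ifelse(found3, scan$s3, lens)
  seqs <- substr(oriented, from, to)
  seqs[too_short] <- reads$sequence[too_short]
  tibble(
    read_id = reads$read_id,
    cell_id = if ("cell_id" %in% names(reads)) reads$cell_id else NA_character_,
    sequence = seqs,
    complete = found5 & found3,
    dist5 = scan$d5, dist3 = scan$d3,
    found5 = found5, found3 = found3,
    direction = ifelse(scan$orient == 0L, "5to3", "3to5")
  )
}

#' Demultiplex and trim in one pass
#'
#' @param reads tibble (read_id, sequence).
#' @param indexes optional named index set; skipped when `NULL`
#'   (non-multiplexed run).
#' @param tso,oligodt adaptor sequences, see [trim_ispcr()].
#' @param params a [pipeline_params()] object.
#' @return trimmed-read tibble as from [trim_ispcr()].
#' @export
preprocess_reads <- function(reads, indexes = NULL, tso = ISPCR,
                             oligodt = seq_revcomp(paste0(ISPCR, "AC",
                                                          strrep("T", 20))),
                             params = pipeline_params()) {
  if (!is.null(indexes)) {
    dm <- demultiplex(reads, indexes, params)
    reads <- dm |> select("read_id", "cell_id", "sequence")
  }
  trim_ispcr(reads, tso, oligodt, params)
}
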