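# PSL spliced-alignment parsing, per-read filtering, and derived quantities.
# All coordinates are kept 0-based half-open as in the format itself.

PSL_COLS <- c("matches", "mismatches", "rep_matches", "n_count",
              "q_num_insert", "q_base_insert", "t_num_insert", "t_base_insert",
              "strand", "qname", "qsize", "qstart", "qend",
              "tname", "tsize", "tstart", "tend",
              "block_count", "block_sizes", "q_starts", "t_starts")

parse_int_list <- function(x) {
  lapply(strsplit(x, ",", fixed = TRUE), as.integer)
}

#' Read spliced alignments from a PSL file
#'
#' Parses the 21-column tab-separated format written by BLAT (no header,
#' 0-based half-open). Alignment score is computed as
#' `matches - mismatches - q_num_insert - t_num_insert`; the gap count as
#' `q_num_insert + t_num_insert` (number of gap openings on either sequence).
#' Target-side soft-clip lengths (`clip_tleft`, `clip_tright`) give the
#' number of unaligned query bases beyond each target end, strand-aware.
#'
#' @param path PSL file.
#' @return tibble with one row per alignment; `block_sizes`, `q_starts` and
#'   `t_starts` are integer list columns. Lines with unsorted or overlapping
#'   target blocks raise an error naming the line.
#' @export
read_psl <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(empty_psl())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 21L)) {
    abort(sprintf("malformed PSL line %d: expected 21 fields, found %d",
                  which(nf != 21L)[1], nf[nf != 21L][1]))
  }
  m <- do.call(rbind, parts)
  num_cols <- c(1:8, 11:13, 15:18)
  suppressWarnings(storage <- apply(m[, num_cols, drop = FALSE], 2, as.integer))
  if (length(lines) == 1) storage <- matrix(storage, nrow = 1)
  if (anyNA(storage)) {
    bad <- which(rowSums(is.na(storage)) > 0)[1]
    abort(sprintf("malformed PSL line %d: non-numeric field", bad))
  }
  aln <- tibble(
    matches = storage[, 1], mismatches = storage[, 2],
    rep_matches = storage[, 3], n_count = storage[, 4],
    q_num_insert = storage[, 5], q_base_insert = storage[, 6],
    t_num_insert = storage[, 7], t_base_insert = storage[, 8],
    strand = m[, 9], qname = m[, 10],
    qsize = storage[, 9], qstart = storage[, 10], qend = storage[, 11],
    tname = m[, 14], tsize = storage[, 12],
    tstart = storage[, 13], tend = storage[, 14],
    block_count = storage[, 15],
    block_sizes = parse_int_list(m[, 19]),
    q_starts = parse_int_list(m[, 20]),
    t_starts = parse_int_list(m[, 21])
  )
  for (i in seq_len(nrow(aln))) {
    ts <- aln$t_starts[[i]]; bs <- aln$block_sizes[[i]]
    if (length(ts) != aln$block_count[i] || length(bs) != aln$block_count[i]) {
      abort(sprintf("malformed PSL line %d: block count mismatch", i))
    }
    if (length(ts) > 1 && any(ts[-1] < (ts + bs)[-length(ts)])) {
      abort(sprintf("malformed PSL line %d: overlapping or unsorted target blocks", i))
    }
  }
  finish_psl(aln)
}

empty_psl <- function() {
  finish_psl(tibble(
    matches = integer(), mismatches = integer(), rep_matches = integer(),
    n_count = integer(), q_num_insert = integer(), q_base_insert = integer(),
    t_num_insert = integer(), t_base_insert = integer(),
    strand = character(), qname = character(), qsize = integer(),
    qstart = integer(), qend = integer(), tname = character(),
    tsize = integer(), tstart = integer(), tend = integer(),
    block_count = integer(), block_sizes = list(), q_starts = list(),
    t_starts = list()))
}

finish_psl <- function(aln) {
  aln |> mutate(
    aligned_bases = map_int(.data$block_sizes, function(x) sum(x)),
    gap_count = .data$q_num_insert + .data$t_num_insert,
    score = .data$matches - .data$mismatches - .data$q_num_insert -
      .data$t_num_insert,
    clip_tleft = ifelse(.data$strand == "+", .data$qstart,
                        .data$qsize - .data$qend),
    clip_tright = ifelse(.data$strand == "+", .data$qsize - .data$qend,
                         .data$qstart)
  )
}

#' Write alignments back to PSL
#' @param aln alignment tibble as produced by [read_psl()].
#' @param path output file.
#' @export
write_psl <- function(aln, path) {
  fmt_list <- function(l) vapply(l, function(x) paste0(paste(x, collapse = ","), ","),
                                 character(1))
  lines <- with(aln, paste(
    matches, mismatches, rep_matches, n_count,
    q_num_insert, q_base_insert, t_num_insert, t_base_insert,
    strand, qname, qsize, qstart, qend, tname, tsize, tstart, tend,
    block_count, fmt_list(block_sizes), fmt_list(q_starts),
    fmt_list(t_starts), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Ratio of aligned bases to read bases
#'
#' @param aln alignment tibble.
#' @return numeric vector in `[0, 1]`.
#' @export
aligned_ratio <- function(aln) {
  if (any(aln$qsize <= 0)) abort("read length must be positive")
  aln$aligned_bases / aln$qsize
}

#' Select one alignment per read
#'
#' Implements the three-step filter: (i) the highest-scoring alignment per
#' read is found, with scores within `tie_fraction` (default 2%) of the
#' maximum treated as ties; (ii) among ties the alignment with the largest
#' number of gap openings wins (selecting spliced alignments over unspliced
#' pseudogene hits), remaining ties broken deterministically by smaller
#' target coordinate then target name; (iii) the winner is discarded when its
#' aligned/read ratio is <= `min_ratio` (default 0.6).
#'
#' @param aln alignment tibble (possibly several alignments per `qname`).
#' @param params a [pipeline_params()] object.
#' @param score_mode `"psl"` (default) scores matches - mismatches - gap
#'   openings; `"matches"` scores match count alone.
#' @return alignment tibble with at most one row per read.
#' @export
filter_best_alignment <- function(aln, params = pipeline_params(),
                                  score_mode = params$score_mode) {
  if (nrow(aln) == 0) return(aln)
  sc <- if (score_mode == "matches") aln$matches else aln$score
  aln |>
    mutate(.score = sc) |>
    group_by(.data$qname) |>
    filter(.data$.score >= max(.data$.score) -
             params$tie_fraction * abs(max(.data$.score))) |>
    arrange(desc(.data$gap_count), .data$tstart, .data$tname,
            .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    select(-".score") |>
    filter(.data$aligned_bases / .data$qsize > params$min_aligned_ratio)
}

# long table of alignment blocks: one row per block
alignment_blocks <- function(aln) {
  n <- map_int(aln$block_sizes, length)
  tibble(
    qname = rep(aln$qname, n),
    tname = rep(aln$tname, n),
    strand = rep(aln$strand, n),
    tstart = unlist(aln$t_starts),
    tend = unlist(aln$t_starts) + unlist(aln$block_sizes)
  )
}
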