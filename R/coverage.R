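# Read-covered-base arithmetic. Feature filters measure distances in bases
# covered by at least one alignment block, so uncovered introns do not
# inflate separations.

#' Build a per-base coverage mask from alignment blocks
#'
#' A base is covered when at least one alignment block overlaps it; adding
#' the same alignment twice does not change the mask.
#'
#' @param aln filtered alignment tibble.
#' @param chrom_lengths named integer vector (chromosome -> length); defaults
#'   to the `tsize` values seen in `aln`.
#' @return object of class `coverage_mask`.
#' @export
coverage_mask <- function(aln, chrom_lengths = NULL) {
  if (is.null(chrom_lengths)) {
    chrom_lengths <- aln |> distinct(.data$tname, .data$tsize) |>
      (\(d) setNames(d$tsize, d$tname))()
  }
  blocks <- alignment_blocks(aln)
  masks <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    b <- blocks[blocks$tname == ch, ]
    if (nrow(b) == 0) {
      mask <- logical(len)
    } else {
      cov <- IRanges::coverage(IRanges::IRanges(start = b$tstart + 1L,
                                                end = b$tend),
                               width = len)
      mask <- as.vector(cov) > 0
    }
    list(mask = mask, cum = c(0L, cumsum(mask)))
  })
  structure(setNames(masks, names(chrom_lengths)), class = "coverage_mask")
}

#' @export
print.coverage_mask <- function(x, ...) {
  for (ch in names(x)) {
    cat(sprintf("%s: %d/%d bases covered\n", ch, sum(x[[ch]]$mask),
                length(x[[ch]]$mask)))
  }
  invisible(x)
}

# covered bases between two 0-based boundary coordinates a < b
covered_between <- function(mask, chrom, a, b) {
  cum <- mask[[chrom]]$cum
  lo <- pmin(a, b); hi <- pmax(a, b)
  cum[hi + 1L] - cum[lo + 1L]
}

#' Walk n covered bases along the genome
#'
#' From boundary position `from`, walks in `direction` (+1 right, -1 left)
#' counting only covered bases until `n` are counted; uncovered stretches
#' (introns, intergenic gaps) are skipped over without being counted.
#'
#' @param mask a [coverage_mask()].
#' @param chrom chromosome name.
#' @param from 0-based boundary position.
#' @param n number of covered bases to count.
#' @param direction `+1` (rightward) or `-1`.
#' @return list with `end` (boundary position after the walk), `short`
#'   (`TRUE` when fewer than `n` covered bases exist before the chromosome
#'   boundary) and `covered` (bases actually counted).
#' @export
covered_distance <- function(mask, chrom, from, n, direction = 1L) {
  cm <- mask[[chrom]]
  if (is.null(cm)) abort(paste("unknown chromosome", chrom))
  cum <- cm$cum
  len <- length(cm$mask)
  if (from < 0 || from > len) abort("position outside chromosome")
  if (direction >= 0) {
    avail <- cum[len + 1L] - cum[from + 1L]
    if (avail < n) return(list(end = len, short = TRUE, covered = avail))
    tgt <- cum[from + 1L] + n
    j <- findInterval(tgt - 1L, cum) # last index with cum < tgt, then step
    while (cum[j] < tgt) j <- j + 1L
    list(end = j - 1L, short = FALSE, covered = n)
  } else {
    avail <- cum[from + 1L]
    if (avail < n) return(list(end = 0L, short = TRUE, covered = avail))
    tgt <- cum[from + 1L] - n
    # smallest boundary b with cum[b + 1] == tgt (walk ends just left of the
    # n-th covered base)
    j <- findInterval(tgt, cum)  # first index with cum == tgt
    list(end = j - 1L, short = FALSE, covered = n)
  }
}

# GRanges of alignment blocks with the read id, for windowed read counting
blocks_granges <- function(aln) {
  b <- alignment_blocks(aln)
  gr <- GenomicRanges::GRanges(seqnames = b$tname,
                               ranges = IRanges::IRanges(start = b$tstart + 1L,
                                                         end = b$tend))
  S4Vectors::mcols(gr)$read <- b$qname
  gr
}

# number of distinct reads with >= 1 block overlapping [start, end) on chrom
reads_in_window <- function(blocks_gr, chrom, start, end) {
  if (end <= start) return(0L)
  q <- GenomicRanges::GRanges(seqnames = chrom,
                              ranges = IRanges::IRanges(start = start + 1L,
                                                        end = end))
  hits <- GenomicRanges::findOverlaps(q, blocks_gr)
  length(unique(S4Vectors::mcols(blocks_gr)$read[S4Vectors::subjectHits(hits)]))
}
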