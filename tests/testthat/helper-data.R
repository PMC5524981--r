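# Shared fixtures, built in code and cached for the test session.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# small zero-noise multiplexed dataset: 2 genes x 3 isoforms, 3 cells
desk_dataset <- function() {
  fixture("desk", function() {
    ds <- sim_dataset(2, 3, n_cells = 3, reads_per_cell = 60, seed = 101)
    psl <- tempfile(fileext = ".psl")
    write_truth_alignments(ds$truth, ds$annotation, psl)
    ds$aln <- filter_best_alignment(read_psl(psl))
    ds$trimmed <- preprocess_reads(ds$reads, ds$indexes)
    ds
  })
}

# full small run over the desk dataset
desk_run <- function() {
  fixture("desk_run", function() {
    ds <- desk_dataset()
    run_longform(ds$reads, ds$aln, annotation = ds$annotation,
                 genome = ds$annotation$genome, indexes = ds$indexes)
  })
}

# hand-built single-block alignment tibble (0-based half-open)
mk_aln <- function(read_ids, chrom, tstart, tend, strand = "+",
                   qsize = NULL, blocks = NULL) {
  n <- length(read_ids)
  tstart <- rep(tstart, length.out = n)
  tend <- rep(tend, length.out = n)
  strand <- rep(strand, length.out = n)
  if (is.null(blocks)) {
    blocks <- lapply(seq_len(n), function(i) {
      cbind(start = tstart[i], end = tend[i])
    })
  }
  sizes <- lapply(blocks, function(b) as.integer(b[, 2] - b[, 1]))
  starts <- lapply(blocks, function(b) as.integer(b[, 1]))
  aligned <- vapply(sizes, sum, integer(1))
  qsize <- rep(qsize %||% (aligned + 10L), length.out = n)
  longform:::finish_psl(tibble::tibble(
    matches = aligned, mismatches = 0L, rep_matches = 0L, n_count = 0L,
    q_num_insert = 0L, q_base_insert = 0L,
    t_num_insert = vapply(sizes, function(s) length(s) - 1L, integer(1)),
    t_base_insert = 0L,
    strand = strand, qname = read_ids, qsize = as.integer(qsize),
    qstart = 0L, qend = aligned,
    tname = rep(chrom, length.out = n), tsize = 100000L,
    tstart = as.integer(tstart), tend = as.integer(tend),
    block_count = vapply(sizes, length, integer(1)),
    block_sizes = sizes,
    q_starts = lapply(sizes, function(s) cumsum(c(0L, s))[seq_along(s)]),
    t_starts = starts
  ))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# pure-R Levenshtein dynamic-programming oracle
lev_oracle <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  d <- matrix(0L, n + 1, m + 1)
  d[, 1] <- 0:n; d[1, ] <- 0:m
  for (i in seq_len(n)) for (j in seq_len(m)) {
    d[i + 1, j + 1] <- min(d[i, j] + (ca[i] != cb[j]),
                           d[i, j + 1] + 1L, d[i + 1, j] + 1L)
  }
  d[n + 1, m + 1]
}

rand_seq <- function(len) paste(sample(c("A", "C", "G", "T"), len,
                                       replace = TRUE), collapse = "")

# brute-force oracle for the one-alignment-per-read filter
filter_oracle <- function(aln, tie = 0.02, min_ratio = 0.6) {
  out <- lapply(split(seq_len(nrow(aln)), aln$qname), function(ix) {
    a <- aln[ix, ]
    mx <- max(a$score)
    ties <- a[a$score >= mx - tie * abs(mx), ]
    ties <- ties[order(-ties$gap_count, ties$tstart, ties$tname), ]
    w <- ties[1, ]
    if (w$aligned_bases / w$qsize <= min_ratio) return(NULL)
    w
  })
  dplyr::bind_rows(out)
}

# truth feature tables for recall scoring
truth_sites <- function(ann) {
  tx <- ann$transcripts
  ends <- dplyr::bind_rows(
    dplyr::distinct(tx, chrom, pos = tss) |> dplyr::mutate(type = "TSS"),
    dplyr::distinct(tx, chrom, pos = tes) |> dplyr::mutate(type = "TES"))
  ss <- dplyr::bind_rows(lapply(seq_len(nrow(tx)), function(i) {
    e <- tx$exons[[i]]
    if (nrow(e) < 2) return(NULL)
    don <- if (tx$strand[i] == "+") e[-nrow(e), 2] else e[-1, 1]
    acc <- if (tx$strand[i] == "+") e[-1, 1] else e[-nrow(e), 2]
    tibble::tibble(chrom = tx$chrom[i], pos = c(don, acc),
                   type = rep(c("SS5", "SS3"), c(length(don), length(acc))))
  })) |> dplyr::distinct()
  list(ends = ends, ss = ss)
}

# how many true sites fall inside exactly one bin of the matching type
site_hits <- function(sites, bins) {
  vapply(seq_len(nrow(sites)), function(i) {
    b <- bins[bins$chrom == sites$chrom[i] & bins$type == sites$type[i], ]
    sum(sites$pos[i] >= b$start & sites$pos[i] < b$end)
  }, numeric(1))
}

# bins whose anchor is farther than tol from every true site on its contig
false_bins <- function(bins, sites, tol = 60) {
  if (nrow(bins) == 0) return(0L)
  sum(vapply(seq_len(nrow(bins)), function(i) {
    s <- sites[sites$chrom == bins$chrom[i], ]
    nrow(s) == 0 || min(abs(s$pos - bins$anchor[i])) > tol
  }, logical(1)))
}

# pair isoform groups with truth transcripts through member reads
group_truth_pairing <- function(groups, truth) {
  groups |>
    dplyr::select("group_id", "read_ids") |>
    tidyr::unnest_longer("read_ids", values_to = "read_id") |>
    dplyr::left_join(truth[, c("read_id", "transcript_id", "cell_id")],
                     by = "read_id")
}

acceptance_dataset <- function(noisy, seed = 2024) {
  name <- paste0("acc_", if (noisy) "noisy" else "clean")
  fixture(name, function() {
    ds <- if (noisy) {
      sim_dataset(2, 3, n_cells = 7, reads_per_cell = 2000, seed = seed + 1,
                  substitution_rate = 0.03, insertion_rate = 0.005,
                  deletion_rate = 0.005, truncation_prob = 0.10)
    } else {
      sim_dataset(2, 3, n_cells = 7, reads_per_cell = 500, seed = seed)
    }
    psl <- tempfile(fileext = ".psl")
    write_truth_alignments(ds$truth, ds$annotation, psl)
    ds$run <- run_longform(ds$reads, psl, annotation = ds$annotation,
                           indexes = ds$indexes)
    ds
  })
}

# a locus with two TSS bins 200 bp apart and one TES bin, no splicing
grouping_fixture <- function(n_main, n_minor, extra = NULL) {
  end_bins <- tibble::tibble(
    chrom = "chr1", anchor = c(1000L, 1200L, 3000L),
    start = c(990L, 1190L, 2990L), end = c(1010L, 1210L, 3010L),
    type = c("TSS", "TSS", "TES"), support = 10L, direction = "+",
    bin_id = c("t1", "t2", "e1"))
  aln <- dplyr::bind_rows(
    mk_aln(sprintf("m%d", seq_len(n_main)), "chr1", 1000, 3000),
    if (n_minor > 0) mk_aln(sprintf("x%d", seq_len(n_minor)), "chr1",
                            1200, 3000),
    extra)
  sb <- detect_splice_bins(aln, coverage_mask(aln, c(chr1 = 5000L)))
  ev <- tibble::tibble(event_id = character(), type = character(),
                       chrom = character())
  group_reads_into_isoforms(aln, end_bins, sb, ev)
}

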