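# Isoform grouping, POA consensus, quantification, consensus matching.

test_that("POA consensus of identical sequences is that sequence", {
  for (n in c(1, 2, 5)) {
    expect_equal(poa_consensus(rep("ACGTACGT", n)), "ACGTACGT")
  }
})

test_that("POA consensus equals the per-column majority", {
  expect_equal(poa_consensus(c("ACGT", "ACGT", "ACTT")), "ACGT")
  # random gap-free MSAs with at most one deviating read per column, so the
  # per-column majority is unique and column-wise alignment is optimal
  set.seed(41)
  for (rep in 1:10) {
    len <- 60
    m <- matrix(rep(strsplit(rand_seq(len), "")[[1]], each = 5), nrow = 5)
    for (j in seq_len(len)) {
      if (runif(1) < 0.3) {
        i <- sample(5, 1)
        m[i, j] <- sample(setdiff(c("A", "C", "G", "T"), m[i, j]), 1)
      }
    }
    reads <- apply(m, 1, paste, collapse = "")
    maj <- apply(m, 2, function(col) names(sort(table(col),
                                                decreasing = TRUE))[1])
    expect_equal(poa_consensus(reads), paste(maj, collapse = ""))
  }
})

test_that("POA consensus beats raw reads on noisy input", {
  set.seed(42)
  truth <- rand_seq(800)
  reads <- vapply(1:15, function(i) {
    set.seed(100 + i)
    cpp <- longform:::cpp_mutate_read(truth, 0.05, 0.005, 0.005)
    cpp$seq
  }, character(1))
  cons <- poa_consensus(reads)
  d_cons <- levenshtein(cons, truth)
  d_reads <- levenshtein(reads, truth)
  expect_lt(d_cons, median(d_reads))
  expect_error(poa_consensus(character(0)), "at least one")
})

test_that("the 1% locus-read threshold is boundary inclusive", {
  g <- grouping_fixture(99, 1)        # minor group = exactly 1% of 100 reads
  expect_equal(nrow(g), 2)
  expect_true(1L %in% g$n_reads)
  g2 <- grouping_fixture(199, 1)      # 0.5%: dropped
  expect_equal(nrow(g2), 1)
  expect_equal(g2$n_reads, 199L)
})

test_that("reads beyond the 60-bp end tolerance go unassigned", {
  stray <- mk_aln("stray", "chr1", 1261, 3000)  # 61 bp from nearest TSS
  g <- grouping_fixture(10, 0, extra = stray)
  expect_false(any(vapply(g$read_ids, function(x) "stray" %in% x,
                          logical(1))))
  expect_true("stray" %in% attr(g, "unassigned"))
  edge <- mk_aln("edge", "chr1", 1260, 3000)    # exactly 60 bp: assigned
  g2 <- grouping_fixture(10, 0, extra = edge)
  expect_false("edge" %in% attr(g2, "unassigned"))
})

test_that("retained groups partition their reads", {
  run <- desk_run()
  ids <- unlist(run$groups$read_ids)
  expect_equal(anyDuplicated(ids), 0)
})

test_that("per-cell isoform counts conserve reads and match truth", {
  ds <- desk_dataset()
  run <- desk_run()
  counts <- run$iso_counts
  expect_lte(sum(counts$count), nrow(ds$truth))
  # groups map 1:1 onto true transcripts at zero noise, with exact counts
  member <- run$groups |>
    dplyr::select("group_id", "read_ids") |>
    tidyr::unnest_longer("read_ids", values_to = "read_id") |>
    dplyr::left_join(ds$truth[, c("read_id", "transcript_id", "cell_id")],
                     by = "read_id")
  purity <- member |>
    dplyr::count(.data$group_id, .data$transcript_id) |>
    dplyr::group_by(.data$group_id) |>
    dplyr::mutate(f = .data$n / sum(.data$n))
  expect_true(all(purity$f == 1))
  got <- dplyr::count(member, .data$transcript_id, .data$cell_id)
  want <- dplyr::count(ds$truth, .data$transcript_id, .data$cell_id)
  j <- dplyr::full_join(want, got, by = c("transcript_id", "cell_id"))
  expect_equal(j$n.x, j$n.y)
})

test_that("consensus sequences match truth transcripts at full identity", {
  ds <- desk_dataset()
  run <- desk_run()
  refs <- transcript_sequences(ds$annotation)
  m <- match_consensus_to_transcripts(run$groups, refs)
  expect_true(all(m$identity >= 99))
  expect_true(all(m$direction == "forward"))
})

test_that("noisy three-isoform recovery stays above 99% identity", {
  ds <- sim_dataset(1, 3, n_cells = 2, reads_per_cell = 60, seed = 88,
                    substitution_rate = 0.03, insertion_rate = 0.005,
                    deletion_rate = 0.005)
  psl <- tempfile(fileext = ".psl")
  write_truth_alignments(ds$truth, ds$annotation, psl)
  aln <- filter_best_alignment(read_psl(psl))
  tr <- preprocess_reads(ds$reads, ds$indexes)
  run <- run_longform(ds$reads, aln, annotation = ds$annotation,
                      indexes = ds$indexes)
  expect_gte(nrow(run$groups), 3)
  m <- match_consensus_to_transcripts(run$groups,
                                      transcript_sequences(ds$annotation))
  expect_true(all(m$identity >= 99))
})

test_that("match_consensus_to_transcripts reports identity and strand", {
  set.seed(50)
  ref <- c(T1 = rand_seq(200))
  exact <- match_consensus_to_transcripts(setNames(ref, "c1"), ref)
  expect_equal(exact$identity, 100)
  expect_equal(exact$direction, "forward")
  # two mismatches over 200 columns -> 99%
  mut <- strsplit(ref[[1]], "")[[1]]
  mut[c(50, 150)] <- vapply(mut[c(50, 150)],
                            function(b) setdiff(c("A", "C", "G", "T"), b)[1],
                            character(1))
  two <- match_consensus_to_transcripts(c(c1 = paste(mut, collapse = "")), ref)
  expect_equal(two$identity, 99)
  rc <- match_consensus_to_transcripts(c(c1 = seq_revcomp(ref[[1]])), ref)
  expect_equal(rc$direction, "reverse")
  expect_equal(rc$identity, 100)
  expect_error(match_consensus_to_transcripts(c(c1 = "ACGT"), character(0)),
               "non-empty")
})

test_that("annotation-independent quantification matches transcript-direct", {
  ds <- desk_dataset()
  # annotation-independent: loci from read intervals, no gene models
  eb <- detect_end_bins(ds$aln, ds$trimmed)
  sb <- detect_splice_bins(ds$aln)
  alt <- call_alt_events(ds$aln, sb, ds$trimmed[, c("read_id", "cell_id")])
  g <- group_reads_into_isoforms(ds$aln, eb, sb, alt$events,
                                 ds$trimmed[, c("read_id", "cell_id")],
                                 models = NULL)
  iso <- quantify_isoforms(g, ds$trimmed[, c("read_id", "cell_id")])
  # transcript-direct route
  f <- tempfile(fileext = ".psl")
  write_truth_transcriptome_psl(ds$truth, ds$annotation, f)
  direct <- quantify_transcript_direct(read_psl(f),
                                       ds$trimmed[, c("read_id", "cell_id")])
  # pair groups with transcripts through their member reads
  pairing <- g |> dplyr::select("group_id", "read_ids") |>
    tidyr::unnest_longer("read_ids", values_to = "read_id") |>
    dplyr::left_join(ds$truth[, c("read_id", "transcript_id")], by = "read_id") |>
    dplyr::count(.data$group_id, .data$transcript_id) |>
    dplyr::group_by(.data$group_id) |> dplyr::slice_max(.data$n, n = 1) |>
    dplyr::ungroup()
  j <- iso |>
    dplyr::inner_join(pairing[, c("group_id", "transcript_id")], by = "group_id") |>
    dplyr::inner_join(direct, by = c(transcript_id = "feature_id", "cell_id"))
  r <- cor(j$count.x, j$count.y)
  expect_gte(r, 0.95)
})
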