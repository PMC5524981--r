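# Synthetic locus generator and read simulator.

tx_features <- function(ann) {
  # per transcript: TSS, TES, and the set of splice junctions
  lapply(seq_len(nrow(ann$transcripts)), function(i) {
    tx <- ann$transcripts[i, ]
    ex <- tx$exons[[1]]
    juncs <- if (nrow(ex) > 1) {
      paste(ex[-nrow(ex), 2], ex[-1, 1], sep = "-")
    } else character(0)
    list(tss = tx$tss, tes = tx$tes, juncs = sort(juncs))
  })
}

test_that("locus generation is deterministic and respects counts", {
  a <- generate_toy_locus(1, 1, seed = 7)
  b <- generate_toy_locus(1, 1, seed = 7)
  expect_identical(a, b)
  expect_equal(nrow(a$transcripts), 1)
  c2 <- generate_toy_locus(2, 3, seed = 1)
  expect_equal(nrow(c2$transcripts), 6)
})

test_that("isoforms of one gene differ in at least one feature", {
  ann <- generate_toy_locus(2, 3, seed = 1)
  f <- tx_features(ann)
  for (g in unique(ann$transcripts$gene_id)) {
    ix <- which(ann$transcripts$gene_id == g)
    for (i in ix) for (j in ix) {
      if (i >= j) next
      differs <- f[[i]]$tss != f[[j]]$tss || f[[i]]$tes != f[[j]]$tes ||
        !identical(f[[i]]$juncs, f[[j]]$juncs)
      expect_true(differs)
    }
  }
})

test_that("some isoform pair shares splice sites but differs in TSS", {
  ann <- generate_toy_locus(1, 4, seed = 3)
  f <- tx_features(ann)
  pairs <- utils::combn(length(f), 2)
  found <- any(apply(pairs, 2, function(p) {
    identical(f[[p[1]]]$juncs, f[[p[2]]]$juncs) &&
      f[[p[1]]]$tss != f[[p[2]]]$tss
  }))
  expect_true(found)
})

test_that("invalid generator arguments error", {
  expect_error(generate_toy_locus(0, 1), "n_genes")
  expect_error(generate_toy_locus(1, 0), "isoforms_per_gene")
  expect_error(generate_toy_locus(1, 25), "not supported")
})

test_that("zero-noise reads reproduce the transcript after trimming", {
  ann <- generate_toy_locus(1, 1, seed = 5)
  counts <- tibble::tibble(cell_id = "cell_1",
                           transcript_id = ann$transcripts$transcript_id[1],
                           n = 10L)
  sim <- simulate_reads(ann, counts, sim_params(seed = 2))
  expect_equal(nrow(sim$reads), 10)
  tr <- preprocess_reads(sim$reads, sim$indexes)
  txseq <- transcript_sequences(ann)[[1]]
  residue <- sim_params()$tso_residue
  expect_true(all(tr$complete))
  # trimmed read = TSO residue + transcript + 10 leftover polyA bases
  expect_true(all(tr$sequence == paste0(residue, txseq, strrep("A", 10))))
})

test_that("simulation is byte-identical under a fixed seed", {
  ann <- generate_toy_locus(1, 2, seed = 5)
  counts <- sim_cell_counts(ann, 2, 20, seed = 6)
  s1 <- simulate_reads(ann, counts, sim_params(seed = 3, substitution_rate = 0.02))
  s2 <- simulate_reads(ann, counts, sim_params(seed = 3, substitution_rate = 0.02))
  f1 <- tempfile(); f2 <- tempfile()
  write_reads_fastq(s1$reads, f1); write_reads_fastq(s2$reads, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(s1$truth, s2$truth)
})

test_that("substitution rate produces the expected edit distance", {
  ann <- generate_toy_locus(1, 1, seed = 9)
  txseq <- transcript_sequences(ann)[[1]]
  counts <- tibble::tibble(cell_id = "cell_1",
                           transcript_id = ann$transcripts$transcript_id[1],
                           n = 30L)
  sim <- simulate_reads(ann, counts, sim_params(seed = 4,
                                                substitution_rate = 0.05))
  tr <- preprocess_reads(sim$reads, sim$indexes)
  residue_n <- nchar(sim_params()$tso_residue)
  inserts <- substr(tr$sequence, residue_n + 1L,
                    nchar(tr$sequence) - 10L)
  d <- levenshtein(inserts, txseq)
  n <- nchar(txseq)
  expect_equal(length(unique(nchar(inserts))), 1) # substitutions only
  # mean distance ~ Binomial(n, 0.05) mean, within 3 sigma of the batch mean
  sigma_mean <- sqrt(n * 0.05 * 0.95 / length(d))
  expect_lt(abs(mean(d) - n * 0.05), 3 * sigma_mean)
})

test_that("truth PSL matches exon structure at zero noise", {
  ds <- desk_dataset()
  aln <- ds$aln
  tx <- ds$annotation$transcripts
  for (i in sample(nrow(ds$truth), 20)) {
    rec <- ds$truth[i, ]
    a <- aln[aln$qname == rec$read_id, ]
    ex <- tx$exons[[match(rec$transcript_id, tx$transcript_id)]]
    expect_equal(a$block_count, nrow(ex))
    expect_equal(a$t_starts[[1]], unname(ex[, 1]))
    expect_equal(a$t_starts[[1]] + a$block_sizes[[1]], unname(ex[, 2]))
  }
})

test_that("truncation shortens the aligned span from the 5' end", {
  ann <- generate_toy_locus(1, 1, seed = 11)
  counts <- tibble::tibble(cell_id = "cell_1",
                           transcript_id = ann$transcripts$transcript_id[1],
                           n = 40L)
  sim <- simulate_reads(ann, counts,
                        sim_params(seed = 5, truncation_prob = 1))
  expect_true(all(sim$truth$trunc_len > 0))
  strand <- ann$transcripts$strand[1]
  full_span <- range(ann$transcripts$exons[[1]])
  for (i in seq_len(5)) {
    b <- sim$truth$blocks[[i]]
    if (strand == "+") {
      expect_gt(min(b[, "tstart"]), full_span[1])
    } else {
      expect_lt(max(b[, "tend"]), full_span[2])
    }
  }
})

test_that("PSL line count equals non-degenerate truth records", {
  ds <- desk_dataset()
  psl <- tempfile(fileext = ".psl")
  n <- write_truth_alignments(ds$truth, ds$annotation, psl)
  ok <- sum(vapply(ds$truth$blocks, function(b) !is.null(b) && nrow(b) > 0,
                   logical(1)))
  expect_equal(n, ok)
  expect_equal(length(readLines(psl)), ok)
})

test_that("abundance conservation holds", {
  ds <- desk_dataset()
  got <- dplyr::count(ds$truth, .data$transcript_id, .data$cell_id)
  want <- dplyr::filter(ds$counts, .data$n > 0)
  j <- dplyr::full_join(got, want, by = c("transcript_id", "cell_id"))
  expect_true(all(j$n.x == j$n.y))
})

test_that("degenerate simulator inputs error", {
  ann <- generate_toy_locus(1, 1, seed = 2)
  expect_error(simulate_reads(ann, tibble::tibble(cell_id = character(),
                                                  transcript_id = character(),
                                                  n = integer())),
               "at least one molecule")
  expect_error(simulate_reads(ann, tibble::tibble(cell_id = "c",
                                                  transcript_id = "nope",
                                                  n = 1L)),
               "unknown transcripts")
})
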