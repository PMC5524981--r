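# TSS/TES and splice-site bin detection, classification, and validation.

mk_events <- function(pos, clip_len, clip_seq = "ATGG", side = "left",
                      chrom = "chr1", complete = TRUE, strand = "+") {
  n <- max(length(pos), length(clip_len))
  tibble::tibble(
    chrom = chrom, pos = rep(pos, length.out = n), side = side,
    clip_len = rep(clip_len, length.out = n),
    clip_seq = rep(clip_seq, length.out = n),
    read_id = sprintf("r%d", seq_len(n)), strand = strand,
    cell_id = "c1", complete = complete)
}

test_that("end candidates need support 2 and the clip profile", {
  p <- pipeline_params()
  good <- mk_events(100, c(8, 10))
  cand <- longform:::find_end_candidates(good, p)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$clip_median, 9)
  # a single read is not enough
  expect_equal(nrow(longform:::find_end_candidates(good[1, ], p)), 0)
  # clips {30, 31}: median 30.5 outside [6, 15]
  bad <- mk_events(100, c(30, 31))
  expect_equal(nrow(longform:::find_end_candidates(bad, p)), 0)
})

test_that("bin placement maximizes contained ends (exhaustive oracle)", {
  p <- pipeline_params()
  x <- 500L
  ev <- mk_events(c(x, x + 3L, x + 18L), clip_len = 8)
  cand <- longform:::find_end_candidates(
    dplyr::bind_rows(ev, ev |> dplyr::mutate(read_id = paste0(read_id, "b"))), p)
  bins <- longform:::place_bins(cand, ev, p$bin_width, c("chrom", "side"))
  # exhaustive scan: the only 20-bp window holding all three ends
  best <- max(vapply(1:600, function(s) sum(ev$pos >= s & ev$pos < s + 20),
                     integer(1)))
  expect_equal(max(bins$support), best)
  expect_equal(best, 3L)
  top <- bins[which.max(bins$support), ]
  expect_true(all(ev$pos >= top$start & ev$pos < top$end))
})

test_that("nearby candidates merge into a single best window", {
  p <- pipeline_params()
  ev <- mk_events(rep(c(100L, 105L), each = 3), clip_len = 8)
  cand <- longform:::find_end_candidates(ev, p)
  expect_equal(nrow(cand), 2)
  bins <- longform:::place_bins(cand, ev, p$bin_width, c("chrom", "side"))
  expect_equal(nrow(bins), 1)
  expect_equal(bins$support, 6L)
})

test_that("the 2%-of-window-reads rule keeps and drops bins", {
  p <- pipeline_params()
  # 10 reads covering [100, 400); 2 of them end at 100
  aln <- mk_aln(sprintf("r%d", 1:10), "chr1", 100, 400)
  cov <- coverage_mask(aln, c(chr1 = 1000L))
  bgr <- longform:::blocks_granges(aln)
  bins <- tibble::tibble(chrom = "chr1", side = "left", start = 90L,
                         end = 110L, anchor = 100L, support = 2L,
                         members = list(NULL))
  kept <- longform:::filter_end_bins(bins, cov, bgr, p)
  expect_equal(nrow(kept), 1)  # 2 ends vs 10 reads = 20% >= 2%
  bins$support <- 0L
  expect_equal(nrow(longform:::filter_end_bins(bins, cov, bgr, p)), 0)
})

test_that("close bins resolve to the higher-support one", {
  p <- pipeline_params()
  aln <- mk_aln(sprintf("r%d", 1:20), "chr1", 100, 400)
  cov <- coverage_mask(aln, c(chr1 = 1000L))
  bgr <- longform:::blocks_granges(aln)
  bins <- tibble::tibble(chrom = "chr1", side = "left",
                         start = c(90L, 130L), end = c(110L, 150L),
                         anchor = c(100L, 140L), support = c(10L, 4L),
                         members = list(NULL, NULL))
  kept <- longform:::filter_end_bins(bins, cov, bgr, p) # 40 covered bases apart
  expect_equal(kept$anchor, 100L)
  # at >= 60 covered bases apart both survive
  bins2 <- dplyr::mutate(bins, start = c(90L, 170L), end = c(110L, 190L),
                         anchor = c(100L, 180L))
  expect_equal(nrow(longform:::filter_end_bins(bins2, cov, bgr, p)), 2)
})

test_that("clip motifs classify bins as TSS or TES", {
  p <- pipeline_params()
  mkbin <- function(seqs) {
    tibble::tibble(chrom = "chr1", side = "left", start = 90L, end = 110L,
                   anchor = 100L, support = length(seqs),
                   members = list(tibble::tibble(clip_seq = seqs,
                                                 strand = "+")))
  }
  expect_equal(classify_tss_tes(mkbin(rep("ATGG", 4)), p)$type, "TSS")
  expect_equal(classify_tss_tes(mkbin(rep("TTTT", 4)), p)$type, "TES")
  # polyA clips on the opposite orientation still classify as TES
  expect_equal(classify_tss_tes(mkbin(rep("AAAA", 4)), p)$type, "TES")
  expect_equal(classify_tss_tes(mkbin(rep("CGCG", 4)), p)$type, "unclassified")
  expect_equal(classify_tss_tes(mkbin(character(0)), p)$type, "unclassified")
})

test_that("splice bins require support, the gap rule and separation", {
  p <- pipeline_params()
  # 10 spliced reads sharing a 500-bp intron [300, 800)
  spliced <- mk_aln(sprintf("s%d", 1:10), "chr1", 100, 1000,
                    blocks = rep(list(cbind(c(100, 800), c(300, 1000))), 10))
  sb <- detect_splice_bins(spliced, coverage_mask(spliced, c(chr1 = 2000L)), p)
  expect_equal(sort(unique(sb$type)), c("SS3", "SS5"))
  expect_equal(nrow(sb), 2)
  expect_equal(sb$anchor[sb$type == "SS5"], 300)
  expect_equal(sb$anchor[sb$type == "SS3"], 800)
  # a 40-bp gap is not an intron
  short_gap <- mk_aln(sprintf("g%d", 1:10), "chr1", 100, 640,
                      blocks = rep(list(cbind(c(100, 340), c(300, 640))), 10))
  expect_equal(nrow(detect_splice_bins(
    short_gap, coverage_mask(short_gap, c(chr1 = 2000L)), p)), 0)
  # a gap seen in one read only is not supported
  one <- spliced[1, ]
  expect_equal(nrow(detect_splice_bins(
    one, coverage_mask(one, c(chr1 = 2000L)), p)), 0)
})

test_that("minus-strand reads swap donor and acceptor sides", {
  p <- pipeline_params()
  spliced <- mk_aln(sprintf("s%d", 1:10), "chr1", 100, 1000, strand = "-",
                    blocks = rep(list(cbind(c(100, 800), c(300, 1000))), 10))
  sb <- detect_splice_bins(spliced, coverage_mask(spliced, c(chr1 = 2000L)), p)
  expect_equal(sb$anchor[sb$type == "SS3"], 300)
  expect_equal(sb$anchor[sb$type == "SS5"], 800)
  expect_equal(unique(sb$direction), "-")
})

test_that("CAGE overlap is within 10 bp, boundary inclusive", {
  p <- pipeline_params()
  bins <- tibble::tibble(chrom = "chr1", anchor = c(100L, 100L),
                         bin_id = c("a", "b"), type = "TSS")
  at10 <- validate_cage_overlap(bins[1, ],
                                tibble::tibble(chrom = "chr1", start = 110L,
                                               end = 111L), p)
  expect_true(at10$cage_overlap)
  at11 <- validate_cage_overlap(bins[1, ],
                                tibble::tibble(chrom = "chr1", start = 111L,
                                               end = 112L), p)
  expect_false(at11$cage_overlap)
  none <- validate_cage_overlap(bins, tibble::tibble(chrom = character(),
                                                     start = integer(),
                                                     end = integer()), p)
  expect_false(any(none$cage_overlap))
  expect_error(validate_cage_overlap(bins, tibble::tibble(chrom = "chr1",
                                                          start = 5L,
                                                          end = 2L), p),
               "malformed")
})

test_that("polyA motifs are found strand-aware near TES bins", {
  p <- pipeline_params()
  set.seed(21)
  left <- rand_seq(80)
  genome <- c(chr1 = paste0(left, "AATAAA", rand_seq(40)))
  # anchor 20 bases downstream of the motif start: hit at offset -20
  bins <- tibble::tibble(chrom = "chr1", anchor = 100L, bin_id = "b1",
                         type = "TES", direction = "+")
  hits <- find_polya_signal(bins, genome, p)
  expect_true(nrow(hits) >= 1)
  expect_true(any(hits$motif == "AATAAA" & hits$offset == -20))
  # no motif in window
  genome2 <- c(chr1 = paste(rep("C", 200), collapse = ""))
  expect_equal(nrow(find_polya_signal(bins, genome2, p)), 0)
  # motif on the opposite strand only: no hit for a plus-direction bin
  genome3 <- c(chr1 = paste0(left, seq_revcomp("AATAAA"), rand_seq(40)))
  h3 <- find_polya_signal(bins, genome3, p)
  expect_false(any(h3$motif == "AATAAA" & h3$offset == -20))
  expect_error(find_polya_signal(dplyr::mutate(bins, anchor = 10000L),
                                 genome, p), "outside")
})

test_that("feature bins assign to genes by slopped span containment", {
  ds <- desk_dataset()
  models <- gene_models(ds$annotation)
  bins <- tibble::tibble(
    chrom = c(models$chrom[1], models$chrom[1]),
    anchor = c(min(models$exons[[1]][, 1]) + 10L, 50L),  # inside; intergenic
    bin_id = c("in", "out"), type = "TSS")
  got <- assign_features_to_genes(bins, models)
  expect_equal(got$gene_id[got$bin_id == "in"], models$gene_id[1])
  expect_true(is.na(got$gene_id[got$bin_id == "out"]))
})

test_that("the desk run recovers every true site with clean separations", {
  ds <- desk_dataset()
  run <- desk_run()
  tx <- ds$annotation$transcripts
  # every true TSS/TES inside exactly one bin of the right type
  ends <- dplyr::bind_rows(
    dplyr::distinct(tx, .data$chrom, pos = .data$tss) |>
      dplyr::mutate(type = "TSS"),
    dplyr::distinct(tx, .data$chrom, pos = .data$tes) |>
      dplyr::mutate(type = "TES"))
  for (i in seq_len(nrow(ends))) {
    b <- run$end_bins[run$end_bins$chrom == ends$chrom[i] &
                        run$end_bins$type == ends$type[i], ]
    expect_equal(sum(ends$pos[i] >= b$start & ends$pos[i] < b$end), 1)
  }
  # pairwise separations hold on the output
  for (ch in unique(run$end_bins$chrom)) {
    a <- run$end_bins$anchor[run$end_bins$chrom == ch]
    if (length(a) > 1) expect_gte(min(dist(a)), 60)
    s <- run$splice_bins$anchor[run$splice_bins$chrom == ch]
    if (length(s) > 1) expect_gte(min(dist(s)), 30)
  }
  # a 2-TSS gene reports both its TSS bins
  fg <- assign_features_to_genes(run$end_bins, gene_models(ds$annotation))
  n_tss <- dplyr::count(dplyr::filter(fg, .data$type == "TSS"), .data$gene_id)
  expect_true(all(n_tss$n == 2))
})

test_that("bin types are invariant to reversing every read orientation", {
  ds0 <- sim_dataset(1, 2, n_cells = 2, reads_per_cell = 30, seed = 55,
                     flip_prob = 0)
  ds1 <- sim_dataset(1, 2, n_cells = 2, reads_per_cell = 30, seed = 55,
                     flip_prob = 1)
  get_bins <- function(ds) {
    psl <- tempfile(fileext = ".psl")
    write_truth_alignments(ds$truth, ds$annotation, psl)
    aln <- filter_best_alignment(read_psl(psl))
    tr <- preprocess_reads(ds$reads, ds$indexes)
    detect_end_bins(aln, tr)[, c("chrom", "anchor", "type")]
  }
  expect_equal(get_bins(ds0), get_bins(ds1))
})
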