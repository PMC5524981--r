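# Demultiplexing and ISPCR adaptor trimming.

test_that("levenshtein matches hand-checked values and the DP oracle", {
  expect_equal(levenshtein("ATGG", "ATGG"), 0L)
  expect_equal(levenshtein("", "AC"), 2L)
  expect_equal(levenshtein("ATGG", "TTTT"), 3L)
  set.seed(31)
  for (i in 1:25) {
    a <- rand_seq(sample(0:30, 1)); b <- rand_seq(sample(0:30, 1))
    expect_equal(levenshtein(a, b), lev_oracle(a, b))
    expect_equal(levenshtein(a, b), levenshtein(b, a)) # symmetry
  }
})

test_that("reads with an exact index are assigned and trimmed", {
  set.seed(1)
  idx <- sim_indexes(c("cA", "cB"), seed = 12)
  insert <- rand_seq(300)
  reads <- tibble::tibble(
    read_id = c("r1", "r2", "r3"),
    sequence = c(paste0(idx[["cA"]], insert),
                 paste0(idx[["cB"]], insert),
                 insert))           # no index at all
  dm <- demultiplex(reads, idx)
  expect_equal(dm$cell_id, c("cA", "cB", NA))
  expect_equal(dm$sequence[1], insert)
  expect_equal(dm$sequence[2], insert)
})

test_that("an index with five substitutions still assigns", {
  set.seed(2)
  idx <- sim_indexes(c("cA", "cB"), seed = 13)
  mutated <- strsplit(idx[["cA"]], "")[[1]]
  for (p in c(3, 17, 31, 45, 59)) {
    mutated[p] <- setdiff(c("A", "C", "G", "T"), mutated[p])[1]
  }
  # Smith-Waterman score >= 60 - 2*5 = 50 >= 20
  reads <- tibble::tibble(read_id = "r1",
                          sequence = paste0(paste(mutated, collapse = ""),
                                            rand_seq(300)))
  dm <- demultiplex(reads, idx)
  expect_equal(dm$cell_id, "cA")
  expect_gte(dm$index_score, 20)
})

test_that("reads matching two indexes are dropped as ambiguous", {
  set.seed(3)
  idx <- sim_indexes(c("cA", "cB"), seed = 14)
  reads <- tibble::tibble(read_id = "r1",
                          sequence = paste0(idx[["cA"]], rand_seq(100),
                                            idx[["cB"]]))
  dm <- demultiplex(reads, idx)
  expect_true(is.na(dm$cell_id))
  expect_equal(dm$n_hits, 2L)
})

test_that("duplicate index sequences are a configuration error", {
  expect_error(demultiplex(tibble::tibble(read_id = "r", sequence = "ACGT"),
                           c(a = "AAAA", b = "AAAA")), "duplicate")
})

test_that("demultiplexing is invariant under reverse complementation", {
  set.seed(4)
  idx <- sim_indexes(c("cA", "cB", "cC"), seed = 15)
  insert <- rand_seq(400)
  fwd <- tibble::tibble(read_id = "r1", sequence = paste0(idx[["cB"]], insert))
  rev <- tibble::tibble(read_id = "r1", sequence = seq_revcomp(fwd$sequence))
  expect_equal(demultiplex(fwd, idx)$cell_id, demultiplex(rev, idx)$cell_id)
})

test_that("exact adaptors are found, trimmed and mark the read complete", {
  p <- sim_params()
  set.seed(5)
  insert <- rand_seq(400)
  oligodt_rc <- seq_revcomp(p$oligodt_full)
  read <- paste0(p$tso_adaptor, p$tso_residue, insert, oligodt_rc)
  tr <- trim_ispcr(tibble::tibble(read_id = "r1", sequence = read))
  expect_true(tr$complete)
  expect_equal(tr$dist5, 0L)
  expect_equal(tr$sequence, paste0(p$tso_residue, insert, strrep("A", 10)))
  expect_equal(tr$direction, "5to3")
  # reverse-complemented input: same trimmed sequence, direction flips
  tr2 <- trim_ispcr(tibble::tibble(read_id = "r1",
                                   sequence = seq_revcomp(read)))
  expect_equal(tr2$sequence, tr$sequence)
  expect_equal(tr2$direction, "3to5")
})

test_that("an adaptor on one end only leaves the read incomplete", {
  p <- sim_params()
  set.seed(6)
  insert <- rand_seq(400)
  read <- paste0(p$tso_adaptor, p$tso_residue, insert) # no 3' adaptor
  tr <- trim_ispcr(tibble::tibble(read_id = "r1", sequence = read))
  expect_false(tr$complete)
  expect_true(tr$found5)
  expect_false(tr$found3)
  # 5' end trimmed, 3' end untouched
  expect_equal(tr$sequence, paste0(p$tso_residue, insert))
})

test_that("an adaptor with two edits is still found within distance three", {
  p <- sim_params(); set.seed(7)
  tso <- strsplit(p$tso_adaptor, "")[[1]]
  tso[5] <- "T"; tso[15] <- "G"  # two substitutions (A->T, A->G)
  insert <- rand_seq(300)
  read <- paste0(paste(tso, collapse = ""), p$tso_residue, insert,
                 seq_revcomp(p$oligodt_full))
  tr <- trim_ispcr(tibble::tibble(read_id = "r1", sequence = read),
                   params = pipeline_params(max_adaptor_distance = 3))
  expect_true(tr$complete)
  expect_equal(tr$dist5, 2L)
})

test_that("trimmed output is a contiguous substring of the read or its rc", {
  ds <- desk_dataset()
  raw <- setNames(ds$reads$sequence, ds$reads$read_id)
  for (i in sample(nrow(ds$trimmed), 10)) {
    tr <- ds$trimmed[i, ]
    r <- raw[[tr$read_id]]
    expect_true(grepl(tr$sequence, r, fixed = TRUE) ||
                  grepl(tr$sequence, seq_revcomp(r), fixed = TRUE))
    expect_lte(nchar(tr$sequence), nchar(r))
  }
})

test_that("zero-noise simulated reads demultiplex and trim perfectly", {
  ds <- desk_dataset()
  expect_true(all(ds$trimmed$complete))
  expect_equal(ds$trimmed$cell_id, ds$truth$cell_id)
  # inferred direction mirrors the simulated orientation flip
  expect_equal(ds$trimmed$direction == "3to5", ds$truth$flipped)
})

test_that("reads shorter than twice the adaptor length are left untrimmed", {
  expect_warning(
    tr <- trim_ispcr(tibble::tibble(read_id = "r1", sequence = "ACGTACGT")),
    "untrimmed")
  expect_false(tr$complete)
  expect_equal(tr$sequence, "ACGTACGT")
})

test_that("the local aligner agrees with an independent implementation", {
  set.seed(8)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  for (i in 1:10) {
    a <- rand_seq(40); b <- rand_seq(150)
    got <- longform:::cpp_smith_waterman(a, b, 1L, -1L, -1L)[1]
    want <- Biostrings::pairwiseAlignment(a, b, type = "local",
                                          substitutionMatrix = mat,
                                          gapOpening = 0, gapExtension = 1,
                                          scoreOnly = TRUE)
    expect_equal(got, max(0, want))
  }
})
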