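# Synthetic multi-isoform loci and full-length cDNA reads with ground truth.
#
# The generator emulates spike-in style artificial gene loci: each gene lives
# on its own contig (like SIRV loci), carries up to 19 isoforms built from a
# canonical 5-exon model by alternative TSS, alternative TES, alternative
# donor/acceptor usage, intron retention and exon skipping, and is transcribed
# into full-length cDNA reads flanked by ISPCR adaptors, an optional 60-nt
# cell index, a TSO residue and a polyA tail. All randomness flows through a
# single seed, so identical parameters give byte-identical output.

ISPCR <- "AAGCAGTGGTATCAACGCAGAGT"

#' Simulation parameters
#'
#' @param substitution_rate,insertion_rate,deletion_rate per-base error rates
#'   applied to the transcript-derived insert (adaptor bases are left intact).
#' @param truncation_prob probability that a molecule is 5'-truncated.
#' @param truncation_mean mean of the geometric truncation length (bases).
#' @param polya_len length of the polyA tail appended 3' of the insert.
#' @param tso_adaptor ISPCR sequence searched at the 5' end.
#' @param tso_residue TSO bases left between the adaptor and the insert;
#'   they remain as the 5' soft clip after trimming and end in the `ATGG`
#'   motif used to classify TSS bins.
#' @param oligodt_trim_t number of polyA-pairing T bases included in the 3'
#'   trim pattern; `polya_len - oligodt_trim_t` A's remain as the 3' clip.
#' @param flip_prob fraction of reads emitted as the reverse complement
#'   (unstranded sequencing).
#' @param indexes optional named character vector (cell id -> 60-nt index);
#'   generated on demand when `NULL`.
#' @param seed integer seed controlling all randomness.
#' @return a named list of class `sim_params`.
#' @export
sim_params <- function(substitution_rate = 0, insertion_rate = 0,
                       deletion_rate = 0, truncation_prob = 0,
                       truncation_mean = 150, polya_len = 30L,
                       tso_adaptor = ISPCR, tso_residue = "ACATGG",
                       oligodt_trim_t = 20L, flip_prob = 0.5,
                       indexes = NULL, seed = 1L) {
  rates <- c(substitution_rate, insertion_rate, deletion_rate,
             truncation_prob, flip_prob)
  if (any(rates < 0 | rates > 1)) abort("rates must lie in [0, 1]")
  if (oligodt_trim_t >= polya_len + 5L) {
    abort("oligodt_trim_t must be smaller than polya_len")
  }
  structure(list(
    substitution_rate = substitution_rate, insertion_rate = insertion_rate,
    deletion_rate = deletion_rate, truncation_prob = truncation_prob,
    truncation_mean = truncation_mean, polya_len = as.integer(polya_len),
    tso_adaptor = tso_adaptor, tso_residue = tso_residue,
    oligodt_full = paste0(tso_adaptor, "AC", strrep("T", polya_len)),
    oligodt_trim = paste0(tso_adaptor, "AC", strrep("T", oligodt_trim_t)),
    oligodt_trim_t = as.integer(oligodt_trim_t), flip_prob = flip_prob,
    indexes = indexes, seed = as.integer(seed)
  ), class = "sim_params")
}

# transcript-variant edits on a matrix of genomic exon intervals
# (0-based half-open, rows ascending), strand-aware in transcript terms
variant_edit <- function(ex, strand, kind, round) {
  n <- nrow(ex)
  d_tss <- 120L * round; d_ss <- 60L * round; d_tes <- 120L * round
  tx2g <- function(i) if (strand == "+") i else n + 1L - i
  switch(kind,
    canonical = ex,
    alt_tss = { i <- tx2g(1L)
      if (strand == "+") ex[i, 1] <- ex[i, 1] + d_tss else ex[i, 2] <- ex[i, 2] - d_tss
      ex },
    alt_tes = { i <- tx2g(n)
      if (strand == "+") ex[i, 2] <- ex[i, 2] - d_tes else ex[i, 1] <- ex[i, 1] + d_tes
      ex },
    alt_donor = { # donor of transcript intron 2 moved d_ss into exon 2
      i <- tx2g(2L)
      if (strand == "+") ex[i, 2] <- ex[i, 2] - d_ss else ex[i, 1] <- ex[i, 1] + d_ss
      ex },
    alt_acceptor = { # acceptor of transcript intron 4 moved d_ss into exon 5
      i <- tx2g(5L)
      if (strand == "+") ex[i, 1] <- ex[i, 1] + d_ss else ex[i, 2] <- ex[i, 2] - d_ss
      ex },
    retention = { # retain transcript intron (4 - round)
      j <- 4L - round
      i <- sort(c(tx2g(j), tx2g(j + 1L)))
      ex[i[1], 2] <- ex[i[2], 2]
      ex[-i[2], , drop = FALSE] },
    skipping = { # skip transcript exon (5 - round)
      ex[-tx2g(5L - round), , drop = FALSE] },
    abort(paste("unknown variant kind", kind))
  )
}

VARIANT_KINDS <- c("alt_tss", "alt_donor", "alt_tes",
                   "retention", "skipping", "alt_acceptor")

#' Generate a toy multi-isoform annotation
#'
#' Builds `n_genes` independent loci (one contig each, alternating strand).
#' Each gene starts from a canonical 5-exon transcript; additional isoforms
#' cycle through alternative TSS (+120 bp per round), alternative donor
#' (+60 bp), alternative TES (-120 bp), intron retention, exon skipping and
#' alternative acceptor, so that every isoform pair differs in at least one
#' of TSS, TES, splice-site usage or a retained intron. Distinct TSS/TES are
#' at least 120 bp apart and distinct splice sites at least 60 bp apart, so
#' all programmed features are resolvable by 20-bp binning with 60-bp end
#' separation and 30-bp splice-site separation. An `AATAAA` polyA signal is
#' planted about 25 bp upstream of every distinct TES.
#'
#' @param n_genes number of gene loci (>= 1).
#' @param isoforms_per_gene isoforms per gene (1--19 with the default
#'   geometry).
#' @param seed integer seed; the same seed reproduces the annotation exactly.
#' @param exon_base,intron_range baseline exon length and intron length range
#'   in bases.
#' @return an object of class `toy_annotation`: a list with `genome` (named
#'   character), `genes` and `transcripts` tibbles (`exons` is a list column
#'   of 0-based half-open interval matrices, ascending).
#' @export
generate_toy_locus <- function(n_genes, isoforms_per_gene, seed = 1L,
                               exon_base = 220L, intron_range = c(200L, 500L)) {
  stopifnot_scalar_count(n_genes, "n_genes")
  stopifnot_scalar_count(isoforms_per_gene, "isoforms_per_gene")
  if (isoforms_per_gene > 19) {
    abort("isoforms_per_gene > 19 is not supported by the default locus geometry")
  }
  set.seed(seed)
  n_exons <- 5L
  rounds <- max(1L, as.integer(ceiling((isoforms_per_gene - 1L) / 6L)))
  flank <- 500L

  genome <- character(0)
  genes <- list(); txs <- list()
  for (g in seq_len(n_genes)) {
    chrom <- sprintf("locus_%d", g)
    strand <- if (g %% 2L == 1L) "+" else "-"
    # exon lengths sized so every round's edit leaves >= 80 exonic bases
    need <- c(120L * rounds, 60L * rounds, 0L, 0L, 180L * rounds)
    ex_len <- exon_base + need + sample(0:80, n_exons, replace = TRUE)
    in_len <- sample(intron_range[1]:intron_range[2], n_exons - 1L, replace = TRUE)
    starts <- flank + cumsum(c(0L, head(ex_len, -1) + in_len))
    ex <- cbind(start = starts, end = starts + ex_len)
    gene_id <- sprintf("gene_%d", g)

    kinds <- c("canonical",
               rep(VARIANT_KINDS, rounds)[seq_len(isoforms_per_gene - 1L)])
    rounds_of <- c(0L, ((seq_len(isoforms_per_gene - 1L) - 1L) %/% 6L) + 1L)
    for (i in seq_len(isoforms_per_gene)) {
      exi <- variant_edit(ex, strand, kinds[i], rounds_of[i])
      txs[[length(txs) + 1L]] <- tibble(
        transcript_id = sprintf("%s_tx%d", gene_id, i),
        gene_id = gene_id, chrom = chrom, strand = strand,
        variant = kinds[i],
        tss = if (strand == "+") exi[1, 1] else exi[nrow(exi), 2],
        tes = if (strand == "+") exi[nrow(exi), 2] else exi[1, 1],
        exons = list(exi)
      )
    }
    gene_end <- max(ex[, 2])
    chrom_len <- gene_end + flank
    seqchars <- sample(BASES, chrom_len, replace = TRUE)
    genes[[g]] <- tibble(gene_id = gene_id, chrom = chrom, strand = strand,
                         start = min(ex[, 1]), end = gene_end,
                         chrom_len = chrom_len)
    # plant a polyA signal ~25 bp upstream (transcript sense) of each TES
    tes_pos <- unique(vapply(txs[vapply(txs, function(t) t$gene_id == gene_id,
                                        logical(1))],
                             function(t) t$tes, numeric(1)))
    for (tp in tes_pos) {
      if (strand == "+") {
        seqchars[(tp - 30L):(tp - 25L)] <- strsplit("AATAAA", "")[[1]]
      } else {
        seqchars[(tp + 25L):(tp + 30L)] <- strsplit("TTTATT", "")[[1]]
      }
    }
    genome[chrom] <- paste(seqchars, collapse = "")
  }
  ann <- structure(list(genome = genome,
                        genes = bind_rows(genes),
                        transcripts = bind_rows(txs)),
                   class = "toy_annotation")
  validate_annotation(ann)
  ann
}

validate_annotation <- function(ann) {
  for (i in seq_len(nrow(ann$transcripts))) {
    tx <- ann$transcripts[i, ]
    ex <- tx$exons[[1]]
    clen <- nchar(ann$genome[[tx$chrom]])
    if (any(ex[, 1] < 0) || any(ex[, 2] > clen)) {
      abort(sprintf("transcript %s has exons outside chromosome bounds",
                    tx$transcript_id))
    }
    if (nrow(ex) > 1 && any(ex[-1, 1] <= ex[-nrow(ex), 2])) {
      abort(sprintf("transcript %s has overlapping or unordered exons",
                    tx$transcript_id))
    }
  }
  invisible(ann)
}

#' @export
print.toy_annotation <- function(x, ...) {
  cat(sprintf("<toy_annotation> %d gene(s), %d transcript(s), %d contig(s)\n",
              nrow(x$genes), nrow(x$transcripts), length(x$genome)))
  invisible(x)
}

#' Spliced transcript sequences (transcript sense)
#'
#' @param annotation a `toy_annotation`.
#' @return named character vector of spliced transcript sequences.
#' @export
transcript_sequences <- function(annotation) {
  out <- vapply(seq_len(nrow(annotation$transcripts)), function(i) {
    tx <- annotation$transcripts[i, ]
    ex <- tx$exons[[1]]
    parts <- substring(annotation$genome[[tx$chrom]], ex[, 1] + 1L, ex[, 2])
    s <- paste(parts, collapse = "")
    if (tx$strand == "-") seq_revcomp(s) else s
  }, character(1))
  setNames(out, annotation$transcripts$transcript_id)
}

#' Simulate per-cell transcript abundances
#'
#' Per gene, baseline isoform proportions decrease linearly (k:...:1). With
#' `differential = TRUE` each cell rotates the proportion vector by its cell
#' index, creating strong cell-to-cell differential isoform usage; with
#' `FALSE` all cells share the baseline (a null dataset).
#'
#' @param annotation a `toy_annotation`.
#' @param n_cells number of cells.
#' @param reads_per_cell sequenced molecules per cell.
#' @param seed integer seed.
#' @param differential rotate isoform proportions per cell?
#' @return tibble (cell_id, transcript_id, n) of molecule counts.
#' @export
sim_cell_counts <- function(annotation, n_cells = 7L, reads_per_cell = 500L,
                            seed = 1L, differential = TRUE) {
  set.seed(seed)
  tx <- annotation$transcripts
  genes <- unique(tx$gene_id)
  out <- list()
  for (ci in seq_len(n_cells)) {
    cell <- sprintf("cell_%d", ci)
    probs <- numeric(0)
    for (g in genes) {
      ids <- tx$transcript_id[tx$gene_id == g]
      k <- length(ids)
      base <- rev(seq_len(k))
      rot <- if (differential && k > 1) (ci - 1L) %% k else 0L
      if (rot > 0) base <- c(base[-seq_len(rot)], base[seq_len(rot)])
      probs <- c(probs, setNames(base / sum(base) / length(genes), ids))
    }
    n <- as.integer(rmultinom(1, reads_per_cell, probs))
    out[[ci]] <- tibble(cell_id = cell, transcript_id = names(probs), n = n)
  }
  bind_rows(out)
}

#' Generate cell index sequences
#'
#' @param cell_ids character vector of cell ids.
#' @param length index length in nucleotides.
#' @param seed integer seed.
#' @return named character vector (cell id -> index sequence).
#' @export
sim_indexes <- function(cell_ids, length = 60L, seed = 1L) {
  set.seed(seed)
  setNames(rand_dna(length, length(cell_ids)), cell_ids)
}

# exon chain with transcript-local offsets, in transcript order
tx_chain <- function(ex, strand) {
  if (strand == "-") ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
  len <- ex[, 2] - ex[, 1]
  tibble(gstart = ex[, 1], gend = ex[, 2],
         lstart = cumsum(c(0L, head(len, -1))),
         lend = cumsum(len))
}

# map a transcript-local interval [a, b) onto genomic blocks via the chain
local_to_genomic <- function(a, b, chain, strand) {
  hit <- which(chain$lend > a & chain$lstart < b)
  lapply(hit, function(j) {
    aa <- max(a, chain$lstart[j]); bb <- min(b, chain$lend[j])
    if (strand == "+") {
      c(gstart = chain$gstart[j] + (aa - chain$lstart[j]),
        gend   = chain$gstart[j] + (bb - chain$lstart[j]),
        la = aa, lb = bb)
    } else {
      c(gstart = chain$gend[j] - (bb - chain$lstart[j]),
        gend   = chain$gend[j] - (aa - chain$lstart[j]),
        la = aa, lb = bb)
    }
  })
}

#' Simulate full-length cDNA reads with ground truth
#'
#' Each molecule is emitted as `[index] + ISPCR + TSO residue + insert +
#' polyA + revcomp(ISPCR + AC)` where the insert is the (possibly
#' 5'-truncated) transcript sequence carrying substitution/indel errors; half
#' the reads are reverse complemented. The truth table records, per read, the
#' source transcript, cell, and the exact genomic alignment blocks of the
#' *trimmed* read (adaptors and index removed, orientation normalized to the
#' cDNA sense), split at every simulated indel.
#'
#' @param annotation a `toy_annotation`.
#' @param counts tibble (cell_id, transcript_id, n) as from
#'   [sim_cell_counts()]; transcripts must exist in the annotation.
#' @param params a [sim_params()] object.
#' @return list with `reads` (tibble read_id, sequence), `truth` (one row per
#'   read) and `indexes` (named character).
#' @export
simulate_reads <- function(annotation, counts, params = sim_params()) {
  if (nrow(counts) == 0 || sum(counts$n) == 0) {
    abort("counts must contain at least one molecule")
  }
  bad <- setdiff(counts$transcript_id, annotation$transcripts$transcript_id)
  if (length(bad)) abort(paste("unknown transcripts:", paste(bad, collapse = ", ")))
  if (any(counts$n < 0)) abort("abundances must be non-negative")

  set.seed(params$seed)
  cells <- sort(unique(counts$cell_id))
  indexes <- params$indexes %||% setNames(rand_dna(60L, length(cells)), cells)
  txseqs <- transcript_sequences(annotation)
  txinfo <- annotation$transcripts
  chains <- setNames(lapply(seq_len(nrow(txinfo)), function(i) {
    tx_chain(txinfo$exons[[i]], txinfo$strand[i])
  }), txinfo$transcript_id)

  tail3 <- seq_revcomp(params$oligodt_full)  # polyA + GT + rc(ISPCR)
  residue <- params$tso_residue
  leftover <- params$polya_len - params$oligodt_trim_t

  counts <- counts |> filter(.data$n > 0) |>
    arrange(.data$cell_id, .data$transcript_id)
  total <- sum(counts$n)
  reads <- character(total); rid <- character(total)
  t_cell <- character(total); t_tx <- character(total); t_gene <- character(total)
  t_chrom <- character(total); t_strand <- character(total)
  t_flip <- logical(total); t_trunc <- integer(total); t_nsub <- integer(total)
  t_qsize <- integer(total); t_qstart <- integer(total); t_qend <- integer(total)
  t_blocks <- vector("list", total)
  k <- 0L
  for (r in seq_len(nrow(counts))) {
    cell <- counts$cell_id[r]; txid <- counts$transcript_id[r]
    info <- txinfo[txinfo$transcript_id == txid, ]
    chain <- chains[[txid]]
    txseq <- txseqs[[txid]]; txlen <- nchar(txseq)
    for (m in seq_len(counts$n[r])) {
      k <- k + 1L
      id <- sprintf("read_%06d", k)
      t0 <- 0L
      if (params$truncation_prob > 0 && runif(1) < params$truncation_prob &&
          txlen > 100L) {
        t0 <- min(rgeom(1, 1 / params$truncation_mean) + 1L, txlen - 50L)
      }
      mut <- cpp_mutate_read(substring(txseq, t0 + 1L, txlen),
                             params$substitution_rate,
                             params$insertion_rate, params$deletion_rate)
      sense <- paste0(indexes[[cell]], params$tso_adaptor, residue,
                      mut$seq, tail3)
      flip <- runif(1) < params$flip_prob
      reads[k] <- if (flip) seq_revcomp(sense) else sense
      rid[k] <- id

      map <- mut$map
      blocks <- NULL
      if (nrow(map) > 0) {
        qoff <- nchar(residue)
        sub_blocks <- list()
        for (b in seq_len(nrow(map))) {
          o0 <- unname(map[b, 1]) + t0; o1 <- o0 + unname(map[b, 3])
          parts <- local_to_genomic(o0, o1, chain, info$strand)
          for (p in parts) {
            sub_blocks[[length(sub_blocks) + 1L]] <- c(
              tstart = unname(p["gstart"]), tend = unname(p["gend"]),
              qstart = qoff + unname(map[b, 2]) + (unname(p["la"]) - o0),
              lstart = unname(p["la"]))
          }
        }
        blocks <- do.call(rbind, sub_blocks)
        blocks <- blocks[order(blocks[, "lstart"]), , drop = FALSE]
      }
      t_cell[k] <- cell; t_tx[k] <- txid; t_gene[k] <- info$gene_id
      t_chrom[k] <- info$chrom; t_strand[k] <- info$strand
      t_flip[k] <- flip; t_trunc[k] <- t0; t_nsub[k] <- mut$n_sub
      t_qsize[k] <- nchar(residue) + nchar(mut$seq) + leftover
      if (is.null(blocks)) {
        t_qstart[k] <- NA_integer_; t_qend[k] <- NA_integer_
      } else {
        nb <- nrow(blocks)
        t_qstart[k] <- blocks[1, "qstart"]
        t_qend[k] <- blocks[nb, "qstart"] + (blocks[nb, "tend"] - blocks[nb, "tstart"])
      }
      t_blocks[[k]] <- blocks
    }
  }
  truth <- tibble(
    read_id = rid, cell_id = t_cell, transcript_id = t_tx, gene_id = t_gene,
    chrom = t_chrom, strand = t_strand, complete = TRUE, flipped = t_flip,
    trunc_len = t_trunc, n_sub = t_nsub, q_size = t_qsize,
    q_start = t_qstart, q_end = t_qend, blocks = t_blocks)
  list(reads = tibble(read_id = rid, sequence = reads),
       truth = truth, indexes = indexes)
}

#' Write ground-truth alignments as PSL
#'
#' One line per read whose trimmed sequence overlaps at least one exon;
#' blocks are the true exonic blocks of the (possibly truncated) read, split
#' at simulated indels. Standard 21-column PSL, 0-based half-open, no header.
#' Reads spanning no exon are excluded with a warning.
#'
#' @param truth truth tibble from [simulate_reads()].
#' @param annotation the `toy_annotation` the reads were simulated from.
#' @param path output file.
#' @return invisibly, the number of PSL lines written.
#' @export
write_truth_alignments <- function(truth, annotation, path) {
  if (nrow(truth) == 0) abort("truth table is empty")
  chrom_len <- setNames(nchar(annotation$genome), names(annotation$genome))
  lines <- character(nrow(truth)); n <- 0L; dropped <- 0L
  tr_strand <- truth$strand; tr_nsub <- truth$n_sub; tr_qsize <- truth$q_size
  tr_qstart <- truth$q_start; tr_qend <- truth$q_end
  tr_chrom <- truth$chrom; tr_id <- truth$read_id
  for (i in seq_len(nrow(truth))) {
    blocks <- truth$blocks[[i]]
    if (is.null(blocks) || nrow(blocks) == 0) { dropped <- dropped + 1L; next }
    # order blocks by ascending target coordinate for PSL
    ord <- order(blocks[, "tstart"])
    bl <- blocks[ord, , drop = FALSE]
    sizes <- bl[, "tend"] - bl[, "tstart"]
    aligned <- sum(sizes)
    mism <- tr_nsub[i]
    # gap bookkeeping in transcript (query) order
    txo <- blocks[order(blocks[, "lstart"]), , drop = FALSE]
    qgaps <- diff(txo[, "qstart"]) -
      (txo[-nrow(txo), "tend"] - txo[-nrow(txo), "tstart"])
    if (tr_strand[i] == "+") {
      tgaps <- txo[-1, "tstart"] - txo[-nrow(txo), "tend"]
    } else {
      tgaps <- txo[-nrow(txo), "tstart"] - txo[-1, "tend"]
    }
    q_num_ins <- sum(qgaps > 0); q_base_ins <- sum(qgaps[qgaps > 0])
    t_num_ins <- sum(tgaps > 0); t_base_ins <- sum(tgaps[tgaps > 0])
    qsize <- tr_qsize[i]
    if (tr_strand[i] == "+") {
      qstarts <- bl[, "qstart"]
    } else {
      qstarts <- qsize - (bl[, "qstart"] + sizes) # reversed-query coords
    }
    n <- n + 1L
    lines[n] <- paste(
      aligned - mism, mism, 0L, 0L,
      q_num_ins, q_base_ins, t_num_ins, t_base_ins,
      tr_strand[i], tr_id[i], qsize, tr_qstart[i], tr_qend[i],
      tr_chrom[i], chrom_len[[tr_chrom[i]]], bl[1, "tstart"], bl[nrow(bl), "tend"],
      nrow(bl),
      paste0(paste(sizes, collapse = ","), ","),
      paste0(paste(qstarts, collapse = ","), ","),
      paste0(paste(bl[, "tstart"], collapse = ","), ","),
      sep = "\t")
  }
  if (dropped > 0) warn(sprintf("%d read(s) spanned no exon and were excluded",
                                dropped))
  writeLines(lines[seq_len(n)], path)
  invisible(n)
}

#' Write ground-truth transcriptome alignments as PSL
#'
#' Alignments of each trimmed read against its source transcript (one PSL
#' target per transcript), blocks split at simulated indels only — the
#' stand-in for aligning reads directly to a spliced transcriptome.
#'
#' @param truth truth tibble from [simulate_reads()].
#' @param annotation the source `toy_annotation`.
#' @param path output PSL file.
#' @return invisibly, the number of lines written.
#' @export
write_truth_transcriptome_psl <- function(truth, annotation, path) {
  if (nrow(truth) == 0) abort("truth table is empty")
  txlen <- nchar(transcript_sequences(annotation))
  lines <- character(nrow(truth)); n <- 0L
  for (i in seq_len(nrow(truth))) {
    blocks <- truth$blocks[[i]]
    if (is.null(blocks) || nrow(blocks) == 0) next
    bl <- blocks[order(blocks[, "lstart"]), , drop = FALSE]
    size <- bl[, "tend"] - bl[, "tstart"]
    # merge sub-blocks split only at exon junctions (contiguous in both
    # transcript-local and query coordinates)
    ls <- bl[, "lstart"]; qs <- bl[, "qstart"]
    keep <- c(TRUE, !(ls[-1] == (ls + size)[-nrow(bl)] &
                        qs[-1] == (qs + size)[-nrow(bl)]))
    grp <- cumsum(keep)
    m_ls <- tapply(ls, grp, min); m_qs <- tapply(qs, grp, min)
    m_sz <- tapply(size, grp, sum)
    qgaps <- diff(m_qs) - head(m_sz, -1)
    tgaps <- diff(m_ls) - head(m_sz, -1)
    aligned <- sum(m_sz); mism <- truth$n_sub[i]
    n <- n + 1L
    lines[n] <- paste(
      aligned - mism, mism, 0L, 0L,
      sum(qgaps > 0), sum(qgaps[qgaps > 0]),
      sum(tgaps > 0), sum(tgaps[tgaps > 0]),
      "+", truth$read_id[i], truth$q_size[i], truth$q_start[i],
      truth$q_end[i], truth$transcript_id[i],
      txlen[[truth$transcript_id[i]]], m_ls[1],
      m_ls[length(m_ls)] + m_sz[length(m_sz)], length(m_sz),
      paste0(paste(m_sz, collapse = ","), ","),
      paste0(paste(m_qs, collapse = ","), ","),
      paste0(paste(m_ls, collapse = ","), ","),
      sep = "\t")
  }
  writeLines(lines[seq_len(n)], path)
  invisible(n)
}

#' Write simulated reads as FASTQ
#'
#' @param reads tibble (read_id, sequence).
#' @param path output FASTQ file.
#' @export
write_reads_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(setNames(reads$sequence, reads$read_id))
  q <- Biostrings::PhredQuality(vapply(nchar(reads$sequence),
                                       function(n) strrep("I", n), character(1)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Read a FASTQ/FASTA file into a read tibble
#'
#' @param path FASTQ (default) or FASTA file.
#' @param format "fastq" or "fasta".
#' @return tibble (read_id, sequence).
#' @export
read_reads <- function(path, format = c("fastq", "fasta")) {
  format <- match.arg(format)
  x <- Biostrings::readDNAStringSet(path, format = format)
  tibble(read_id = sub("\\s.*$", "", names(x)), sequence = as.character(x))
}

#' Write the simulated genome as FASTA
#' @param annotation a `toy_annotation`.
#' @param path output FASTA file.
#' @export
write_genome_fasta <- function(annotation, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(annotation$genome), path)
  invisible(path)
}

#' Export the toy annotation as GTF
#'
#' Exon features with gene_id/transcript_id attributes (GENCODE-style).
#' @param annotation a `toy_annotation`.
#' @param path output GTF file.
#' @export
write_annotation_gtf <- function(annotation, path) {
  tx <- annotation$transcripts
  rows <- lapply(seq_len(nrow(tx)), function(i) {
    ex <- tx$exons[[i]]
    GenomicRanges::GRanges(
      seqnames = tx$chrom[i],
      ranges = IRanges::IRanges(start = ex[, 1] + 1L, end = ex[, 2]),
      strand = tx$strand[i], type = "exon",
      gene_id = tx$gene_id[i], transcript_id = tx$transcript_id[i])
  })
  gr <- suppressWarnings(do.call(c, rows))
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Write the truth table as TSV
#' @param truth truth tibble from [simulate_reads()].
#' @param path output TSV file.
#' @export
write_truth_table <- function(truth, path) {
  flat <- truth |> select(-"blocks")
  utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Simulate a complete dataset
#'
#' Convenience wrapper: annotation, per-cell abundances, indexes, reads and
#' ground truth in one call, all driven by one seed.
#'
#' @param n_genes,isoforms_per_gene locus layout (see [generate_toy_locus()]).
#' @param n_cells,reads_per_cell sequencing depth layout.
#' @param seed master seed.
#' @param differential cell-dependent isoform proportions?
#' @param ... overrides passed to [sim_params()] (error rates etc.).
#' @return list (annotation, counts, reads, truth, indexes, params).
#' @export
sim_dataset <- function(n_genes = 2L, isoforms_per_gene = 3L, n_cells = 7L,
                        reads_per_cell = 500L, seed = 1L,
                        differential = TRUE, ...) {
  ann <- generate_toy_locus(n_genes, isoforms_per_gene, seed = seed)
  counts <- sim_cell_counts(ann, n_cells, reads_per_cell, seed = seed + 1L,
                            differential = differential)
  sp <- sim_params(seed = seed + 2L, ...)
  sim <- simulate_reads(ann, counts, sp)
  c(list(annotation = ann, counts = counts, params = sp), sim)
}
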