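# End-to-end orchestration: preprocess -> filter alignments -> quantify ->
# detect features -> alternative splicing -> isoform groups + consensus ->
# differential usage, with a machine-readable run summary.

#' Run the full pipeline
#'
#' All analysis stages are deterministic; only the read simulator draws
#' random numbers. Inputs may be in-memory objects (tibbles from the
#' simulator/preprocessor) or file paths (FASTQ reads, PSL alignments, GTF
#' annotation, FASTA genome, TSV indexes, BED CAGE peaks).
#'
#' @param reads read tibble or FASTQ path.
#' @param psl alignment tibble (from [read_psl()]) or PSL path.
#' @param annotation `toy_annotation`, gene-model tibble, or GTF path; `NULL`
#'   runs annotation-independent locus detection.
#' @param genome named character vector or FASTA path (enables polyA-signal
#'   profiling); optional.
#' @param indexes named character vector, TSV path (`cell_id<TAB>sequence`),
#'   or `NULL` for a non-multiplexed run.
#' @param cage BED path or peak tibble; optional.
#' @param params a [pipeline_params()] object.
#' @param outdir directory for per-stage outputs; nothing is written when
#'   `NULL`.
#' @return list of class `longform_run` with elements `trimmed`, `alignments`,
#'   `expression`, `end_bins`, `splice_bins`, `combinations`, `events`,
#'   `groups`, `iso_counts`, `complex_genes`, `tests` and `summary`.
#' @export
run_longform <- function(reads, psl, annotation = NULL, genome = NULL,
                         indexes = NULL, cage = NULL,
                         params = pipeline_params(), outdir = NULL) {
  if (is.character(reads)) reads <- read_reads(reads)
  if (is.character(psl)) psl <- read_psl(psl)
  if (is.character(indexes) && length(indexes) == 1 && is.null(names(indexes))) {
    tab <- utils::read.table(indexes, sep = "\t", header = FALSE,
                             col.names = c("cell_id", "sequence"))
    indexes <- setNames(tab$sequence, tab$cell_id)
  }
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    x <- Biostrings::readDNAStringSet(genome)
    genome <- setNames(as.character(x), sub("\\s.*$", "", names(x)))
  }
  models <- resolve_models(annotation)

  trimmed <- preprocess_reads(reads, indexes, params = params)
  read_cells <- trimmed |> select("read_id", "cell_id")

  aln <- filter_best_alignment(psl, params)
  cov <- coverage_mask(aln)

  totals <- aln |>
    left_join(read_cells, by = c(qname = "read_id")) |>
    mutate(cell_id = ifelse(is.na(.data$cell_id), "unassigned", .data$cell_id)) |>
    count(.data$cell_id) |>
    (\(d) setNames(d$n, d$cell_id))()
  expression <- NULL
  if (!is.null(models)) {
    gene_counts <- count_reads_per_gene(aln, models, read_cells,
                                        unique_gene = params$unique_gene)
    expression <- rpg10k(gene_counts, totals)
  }

  end_bins <- detect_end_bins(aln, trimmed, cov, params)
  splice_bins <- detect_splice_bins(aln, cov, params)
  alt <- call_alt_events(aln, splice_bins, read_cells, params)
  groups <- group_reads_into_isoforms(aln, end_bins, splice_bins, alt$events,
                                      read_cells, models, params)
  groups <- consensus_for_groups(groups, aln, trimmed, params)
  iso_counts <- quantify_isoforms(groups, read_cells)

  complex_genes <- NULL; tests <- NULL
  if (!is.null(models)) {
    feat_genes <- assign_features_to_genes(end_bins, models, params)
    ev_genes <- events_to_genes(alt$events, splice_bins, models, params)
    complex_genes <- find_complex_isoform_genes(feat_genes, ev_genes)
    cg <- complex_genes$gene_id[complex_genes$complex]
    tests <- test_differential_usage(iso_counts, genes = cg,
                                     alpha = params$alpha,
                                     correct = params$yates_correction)
  }
  if (!is.null(genome) && nrow(end_bins) > 0) {
    polya <- find_polya_signal(end_bins, genome, params)
  } else polya <- NULL
  if (!is.null(cage) && nrow(end_bins) > 0) {
    end_bins <- validate_cage_overlap(end_bins, cage, params)
  }

  summary <- list(
    n_reads = nrow(reads),
    n_demultiplexed = sum(!is.na(trimmed$cell_id)),
    n_complete = sum(trimmed$complete),
    n_alignments_in = nrow(psl),
    n_alignments_kept = nrow(aln),
    n_tss = sum(end_bins$type == "TSS"),
    n_tes = sum(end_bins$type == "TES"),
    n_ss5 = sum(splice_bins$type == "SS5"),
    n_ss3 = sum(splice_bins$type == "SS3"),
    n_junction_combinations = nrow(alt$combinations),
    n_events = as.list(table(alt$events$type)),
    n_isoform_groups = nrow(groups),
    n_complex_genes = if (is.null(complex_genes)) NA_integer_
      else sum(complex_genes$complex),
    n_significant = if (is.null(tests)) NA_integer_ else sum(tests$significant),
    params = unclass(params)
  )
  run <- structure(list(
    trimmed = trimmed, alignments = aln, expression = expression,
    end_bins = end_bins, splice_bins = splice_bins,
    combinations = alt$combinations, events = alt$events,
    groups = groups, iso_counts = iso_counts, polya = polya,
    complex_genes = complex_genes, tests = tests, summary = summary
  ), class = "longform_run")
  if (!is.null(outdir)) write_run_outputs(run, outdir)
  run
}

resolve_models <- function(annotation) {
  if (is.null(annotation)) return(NULL)
  if (inherits(annotation, "toy_annotation")) return(gene_models(annotation))
  if (is.character(annotation)) return(read_gene_models(annotation))
  annotation
}

#' @export
print.longform_run <- function(x, ...) {
  s <- x$summary
  cat("<longform_run>\n")
  cat(sprintf("  reads: %d (%d complete), alignments kept: %d\n",
              s$n_reads, s$n_complete, s$n_alignments_kept))
  cat(sprintf("  TSS %d / TES %d / SS5 %d / SS3 %d bins\n",
              s$n_tss, s$n_tes, s$n_ss5, s$n_ss3))
  cat(sprintf("  %d junction combination(s), %d isoform group(s)\n",
              s$n_junction_combinations, s$n_isoform_groups))
  if (!is.na(s$n_complex_genes)) {
    cat(sprintf("  %d complex gene(s), %d significant for differential usage\n",
                s$n_complex_genes, s$n_significant))
  }
  invisible(x)
}

write_run_outputs <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wtsv <- function(x, f) utils::write.table(
    x, file.path(outdir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wtsv(run$trimmed |> select(-"sequence"), "trimmed_reads.tsv")
  write_psl(run$alignments, file.path(outdir, "filtered.psl"))
  if (!is.null(run$expression)) wtsv(run$expression, "expression.tsv")
  write_feature_bed(bind_rows(
    run$end_bins |> select(any_of(c("chrom", "start", "end", "type",
                                    "support", "direction"))),
    run$splice_bins |> select(any_of(c("chrom", "start", "end", "type",
                                       "support", "direction")))),
    file.path(outdir, "features.bed"))
  if (nrow(run$combinations) > 0) {
    wtsv(run$combinations |> select(-"read_ids", -"cells"), "combinations.tsv")
  }
  if (nrow(run$events) > 0) {
    wtsv(run$events |> select(!where(is.list)), "events.tsv")
  }
  if (nrow(run$groups) > 0) {
    wtsv(run$groups |> select(-"read_ids", -"consensus"), "isoform_groups.tsv")
    write_consensus_fasta(run$groups, file.path(outdir, "consensus.fasta"))
    wtsv(run$iso_counts, "isoform_counts.tsv")
  }
  if (!is.null(run$tests)) wtsv(as_tibble(run$tests), "differential_usage.tsv")
  jsonlite::write_json(run$summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' Export feature bins as BED6
#'
#' @param bins feature bins (end and/or splice); name is `type:support`,
#'   strand the bin direction.
#' @param path output BED file.
#' @export
write_feature_bed <- function(bins, path) {
  if (nrow(bins) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  lines <- with(bins, paste(chrom, start, end,
                            paste0(type, ":", support), support,
                            direction, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
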