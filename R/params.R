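#' Pipeline parameters
#'
#' Every numeric threshold of the analysis pipeline in one auditable record.
#' Defaults reproduce the published method: 20-bp feature bins supported by at
#' least two complete-read alignment ends whose clip-length distribution has a
#' median in 6--15 bases and a 75th percentile of at most 20; end bins kept
#' when their support is at least 2% of the reads in the next 50 read-covered
#' bases and separated by at least 60 read-covered bases (plain 60 bp genomic
#' in SIRV mode); introns are alignment gaps larger than 50 bp; splice bins
#' require a >0.9 aligned/read ratio, the 2%/40-covered-bases support filter
#' and 30 bp separation; junction combinations come from reads with a
#' ratio above 0.85 and need at least two supporting reads; intron retention needs a
#' single read covering at least 70% of the intron; isoform groups keep reads
#' ending within 60 bp of a TSS and a TES and must hold at least 1% of the
#' locus reads; TSS/TES are told apart by a median Levenshtein distance of at
#' most 2 between end clips and the TSO (`ATGG`) or oligodT (`TTTT`) motifs;
#' CAGE overlap within 10 bp; polyA motifs `AATAAA`/`ATTAAA`; alpha 0.001.
#'
#' @param ... named overrides of any default listed above (see
#'   [pipeline_params()] defaults via `pipeline_params()`).
#' @return an object of class `pipeline_params` (a named list).
#' @export
pipeline_params <- function(...) {
  p <- list(
    # alignment filtering
    min_aligned_ratio  = 0.6,
    tie_fraction       = 0.02,
    score_mode         = "psl",   # "psl" (matches-mismatches-gaps) or "matches"
    # TSS/TES detection
    min_end_support    = 2L,
    clip_median_range  = c(6, 15),
    clip_p75_max       = 20,
    bin_width          = 20L,
    end_filter_fraction = 0.02,
    end_filter_window  = 50L,     # read-covered bases
    end_separation     = 60L,     # read-covered bases (genomic bp in SIRV mode)
    sirv_mode          = FALSE,
    tss_motif          = "ATGG",
    tes_motif          = "TTTT",
    end_clip_k         = 4L,      # clip bases adjacent to the alignment end
    clip_distance_max  = 2,
    # splice sites
    min_intron         = 51L,     # gap larger than 50 bp
    splice_read_ratio  = 0.9,
    min_splice_support = 2L,
    splice_filter_fraction = 0.02,
    splice_filter_window = 40L,   # read-covered bases
    splice_separation  = 30L,     # genomic bp
    # alternative splicing
    combo_read_ratio   = 0.85,
    combo_min_reads    = 2L,
    retention_coverage = 0.70,
    # isoform grouping
    isoform_min_fraction = 0.01,
    isoform_end_tolerance = 60L,
    poa_match          = 2L,
    poa_mismatch       = -2L,
    poa_gap            = -4L,
    poa_max_reads      = 12L,
    # validation
    cage_max_distance  = 10L,
    polya_motifs       = c("AATAAA", "ATTAAA"),
    polya_window       = 50L,
    # differential usage
    alpha              = 0.001,
    yates_correction   = TRUE,
    # preprocessing
    index_min_score    = 20L,     # Smith-Waterman +1/-1/-1 local score
    sw_match           = 1L,
    sw_mismatch        = -1L,
    sw_gap             = -1L,
    adaptor_window     = 100L,
    max_adaptor_distance = NULL,  # default ceiling(0.25 * adaptor length)
    # gene counting
    unique_gene        = FALSE,
    gene_slop          = 60L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown)) {
    abort(paste0("unknown pipeline parameter(s): ", paste(unknown, collapse = ", ")))
  }
  p[names(dots)] <- dots
  fracs <- c("min_aligned_ratio", "tie_fraction", "end_filter_fraction",
             "splice_filter_fraction", "combo_read_ratio", "retention_coverage",
             "isoform_min_fraction", "splice_read_ratio", "alpha")
  for (f in fracs) {
    if (!is.numeric(p[[f]]) || p[[f]] <= 0 || p[[f]] > 1) {
      abort(sprintf("parameter `%s` must be a fraction in (0, 1]", f))
    }
  }
  counts <- c("min_end_support", "bin_width", "end_filter_window",
              "end_separation", "min_intron", "splice_filter_window",
              "splice_separation", "combo_min_reads", "isoform_end_tolerance",
              "cage_max_distance", "index_min_score", "adaptor_window",
              "min_splice_support", "poa_max_reads")
  for (f in counts) {
    if (!is.numeric(p[[f]]) || p[[f]] < 1) {
      abort(sprintf("parameter `%s` must be a positive count", f))
    }
  }
  structure(p, class = "pipeline_params")
}

#' @export
print.pipeline_params <- function(x, ...) {
  cat("<pipeline_params>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-24s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}

default_adaptor_distance <- function(adaptor, max_dist = NULL) {
  if (!is.null(max_dist)) return(max_dist)
  as.integer(ceiling(0.25 * nchar(adaptor)))
}
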