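#' @keywords internal
"_PACKAGE"

#' @useDynLib longform, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import dplyr
#' @importFrom tibble tibble as_tibble
#' @importFrom rlang .data abort warn
#' @importFrom purrr map map2 map_int map_chr map_dbl pmap
#' @importFrom stats median quantile setNames pchisq cor rmultinom rgeom runif
#' @importFrom utils head tail
NULL

BASES <- c("A", "C", "G", "T")

#' Reverse complement of nucleotide strings
#'
#' @param x character vector of sequences over A/C/G/T/N.
#' @return character vector of reverse complements.
#' @export
seq_revcomp <- function(x) {
  out <- chartr("ACGTacgt", "TGCAtgca", x)
  vapply(strsplit(out, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

# random DNA string(s); uses the current RNG stream
rand_dna <- function(len, n = 1L) {
  vapply(rep(len, length.out = n), function(l) {
    paste(sample(BASES, l, replace = TRUE), collapse = "")
  }, character(1))
}

# 0-based half-open interval overlap width
interval_overlap <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stopifnot_scalar_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || is.na(x) || x < min || x != as.integer(x)) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min))
  }
}
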