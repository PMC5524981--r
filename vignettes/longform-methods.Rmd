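---
title: "Isoform detection from full-length cDNA long reads: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isoform detection from full-length cDNA long reads: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longform)
library(dplyr)
```

## The problem

Nanopore cDNA sequencing reads entire transcripts end to end, so a single
read can report a transcript's start site, its end site, and every splice
junction in between — information that short reads only recover by assembly.
`longform` turns basecalled full-length cDNA reads plus their spliced genome
alignments (PSL, as produced by BLAT) into:

1. per-cell gene expression (RPG10K),
2. transcription start/end sites (TSS/TES) and splice sites as 20-bp bins,
3. alternative splicing calls (alternative donors/acceptors, intron
   retention, exon skipping),
4. isoform groups with partial-order-alignment (POA) consensus sequences, and
5. chi-square tests of differential isoform usage across single cells.

The library chemistry drives the design throughout. Smartseq2 cDNA carries an
ISPCR handle on both ends; when both handles are found, the read is
"complete" — it covers the transcript from cap to polyA, and its alignment
ends mark the true TSS and TES. The template-switching oligo (TSO) leaves an
`ATGG`-containing residue at the 5' end and the oligodT primer leaves a
`TTTT`/polyA residue at the 3' end; after trimming, those residues survive as
short soft-clipped tails on the alignment and are what lets the pipeline tell
a TSS bin from a TES bin.

## Stage by stage

### Demultiplexing

Cells are marked by 60-nt index sequences. Each index (and its reverse
complement) is aligned locally — Smith–Waterman, +1 match / −1 mismatch /
−1 gap — against both terminal windows of the read; an assignment requires
exactly one index reaching score 20, mirroring an aligner run at
`-minScore=20`. Two details matter:

* **Seeding.** The scan only scores an index against a window when they
  share an exact 11-mer. A tiled aligner never reports an alignment without
  a seed hit, and without this gate a +1/−1/−1 local alignment reaches score
  20 by chance in roughly 4% of unrelated index–window pairs, which would
  spuriously mark many reads "ambiguous".
* **Ambiguity.** Reads reaching the score threshold for two or more indexes
  are dropped rather than best-assigned, to avoid cross-cell contamination.

### Adaptor trimming and completeness

The ISPCR sequence is located at the 5' end and the oligodT-side pattern at
the 3' end by semi-global edit distance within a terminal window of 100
bases, on both read orientations; the orientation that explains more
adaptors wins. A read is *complete* when both adaptors are found within
`max_adaptor_distance` edits (default: a quarter of the adaptor length,
rounded up — the source method does not state its cutoff, so it is an
explicit parameter). Trimmed reads are orientation-normalized to the cDNA
sense, so downstream the alignment strand equals the transcript strand.

### One alignment per read

PSL alignments are filtered in three steps: the highest-scoring alignment
per read is found with scores within 2% treated as ties; ties resolve to the
alignment with the most gap openings (a spliced alignment beats an unspliced
pseudogene hit); and the winner is discarded if its aligned/read-length
ratio is at or below 0.6. Score is the standard PSL score
(matches − mismatches − gap openings); a pure match count is available via
`score_mode = "matches"`. Remaining ties break deterministically by smaller
target coordinate, then target name.

### Gene expression

A read counts for every gene whose merged exons overlap at least one of its
alignment blocks by at least one base (strand ignored — raw reads are
unstranded). Values are normalized as

$$\mathrm{RPG10K} = \frac{\text{reads on the gene's exons}}
{\text{reads aligned in the sample}} \times 10^4 ,$$

and a gene is *expressed* when RPG10K > 0. Full-length reads make counts
independent of transcript length, so no length normalization is applied
anywhere. Whether a multi-gene read should count once or for every
overlapping gene is not specified by the method; both behaviours are
implemented (`unique_gene`).

### TSS/TES bins

Candidate end positions are genomic positions where at least two
complete-read alignments end and where the clipped (unaligned) bases at that
end have median length 6–15 and 75th percentile ≤ 20 — the footprint of
untrimmed primer residue. A 20-bp window is then placed to contain the
maximum number of alignment ends (exhaustive scan over the 20 possible
offsets; overlapping windows collapse onto the best one). Two filters
follow:

* support must be ≥ 2% of the reads overlapping the next 50 *read-covered*
  bases — counting only covered bases means uncovered introns do not dilate
  the window;
* retained bins must be ≥ 60 read-covered bases apart (plain 60 bp genomic
  in `sirv_mode`, for compact artificial loci), conflicts resolved greedily
  by descending support with a coordinate tie-break.

The method does not orient the "next 50 covered bases" window; here it walks
into the transcript body, i.e. away from the side the member alignment ends
face (left-end bins walk right, right-end bins walk left).

Bins are typed by the median Levenshtein distance between the clip bases
adjacent to the member alignment ends and the TSO motif `ATGG` (≤ 2 → TSS)
or the oligodT motif `TTTT` (≤ 2 → TES). Because reads come off either
strand and the clip orientation is lost after alignment, each clip is
compared in both orientations and the smaller distance used; bins passing
both motifs, or with no clip sequence at all, stay unclassified — ambiguous
evidence must not create features.

### Splice-site bins

Only reads with aligned/read ratio > 0.9 contribute. Alignment gaps larger
than 50 bp are read as introns; the gap-open and gap-close positions are
donor (SS5) or acceptor (SS3) according to the read's direction. Positions
supported by ≥ 2 reads are binned (20 bp, same placement rule), kept when
support is ≥ 2% of the reads in the adjacent 40 read-covered exonic bases,
and thinned to ≥ 30 bp separation. Bin direction is the majority read
direction.

### Alternative splicing

Junctions are counted in reads with ratio > 0.85; a donor–acceptor
combination needs ≥ 2 reads. One donor with two acceptors scores an
alternative-3' event, one acceptor with two donors an alternative-5' event.
Intron retention is called when a *single* read covers ≥ 70% of a retained
combination's intron — union coverage across reads does not count — and, as
an extra guard not in the original description, that read must also overlap
both flanking exons, so a truncated fragment lying inside an intron cannot
call retention. Exon skipping (the source method never defines its
procedure; ours is a labelled heuristic behind the `skipping` flag) is
called when a retained combination's intron fully spans an internal exon —
a span between one junction's acceptor and the next junction's donor used
together in ≥ 2 reads.

### Isoform groups and consensus

Reads whose 5' and 3' alignment ends fall within 60 bp of a TSS bin anchor
and a TES bin anchor are partitioned by (nearest TSS, nearest TES,
alternative-splice signature). The signature records, per alternative
donor/acceptor event at the locus, which member site the read uses, and per
retained intron, whether the read splices it or reads through it. Groups
holding at least 1% of the locus reads are retained (boundary inclusive: 1
read of 100 stays). The locus is the annotated gene span when a GTF is
given, otherwise the maximal interval of overlapping alignments
(annotation-independent mode, as used for spike-in benchmarking). Whether
the 1% denominator should count all locus reads or only end-assignable ones
is ambiguous in the source; all locus reads are used here.

Each group's consensus comes from a partial-order alignment graph: reads are
added progressively (longest first), matching bases fuse into shared nodes,
mismatches and insertions branch, and each edge carries the number of reads
traversing it. The consensus is the heaviest source-to-sink path, found by
dynamic programming over the DAG with deterministic tie-breaks
(lexicographically smaller base, then older node). Three implementation
choices are worth stating:

* **Scoring is +2 match / −2 mismatch / −4 gap.** With gap cost equal to
  mismatch cost, a "slipped" alignment around a short tandem repeat can be
  *strictly optimal* for an individual read, after which the heaviest path
  can traverse two alternatives of the same column and emit a spurious
  extra base. A gap at twice the mismatch cost — the usual ratio in POA
  tools — makes column-wise alignment strictly preferred, and the consensus
  of a gap-free alignment then provably equals the per-column majority
  (this is asserted against a majority oracle in the test suite).
* **POA input is the aligned span** of each read (`qstart`–`qend`), not the
  full trimmed sequence, so primer residues and leftover polyA do not dilute
  consensus identity.
* **At most 12 reads feed each consensus** (longest aligned spans first,
  ties by read id). Consensus accuracy saturates well below that depth at
  the error rates studied here, and the cap bounds the quadratic alignment
  cost on deeply covered isoforms.

Consensus sequences are compared to reference transcripts by free-end-gap
(overlap) alignment of both strands; identity is matches over alignment
columns.

### Differential isoform usage

A gene expresses *complex isoforms* when it has alternative ends (≥ 2 TSS
bins or ≥ 2 TES bins) *and* at least one alternative-splicing event. For
each such gene the cells × isoform-groups count table is tested with a
Pearson chi-square contingency test (expected counts from the marginals;
Yates continuity correction on 2×2 tables, matching the reference
implementation's default; the test runs regardless of low expected counts
but warns when any expected count is below 5). P values are corrected across
genes by the Holm–Šídák step-down:

$$\tilde p_{(i)} = 1 - (1 - p_{(i)})^{\,m - i + 1},$$

enforced monotone and declared significant while $\tilde p \le \alpha$
(default $\alpha = 0.001$). `stats::p.adjust` offers Holm–Bonferroni but not
the Šídák variant, so the adjustment is implemented directly; a closed-form
oracle checks it in the tests.

## The simulator

All validation rests on `generate_toy_locus()` / `simulate_reads()`: gene
loci in the style of synthetic spike-in controls — each gene on its own
contig, alternating strands, a canonical 5-exon transcript plus isoforms
cycling through alternative TSS (+120 bp per round), alternative donor
(+60 bp), alternative TES (−120 bp), intron retention, exon skipping and
alternative acceptor. The offsets are chosen so every programmed feature is
resolvable by the method's own bins and separations (TSS/TES ≥ 120 bp apart
against the 60-base separation rule; splice-site shifts of 60 bp against the
30-bp rule); an `AATAAA` signal is planted ~25 bp upstream of each TES.

Reads mirror the library structure: `[60-nt index] + ISPCR + ACATGG residue
+ insert + polyA(30) + revcomp(ISPCR·AC)`, half emitted as reverse
complements. Errors (substitutions, insertions, deletions — free parameters,
since the platform's error composition is not asserted) apply to the
transcript-derived insert only; 5'-truncation removes a geometric-length
prefix (mean 150 nt) while both adaptors remain attached, which is exactly
the template-switch artifact the clip and 2%-support filters exist to
reject. The 3' trim pattern includes 20 of the 30 polyA bases, so trimming
leaves a 10-base polyA clip and the 6-base TSO residue leaves a 5' clip —
reproducing the published clipped-base profile (median 6–15, p75 ≤ 20) by
construction.

Ground truth is emitted as PSL against the genome (blocks split at every
simulated indel, so the file is what an idealized spliced aligner would
report) and against the transcriptome (for transcript-direct
quantification). Every read has exactly one truth record; a fixed seed
reproduces reads, truth and PSL byte for byte.

**What the simulator does not model** — and therefore what green tests do
not establish about real data: basecalling error structure (homopolymer
compression, strand-specific biases), chimeric reads, PCR duplicates/UMIs,
internal oligodT mispriming, genes sharing a chromosome with ambient
intergenic coverage, and alignment error by a real aligner (truth PSL is
exact). Results on real libraries depend on the aligner's behaviour in ways
desk-scale simulation cannot certify.

## Problem sizes and numerical choices

The validation suite runs two study conditions, chosen to finish in minutes
on one core while leaving every filter a meaningful denominator:

* **zero-noise**: 2 genes × 3 isoforms × 7 cells × 500 reads/cell (3,500
  reads) — the pipeline must be *exact* here: every true site in exactly one
  bin of the right type, no false bins, per-cell isoform counts equal to
  truth;
* **noisy**: the same layout at 3% substitutions + 1% indels + 10%
  5'-truncation, 2,000 reads/cell (14,000 reads) — ≥ 90% site recall, no
  bin farther than 60 bp from a true site, consensus identity ≥ 99%.

Statistical calibration uses 1,000 replicate families of 10 null
multinomial tables (7 cells × 3 isoforms, 100 reads/cell); the observed
family-wise error is compared to $\alpha$ plus three Monte-Carlo standard
errors. Primitive-level checks run the Levenshtein distance against a
pure-R dynamic program (1,000 random pairs), the POA consensus against
per-column majority on gap-free 5×100 alignments, and the alignment filter
against brute-force enumeration of its three rules (1,000 random sets) —
all exact.

Other numerical conventions: all coordinates are 0-based half-open
(PSL-native); feature "anchors" are the original candidate positions inside
their bins and all distances are measured anchor-to-anchor; covered-base
distances come from a cumulative-sum mask so walks skip uncovered introns in
O(log n); every greedy conflict resolution orders by descending support with
coordinate tie-breaks, making all analysis stages fully deterministic — the
simulator is the only seeded component.

## Limitations

* Bins are 20 bp; the pipeline does not resolve base-accurate sites.
* The exon-skipping rule is a stated stand-in, not a published procedure.
* Chi-square p values on sparse single-cell tables are approximate; the
  package warns but does not switch to an exact test.
* Genomic realignment of consensus sequences is out of scope; a group's
  structure is reported from its bins and junctions directly.
* Highly repetitive loci needing special aligner treatment (e.g. antibody
  heavy-chain genes) are not special-cased.

## A worked run

```{r example, eval = FALSE}
ds <- sim_dataset(2, 3, n_cells = 7, reads_per_cell = 500, seed = 11)
psl <- tempfile(fileext = ".psl")
write_truth_alignments(ds$truth, ds$annotation, psl)

run <- run_longform(ds$reads, psl, annotation = ds$annotation,
                    genome = ds$annotation$genome, indexes = ds$indexes)
run
glance(run$tests)
autoplot(run$tests)
plot_isoform_usage(run$iso_counts)
```
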