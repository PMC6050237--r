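---
title: "Profiling EV small RNA cargo with a tiered annotation cascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling EV small RNA cargo with a tiered annotation cascade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evcargo)
library(dplyr)
```

## The problem

Extracellular vesicles (EVs) carry a short-RNA cargo that differs sharply
from the cells that secrete them. When libraries are size-selected to the
17–35 nt range, parental cells are dominated by miRNAs, whereas EV
libraries are rich in *fragments* of longer RNAs: rRNA, tRNA, Y RNA and
coding transcripts. Attributing a 17–35 nt read to the right RNA class is
therefore the central, and surprisingly delicate, step: loci of different
biotypes overlap, fragments of abundant RNAs can masquerade as small-RNA
species (a classic case is piRNA annotations overlapping tRNA or Y RNA
genes), and the answer depends on the *order* in which annotation sources
are consulted.

`evcargo` makes that ordering explicit as a three-tier priority cascade
and provides everything around it: input parsing, quantification,
composition statistics, a matched proteome analysis and a synthetic-data
generator that produces fully labelled inputs for testing.

## The cascade model and its assumptions

Reads are assigned by visiting three tiers in fixed priority order —
`small_rna` (miRNA, piRNA, snRNA, snoRNA), `rrna` (rRNA_LSU, rRNA_SSU,
Mt_rRNA), `other_rna` (tRNA, Mt_tRNA, protein_coding, lncRNA, misc_RNA,
processed_transcript, pseudogene, scRNA). At the first tier where at
least one feature overlaps the read on its strand (any overlap ≥ 1 base
by default, configurable via `min_overlap`):

* one distinct gene id → **assigned** to that gene;
* two or more distinct gene ids → **ambiguous** at that tier.

Only reads with *no* feature at a tier continue to the next; an ambiguous
read has found features and therefore stops. This is the single most
consequential reading of the stepwise procedure, and we adopt it
deliberately: letting ambiguous reads fall through would silently convert
within-tier annotation conflicts into lower-tier assignments. Within a
tier, the multi-feature rule follows HTSeq's union-mode semantics, with
uniqueness judged per gene id — a locus annotated under two biotypes with
the same gene id is still one gene, not an ambiguity.

Assumptions inherited from the study design: alignments are single-end
with one reported alignment per read (best-stratum reporting), so each
read is counted once and multimapper weighting is out of scope; strand
matching is exact (stranded protocol), and antisense assignment is not
offered; alignments have no indels, so reference span and read length
coincide (on degenerate inputs the package measures overlap by reference
span and size histograms by sequence length).

## Annotation database construction

`read_gtf()` and `read_bed()` load features from the two standard formats
into one internal convention (0-based half-open; GTF is converted on
read, BED taken as-is) — a single convention eliminates whole classes of
off-by-one errors. The species-specific source lists of the original
analyses (miRBase, piRNA databases, Ensembl, RepeatMasker, UCSC tRNAs)
are replaced by a generic multi-source loader with per-source biotype
tagging; inputs are assumed to be in one coordinate system, and
coordinate lifting is out of scope.

Redundant rRNA sources are merged with `reciprocal_overlap_filter()`:
a candidate entry is dropped iff some reference entry on the same
chromosome and strand overlaps it by at least `min_fraction` (default
0.5) of *both* lengths. The reciprocity matters: a short RepeatMasker
fragment inside a long Ensembl gene removes neither.

`build_tiered_annotation()` validates biotypes against the tier config,
deduplicates identical `(chrom, start, end, strand, gene_id)` entries —
keeping identical intervals that belong to *different* genes, which is
precisely what later produces honest ambiguity calls — and builds
per-tier stranded interval indexes (GenomicRanges). The database
round-trips losslessly through a TSV dump plus a sidecar config
(`write_annotation_db()` / `read_annotation_db()`). The rRNA LSU/SSU
split is a biotype tag supplied at load time; biotypes outside the
configured vocabulary are an error, never silently binned.

## Preprocessing

`trim_adapters()` is a self-contained 3′ adapter trimmer so the pipeline
has no external binary dependency: the best adapter occurrence (fewest
mismatches per aligned base, ties leftmost) with ≥ `min_overlap` = 3
aligned bases and error rate ≤ `max_error_rate` = 0.1 is removed together
with everything 3′ of it. The defaults mirror the documented defaults of
the standard trimming tool; both are exposed as arguments, and users with
pre-trimmed FASTQ can skip the stage entirely. `filter_read_lengths()`
then keeps reads of 17–35 nt (inclusive on both ends), counting drops as
too-short / too-long / no-adapter — only reads in which an adapter was
found are eligible, mirroring the rule that untrimmed reads are
uninterpretable in a short-insert protocol. Base-quality information is
carried through but never used as a filter.

## Quantification choices

* **Isoacceptor pooling** (`pool_trna_isoacceptors()`): tRNA counts from
  different genomic loci of one isoacceptor (amino acid + anticodon) are
  summed under `tRNA-<AA>-<anticodon>`; ids not matching the pattern are
  left unpooled with a warning rather than guessed.
* **Threshold normalisation** (`threshold_normalize()`): miRNA/piRNA
  genes with ≥ 3 reads are divided by the *total* reads of that biotype
  in the sample, sub-threshold reads included in the denominator. Output
  fractions therefore sum to ≤ 1, with equality exactly when nothing
  fell below threshold — a property the tests assert.
* **Denominators**: all "fraction of annotated reads" statistics default
  to assigned reads only; `denominator = "include_ambiguous"` adds
  ambiguous reads to their tier. Both modes exist because the choice is
  genuinely underdetermined; results report which mode was used.
* **Cross-biotype ambiguity** (`cross_biotype_ambiguity()`): for reads
  assigned to an early-tier biotype (e.g. piRNA), all tiers are
  re-queried ignoring priority to ask whether a later-tier biotype (e.g.
  tRNA) also overlaps. The statistic is per-read (cross-ambiguous reads
  over all annotated reads) and is labelled as such; a per-locus variant
  would be a different quantity.

## Composition statistics

Length histograms are per-read over the fixed 17–35 support. The 5′-base
profile is computed in biological read orientation (minus-strand
alignments are reverse-complemented first, so position 1 is the true 5′
end); T is displayed as U only at the plotting layer — the internal
alphabet stays DNA. The mature-piRNA criterion is the joint event
(length in 27–35 nt) ∧ (5′ base U), reported with both marginals.
Undefined statistics — zero denominators, zero variance — surface as `NA`
with a warning, never as silent zeros, which keeps the fraction-sum
invariants meaningful.

Ranking statistics (`top_n_cumulative()`, `proteins_covering()`) sort in
decreasing abundance with lexicographic key tie-break, making curves and
"minimal n covering 75 %" answers deterministic. Clustering
(`hierarchical_cluster()`) uses d = 1 − Pearson (range 0–2) after
removing genes with zero counts throughout, and average linkage — the
default of the heatmap tool the workflow emulates — exposed as a
parameter; leaf order is deterministic because `stats::hclust` resolves
ties by input order. Profile correlation defaults to a union join with
absent genes scored zero (mirroring scatter plots that include
EV-enriched genes); an intersection mode is available.

## Proteome analysis

Protein records are unique identifiers with MS-Area abundances (isoforms
are distinct records); a protein's share is its area over the sample
total. The overrepresentation test against a reference list (all
identifications of the sample) is the one-sided hypergeometric tail with
BH adjustment — an explicit, reproducible approximation of the
release-dependent statistic of the web tool used in this field, with a
binomial tail offered as the alternative (`test = "binomial"`).
Expression-aware enrichment is represented by a rank-based analogue
(`abundance_rank_enrichment()`, Mann–Whitney on abundance ranks),
documented as an analogue, not a replication. GO term sets are plain
input files/lists; no ontology-graph traversal or live queries, so child
terms for `child_term_curation()` are supplied as lists, and membership
is explicitly non-exclusive (one protein may appear under several child
terms, so term shares may sum beyond 1).

## The synthetic-data generator

`generate_annotation()` places non-overlapping loci per biotype on a toy
genome (deterministic given the seed), with two deliberate structures:
a requested fraction of piRNA loci nested inside tRNA loci on the same
strand (to exercise cascade-masked ambiguity) and a duplicated rRNA
source (to exercise the reciprocal-overlap merge). `generate_reads()`
draws each read hierarchically — tier, biotype, locus, length, position,
5′ base — and emits it already aligned: the SAM file is the ground truth
of placement, with a parallel FASTQ carrying the 3′ adapter and a random
tail truncated at 51 cycles for testing the preprocessing stage.
`generate_protein_table()` draws log-normal abundances (heavy-tailed, so
few proteins carry most of the mass) with independent Bernoulli set
memberships.

Two presets encode the study conditions as defaults: `preset_cell_like()`
(tier mixture 0.80 / 0.08 / 0.12, miRNA-dominated small-RNA tier) and
`preset_ev_like()` (0.22 / 0.60 / 0.18, piRNA-rich small-RNA tier,
tRNA/Y-RNA-rich other-RNA tier, mitochondrial rRNA practically absent).
Length models: miRNA reads concentrate 97 % of their mass in 20–25 nt;
piRNA-locus reads carry half their mass in the mature 27–35 nt range
with a 5′-U probability of 0.8; tRNA fragments are mostly 30–34 nt;
unlisted biotypes draw uniformly on 17–35 nt. Where the 5′ base is not
forced to U it is uniform over A/C/G, so the realised 5′-U rate equals
the stated probability exactly in expectation.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: sequencing error and quality structure,
genome sequence (overlap logic is purely coordinate-based), non-uniform
read starts within a locus (real fragments have precise cleavage
patterns), correlated expression between cell and EV samples, and
multimapping. Conclusions about those phenomena need real libraries.

## Numerical choices and degenerate inputs

Probability vectors must sum to 1 within 1e-9; fraction-sum invariants
are asserted at the same tolerance. All randomness flows through
explicit seeds (`withr::with_seed`), so every generator output and every
pipeline TSV is byte-reproducible. Ties are always broken
deterministically (lexicographic keys; input order in clustering).
Degenerate inputs have defined behaviour: empty annotation or read sets
give empty results, zero denominators give `NA` markers, all-zero
abundance vectors and zero-variance samples are errors naming the
offender.

## Problem sizes used in the test suite

The suite checks the cascade against a brute-force all-feature scan on
100 random annotations (500–5,000 features) of 10,000 reads each;
mixture recovery at 50,000 reads per library over 5 seeds and both
presets; the reciprocal filter against a pairwise oracle on 1,000 random
interval pairs; the hypergeometric test against closed forms and a
1,000-replicate permutation oracle; and full-pipeline byte-identity
across two identically seeded runs. These sizes were chosen to exercise
the algorithms well beyond the toy regime while keeping a full test run
in a few minutes on one CPU.

## Known limitations

* Ambiguous reads never fall through to later tiers; workflows that
  prefer fall-through need a different cascade rule.
* No isoform- or arm-level miRNA resolution beyond what the annotation
  provides; no differential expression or abundance testing.
* The overrepresentation test conditions on detection only; the
  rank-based enrichment analogue is not a replication of any specific
  external tool's statistic.
* Identifier namespaces for proteome comparisons must be harmonised by
  the caller.
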