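---
title: "Methods and design of the pancore pangenome pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the pancore pangenome pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`pancore` implements the computational core of a genus-level comparative
genomics study: ortholog assignment between bacterial genomes, partition of
the resulting gene families into core, accessory and singleton classes,
rarefaction-style development curves of the pan and core genome, power-law
and exponential-decay fits to those curves, and AAI/ANI identity matrices
with genus/species rank calls. This vignette records the model, the
parameters that matter, and the design decisions taken where several
reasonable conventions exist.

## Genome representation and summary statistics

A genome set is a tidy tibble with one row per sequence record — contigs
(nucleotide, A/C/G/T/N) and proteins (20 standard residues plus X) — so the
whole pipeline composes with dplyr verbs. FASTA ids are the first
whitespace-delimited header token; ids must be unique within a genome.

Two conventions deserve explicit statement:

* **Scaffold filter.** `filter_scaffolds()` discards contigs *shorter than*
  the threshold (default 1500 nt), i.e. the boundary length is kept. The
  filter is idempotent, and proteins are only removed with their contig
  when a GFF3-derived gene-to-contig mapping is available; otherwise they
  are kept and the mismatch is logged.
* **GC content.** `gc_percent = 100·(G+C)/(A+C+G+T)`: ambiguous bases (N)
  are excluded from both numerator and denominator, matching assembly-QC
  practice and avoiding GC deflation on N-rich drafts; `n_bases`
  nevertheless counts all bases. Set-level dispersion (`gc_summary()`) is
  the sample standard deviation (n−1 denominator) — the convention that
  reproduces published per-genus GC summaries from their per-genome values
  — and values are kept unrounded until reporting.

## Protein alignment and bit scores

Ortholog detection needs only pairwise scores, so the aligner is an exact
affine-gap Smith–Waterman (Rcpp), not a seeded heuristic: on the small
proteomes this package targets, exactness is affordable and makes the
aligner testable against a brute-force dynamic-programming oracle, which
the test suite does on hundreds of random pairs. Scoring is BLOSUM62 with
gap cost `11 + L` for a gap of length `L` (BLAST's "open 11, extend 1"
convention), and raw scores are converted to bits with the standard gapped
Karlin–Altschul constants (λ = 0.267, K = 0.041):
`bits = (λ·S − ln K)/ln 2`. Percent identity is counted over aligned
columns, gaps included.

`best_hits()` optionally prescreens subject proteins by exact shared
k-mers (k = 4) before running the DP. A best hit strong enough to pass the
60-bit retention floor shares short exact words with its query in all
realistic settings, and a dedicated test asserts that prescreen on/off
yields identical results; `prescreen = FALSE` restores the pure
all-against-all scan. Score ties are broken toward the lexicographically
smallest subject id and flagged.

## BBH orthology and family construction

A gene pair is orthologous (BBH) when each member is the other's best hit
at ≥ 60 bits — the threshold is inclusive and exposed as `min_bitscore`.
`build_ortholog_table()` then builds families in three deterministic steps:

1. families are seeded by the reference genome's genes, each joined by its
   BBH partner in every other genome;
2. genes without a reference partner are clustered among themselves by
   single-linkage over the remaining BBH graph;
3. anything left becomes a singleton family.

The matrix is kept binary — one gene per genome per family. When a mop-up
cluster contains two genes of one genome, the gene with the higher summed
BBH bit score stays and the other starts its own family (logged). Family
ids are reference gene ids where anchored, otherwise `FAM<k>` in a
deterministic (genome, gene) sort order, so family composition is invariant
to genome input order up to labels. After every build the partition
property is validated: each gene of each genome occurs in exactly one
family.

This reference-anchored construction mirrors how multi-genome core-gene
analyses designate a complete genome as reference; a score-ratio cutoff
instead of a fixed bit score would be a plausible alternative and is
deliberately not guessed at — the fixed threshold is exposed as a flag.

## Development curves and fits

`pan_development()` samples genome subsets for every subset size
N = 1..G. Whenever `choose(G, N)` does not exceed `max_samples_per_n`
(default 500) all subsets are enumerated, which guarantees exact agreement
with a brute-force oracle; otherwise distinct subsets are drawn uniformly
(seeded rejection sampling). Medians of an even number of samples are the
mean of the two central values; quartiles are `quantile()` type 7.

Fits are nonlinear least squares on the original scale (Levenberg–
Marquardt via minpack.lm), not log-log regression — fitting the power law
itself to the medians:

* **Heaps' law** `n = k·N^γ`, initialized from a log-log OLS fit;
  α = 1 − γ by definition, and `classify_openness()` calls α < 1 "open",
  assigning the boundary α = 1 to "closed" since only α < 1 is defined as
  open.
* **Exponential decay** `n = k·e^(−N/τ) + tgθ`, initialized with
  tgθ₀ = min median, k₀ = range, τ₀ = G/3, with τ constrained positive and
  tgθ non-negative.

Flat input (all medians equal) makes both problems unidentifiable in their
nonlinear parameterization, so the closed-form least-squares solutions are
returned directly (γ = 0, k = the common value; k = 0, tgθ = the common
value). On noiseless data generated from known constants both fitters
recover the parameters to 1e−6 relative, which the test suite asserts over
a γ grid and for known decay constants.

## Identity matrices and rank calls

**AAI** is the mean percent identity over BBH pairs, symmetrized across
the two alignment directions (identical under exact SW; asserted). The
mean is unweighted by default — alignment-length weighting is available as
a flag — because published AAI matrices rarely state their weighting.

**ANI** follows the classic fragment recipe: query contigs cut into
consecutive 1020-nt windows (trailing partial windows dropped), each
fragment placed at its best-supported position in the subject by exact
13-mer diagonal voting and aligned there with an affine-gap local DP
(match +1, mismatch −1, gap `5 + 2L`); fragments with ≥ 30 % identity over
≥ 70 % of their length are retained and averaged, and the reported ANI is
the mean of the two directions. Genomes with no retained fragments give NA
(propagated into the matrix and excluded, with a message, from heatmap
ordering). Matrix ordering is average-linkage hierarchical clustering on
`100 − identity`; an all-equal matrix preserves input order.

`classify_pair()` applies the conventional thresholds with species taking
precedence over genus: ANI > 95 % (the conservative lower end of the
">95–96 %" convention, configurable) calls the same species; otherwise AAI
within 65–95 % — supported, when supplied, by 16S identity within
95–98.6 % — calls the same genus. The intervals are read literally: a pair
above the genus AAI interval but at or below the species ANI bound is
reported `different_genus`, and raising ANI can never demote a call
(monotonicity is property-tested).

## The synthetic genome-set generator

`simulate_genome_set()` emulates the statistical structure a genus-level
pangenome study assumes: a core pool present in every genome, accessory
families assigned to uniform random genome subsets of configured occupancy,
and per-genome singletons, on a star phylogeny. Each family has a random
root protein, a back-translated root CDS (uniform synonymous codons), and a
family-rooted intergenic spacer; genomes concatenate their gene copies into
contigs.

The divergence parameters are calibrated to what the downstream estimators
measure: `aa_divergence`/`nt_divergence` are the expected *pairwise*
divergence between two genomes, implemented by substituting each copy at
half that rate relative to the family root (i.i.d. per site, never back to
the original character). Spacers diverge like CDS — real intergenic DNA of
congeneric genomes is homologous, and independent random spacers would
systematically depress fragment ANI by the intergenic fraction. With this
design, AAI and ANI recover `100·(1 − divergence)` to well within one
percentage point at realistic sequence lengths, which the suite checks on
a divergence grid (0.01/0.05/0.10, proteins of 300 aa, genomes ≥ 100 kb).

What the generator does *not* model: indels, rearrangements, HGT, gene
length variation, paralogy, or phylogenetically correlated divergence.
Passing tests therefore demonstrate that the pipeline's machinery is
correct under its stated assumptions — they do not show robustness to
fragmented assemblies, paralog-rich families or uneven evolutionary rates
in real data.

The shipped preset `"guyparkeria-like"` reproduces a published
eight-genome partition design — 1458 core, 909 accessory families spread
over occupancies 2..7 (152/152/152/151/151/151), 837 singletons
(105×5 + 104×3 per genome), a 3204-family pangenome — at 50-aa proteins so
full-scale family counts remain cheap to align; the BBH pipeline recovers
that partition exactly, which the acceptance tests exercise end to end.

## Problem sizes and runtime choices

The test suite runs module tests on 2–5 genome sets with tens of families
(seconds each), the identity-recovery grid on two-genome sets of ~110 kb,
and one full-scale preset run (8 genomes, 3204 families, ≈ 1 min);
the whole suite completes in a few minutes on one CPU. These sizes were
chosen so that exhaustive oracles (brute-force alignment, full subset
enumeration) remain feasible alongside the implementation they check.

## Known limitations

* Orthology is BBH-based and binary; in-paralogs are forced apart rather
  than modelled.
* The fragment ANI placement assumes a dominant colinear diagonal per
  fragment; heavily rearranged genomes within a fragment length would need
  a chaining step.
* E-values are not computed; significance is carried entirely by the bit
  score.
* 16S identities are user-supplied — rRNA gene prediction is out of scope.
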