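---
title: "Benchmarking targeted pharmacogenomic long-read assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking targeted pharmacogenomic long-read assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgxbench)
```

## The evaluation problem

Adaptive sampling lets a nanopore sequencer enrich an arbitrary set of
genomic targets in silico: each DNA strand is accepted or rejected in real
time after its first few hundred bases are aligned against a target BED.
For pharmacogenomics this makes it practical to sequence every gene with
documented PGx relevance in one PCR-free run and to call star-allele
diplotypes from long, phase-informative reads. `pgxbench` provides the
downstream evaluation layer for such an assay: panel construction,
panel-restricted variant benchmarking, per-gene phasing concordance,
star-allele concordance classification, and coverage summaries, plus a
synthetic-data module that makes the whole stack testable end to end.

## Panel construction

The panel starts from a clinical-annotation table (variant id, gene symbol,
evidence level). Because that dialect carries no genomic coordinates, a
separate coordinate table is joined on variant id. Three rules then map
each variant to a raw target region:

* **Intragenic** (exon or intron): the entire gene body becomes the target.
  The full locus is deliberately targeted — intronic and regulatory
  variants matter in PGx, and phasing benefits from every heterozygous site
  in the span.
* **Flanking**: a variant within `max_dist` (default 100,000 bases,
  inclusive at exactly the threshold) of the nearer gene boundary extends
  the target from the gene through the variant. The gene body is always
  included: a sliver from boundary to variant alone would contradict the
  whole-locus philosophy above.
* **Discarded**: variants further away, and variants whose gene symbol is
  unknown, produce no region. Malformed records are rejected individually
  with a reason; a batch never aborts.

Each raw region is padded by `flank` (default 20,000 bases) on both sides —
long molecules whose leading bases fall outside the target would otherwise
be rejected even though they cover it — then clipped to the chromosome and
merged. Bookended regions (end of one equals start of the next) are merged
too, since the sequencer treats them as one target. Interval arithmetic is
delegated to `GenomicRanges`; the test suite checks the merged base count
against a per-base boolean-mask oracle on small genomes.

The merged panel's genome fraction is compared with the 1–10% window
recommended for adaptive sampling; `genome_fraction()` flags panels outside
it. All internal coordinates are 0-based half-open (BED convention);
1-based VCF positions are converted at the parser boundary.

## Variant benchmarking with true negatives

Standard small-variant benchmarking ignores true negatives because in
whole-genome comparisons concordant reference positions dominate. A fixed
PGx panel is different: the assay's claim is a statement about every panel
variant, and reporting "ALT absent" correctly is clinically as important as
detecting ALT. The package therefore counts, over the panel sites present
in the truth evaluation:

* `truth_tp` / `truth_fn` — truth-ALT sites recovered / missed;
* `query_tp` / `query_fp` — query-ALT calls confirmed / spurious;
* `truth_tn` — sites where both callsets agree the ALT is absent;

and reports

$$\text{recall} = \frac{tp_t}{tp_t + fn_t},\quad
\text{precision} = \frac{tp_q}{tp_q + fp_q},\quad
\text{accuracy} = \frac{tp_t + tn_t}{\text{panel variants in truth set}}.$$

Conventions, chosen to mirror mainstream (GA4GH-style) benchmarking:

* A site where both callsets carry the ALT but with different genotypes is
  a *genotype mismatch*, contributing one truth FN and one query FP.
* Panel variants outside the supplied truth high-confidence regions are
  excluded from the denominator entirely.
* FILTER-failed query records are no-calls.
* Records are normalized before matching: shared padding bases trimmed
  (keeping at least one base per allele), multi-allelic records decomposed
  with genotypes recoded, MNPs decomposed into SNVs. The SNV/INDEL class is
  decided after normalization.
* Undefined ratios (0/0) are reported as NA rather than 0 or 1.
* Report percentages are rounded half away from zero to two decimals, the
  convention of published benchmarking tables (base R's `round()` would
  round half to even).

This is deliberately a *site-based* comparator: it does not perform
haplotype-aware complex-representation matching, so callsets with wildly
different local representations of the same haplotype may show small count
differences against a full comparison engine. For a panel of
point-annotated clinical variants this is the appropriate trade-off.

## Phasing concordance

Within a phase block only *relative* phase is meaningful; the labelling of
the two haplotypes is arbitrary per block. The per-gene phasing success
rate is computed as:

1. The *reference variants* of a gene are the truth callset's phased
   heterozygous variants within the gene span (convention: in `a|b` the
   left allele is haplotype 1; truth sets are globally phased per
   chromosome).
2. Each query phase block intersecting the gene is compared with the truth
   under both orientations (identity and global flip) **restricted to the
   gene**; the better orientation wins, ties break toward identity.
   Orienting per block-by-gene intersection means a switch error far
   outside the gene does not penalize the gene.
3. The rate is (matched reference variants) / (reference variants).
   Reference variants the query leaves unphased or misses entirely count as
   incorrectly phased — the reference considers them, and unphased variants
   are exactly what depresses the rate in practice. Counting missing
   variants in the denominator is a deliberate choice (the alternative —
   dropping them — inflates rates when the query callset is sparse); it is
   easy to probe by filtering the query before scoring.

Genes with no reference variants are flagged, not scored. For downstream
summaries, genes are split at a phased-fraction threshold (default 0.90,
*inclusive* in the upper group) and the gene span lengths of the two groups
are summarised — long genes accumulate unphased variants because even long
reads cannot span the locus, and the synthetic tests reproduce that
pattern. Switch/flip-error decompositions (NG50-style block metrics) are
out of scope.

## Star-allele concordance

Star-allele nomenclature is irregular enough that string equality is the
wrong comparator. The parser normalizes tokens (leading `*` stripped, case
folded, whitespace and footnote markers tolerated, caller-specific suffixes
after a `.` dropped) and applies three structural rules:

* **Suballele wildcard**: a bare core allele matches any single-letter
  suballele of itself (`*1` ~ `*1A`) — the core is simply less resolved —
  but two fully specified suballeles differ (`*1F` !~ `*1M`), and a
  trailing digit is never a suballele letter (`*1` !~ `*12`).
* **Multisets**: multi-copy sides (`*1+*1`) and compound alleles
  (`*5A_7A_1B`) match only as equal multisets of members under the same
  rule; the two sides of a diplotype are unordered.
* **References**: a bare dash is an absent reference; a dash with a
  parenthetical is an *assigned* reference (taken from a secondary source)
  and is compared normally; any cell containing "no consensus" is treated
  as absent even when a candidate is printed (such candidates reflect a
  single assay, not a consensus); `;`-separated alternatives are an
  ambiguous reference that can never be concordant; gene-specific assay
  shorthand is resolved through an extensible alias table (e.g. G6PD "NEG",
  the absence of the A+/A− allele, is the wild type `*B/*B`).

Whether a discordant call *augments* the reference (the assays behind the
reference simply never tested the allele found) cannot be decided from the
strings; it is supplied as a curation list. The default list covers the
three curated genes of the flagship sample/chemistry column (CYP1A2, DPYD,
GSTP1). The bundled `example_diplotype_table()` transcription feeds both
the regression tests and `scripts/acceptance.R`.

## Read filters and coverage

Two read filters mirror the adaptive-sampling workflow: a mean-quality
filter, *strict* at the threshold (quality > 10; the `inclusive` switch
admits >= for sensitivity analysis), and an accepted-only filter, since
rejected strands leave short fragments that map poorly. Depth statistics
are computed over targeted bases only, with panel bases missing from the
depth track counted as depth 0 in every denominator; the reported fractions
at 15/20/30X are monotone by construction and are checked against a
per-base scan in the tests.

## The synthetic-data generator

The generator emulates the *statistical structure* of the real inputs at a
desk scale, with defaults chosen once to reflect the study conditions the
package is designed around:

* a 24 Mb, four-chromosome genome with 20 non-overlapping genes
  (log-uniform lengths 5–30 kb) whose merged 20 kb-flanked targets cover
  roughly 5% of the genome — inside the 1–10% adaptive-sampling window;
* ~70% of clinical variants intragenic, 20% flanking, 10% beyond-threshold
  decoys; ~2.5% INDELs;
* ~38% of panel sites carrying ALT in truth, 60% of those heterozygous,
  and ~2.5% of panel sites excluded from the high-confidence regions
  (matching the observed panel-to-truth attrition);
* query error rates of the order seen in the nanopore callsets (FN 0.5%,
  FP 0.2%, genotype error 0.2%);
* phase corruption as a Markov process along each chromosome: a new block
  starts between consecutive heterozygous sites with `block_break_rate`,
  and the haplotype labelling flips with `switch_error_rate` — the standard
  switch-error model;
* negative-binomial depth (mean 47, matching the flagship run's on-target
  average) in 500 bp chunks, log-normal read lengths, normal quality
  scores, and accept/reject/no-decision labels.

Every generator is deterministic under the config seed and emits an intent
sidecar (which sites were dropped, added, mistyped; which sites were
excluded), which the tests use as an exact oracle: the classifier must
reproduce the injection table site by site, and observed FN/FP/switch rates
must fall inside exact binomial 99% intervals at n ≥ 1,000–2,000.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: base-level sequencing error and its sequence
context, alignment and variant-representation ambiguity (simulated variant
positions are unique per chromosome; normalization is instead exercised on
crafted fixtures), linkage structure between sites, copy-number and
structural variation, and the biased genome-wide distribution of clinical
annotations. Headline results that depend on the real data — genome-wide
panel size, sample depths, per-gene figure percentages — are consequently
not regression targets; the package reproduces the published *worked
examples* (benchmarking table recalls, the diplotype concordance counts,
the one-of-three phasing example) and the structural properties.

## Numerical and degenerate-input choices

* Half-up rounding to two decimals for reported percentages; fractions kept
  at full precision internally.
* Orientation ties break toward identity; with zero shared variants a block
  contributes nothing.
* Bookended intervals merge; empty panels are an error for depth statistics
  (there is no denominator) but valid for `genome_fraction()` (fraction 0,
  outside the window).
* 0/0 metrics are NA, never silently 0 or 100%.
* Per-record rejection with a recorded reason for malformed annotations;
  errors that indicate a broken invocation (unknown chromosome, missing
  decision column with the accept-filter on, negative counts) abort with a
  message naming the offender.

## Problem sizes

The test suite runs entirely on synthetic data: toy genomes up to ~1 Mb for
the per-base oracles, 1,500–2,000-site callsets for the binomial
parameter-recovery checks, 200-replicate Monte-Carlo loops for the
switch-error monotonicity property, and the printed-table compositions
(~3,300 sites) for the benchmarking worked examples. These sizes keep the
suite fast while leaving the statistical assertions well-powered; all of
them are set in the fixtures and can be scaled up freely.
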