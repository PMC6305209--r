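---
title: "Cross-mappability: quantifying and filtering read-misalignment artifacts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-mappability: quantifying and filtering read-misalignment artifacts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossmapR)
```

## The problem

Short RNA-seq reads originating from one gene can be misaligned to another
gene whenever the two share stretches of similar sequence — pseudogenes and
their parent genes being the canonical case.  The misaligned reads make the
second gene appear expressed, and its apparent expression tracks the first
gene's true expression.  Two kinds of false positives follow:

* a variant that is a genuine *cis*-eQTL of the source gene shows up as a
  spurious *trans*-eQTL of the sequence-similar target gene (often on a
  different chromosome), and
* the two genes appear co-expressed.

Both artifacts survive the common practice of discarding multi-mapped
reads, because genetic variation and reference errors can make a misaligned
read look unique.  `crossmapR` quantifies the *potential* for this
misalignment for every directed pair of annotated genes, and provides the
screening tools that use that resource to flag suspect associations.

## The metric

Reads are proxied by positional k-mers drawn from each gene's collapsed
exonic and untranslated regions.  For a k-mer with $C_k$ genomic placements
within a Hamming-distance budget (both strands, no indels), its
**mappability** is $1/C_k$; a value of 1 means genome-unique.  A gene's
exon (UTR) mappability is the mean over its exonic (UTR) k-mers, and its
**gene mappability** is the average of the two components weighted by the
collapsed region lengths.

**Cross-mappability** from gene A to gene B, $\mathrm{crossmap}(A,B)$, is
the number of A's k-mers having at least one placement whose leftmost
coordinate starts inside B's exonic or UTR intervals.  It is a directed,
integer-valued score; $(A,B)$ and $(B,A)$ are distinct records and need not
be equal (a long gene harbouring a copy of a short gene receives more
k-mers than it sends).  A trans association is *cross-mappable* when some
gene with TSS within 1 Mb of the variant cross-maps with the trans target
gene — a candidate artifact, not a proven false positive.

## Parameters and defaults

| parameter | default | rationale |
|---|---|---|
| `k_exon` | 75 bp | typical RNA-seq read length; k-mers proxy reads |
| `k_utr` | 36 bp | UTR regions are usually shorter than exons; a smaller k avoids leaving short UTRs unmeasured |
| `max_mismatches` | 2 | mismatch tolerance of a standard short-read aligner in `-v 2` style mode; configurable because larger budgets strictly enlarge the resource |
| cis window / flag window | 1 Mb | conventional cis-eQTL window, anchored at the gene TSS, inclusive at the boundary |
| MAF filter | `>= 0.05` inclusive | standard association-scan floor |
| flag direction | `either` | conservative: a pair is suspect if either direction cross-maps; `a_to_b` restricts to candidate-gene → target |

A gene whose exons are all shorter than `k_exon` *and* whose UTRs are all
shorter than `k_utr` yields no k-mers: its mappability and its
cross-mappability (in both directions) are **undetermined** (`NA` in
output; such genes are excluded as targets as well as sources).  A region
class that is merely too short for its own k (e.g. a 74 bp exon alongside a
long UTR) is undetermined *componentwise* and drops out of the
length-weighted gene average together with its weight — the weighting uses
collapsed region lengths, not k-mer counts.

## Collapsed gene models

All transcripts of a gene are merged: overlapping exon intervals are
unioned, overlapping UTR intervals are unioned, and (by default) UTR bases
are subtracted from the exon class so each base belongs to exactly one
class.  Annotations leave it ambiguous whether UTR bases — which sit inside
exons in a GTF — should be double-counted when choosing k; we subtract,
because otherwise the same base would be sampled at two different k values,
and we expose `utr_subtraction = FALSE` for the alternative reading.
Coordinates are 0-based half-open internally; GTF input (1-based inclusive)
is converted on ingest.  Genes with no exon or UTR feature are skipped with
a warning.

## The aligner and its oracle

Placements are found by a pigeonhole-seeded search implemented in C++: a
k-mer searched at Hamming distance $\le m$ is split into $m+1$ blocks, any
valid placement must match at least one block exactly, so candidate
positions are harvested from an exact 6-gram index of the genome and
verified by Hamming count with early exit.  When blocks are shorter than
the index q-gram (small k with large $m$), the search falls back to
scanning every offset — the output contract is identical.  Reverse-strand
placements are found by searching the reverse complement; a hit's
coordinate is its leftmost genomic position, as aligners report.

Choices worth making explicit:

* **N policy.**  A genome or query position containing N never matches
  anything (including another N); k-mers containing N are skipped during
  enumeration and counted in a skip log.  IUPAC codes other than N are
  mapped to N on FASTA ingest.
* **Palindromes.**  A sequence matching at the same leftmost coordinate on
  both strands counts as two placements — placements are distinct
  (chromosome, start, strand) triples.  At k = 36/75 this is negligible.
* **Self-hits.**  Every genomic k-mer has $C_k \ge 1$ (its origin);
  $C_k \le 0$ is an error, so mappability is always in $(0, 1]$ when
  defined.

The package also ships `brute_force_oracle()`, a deliberately independent
R implementation that scans every offset on both strands and counts
mismatches naively (guarded to genomes $\le$ 1 Mb).  The test suite checks
set-equality of the two on hundreds of randomized genome/k/m cases, and all
planted-fixture truths are derived from the oracle, never from the seeded
search being tested.

## Computing the resource

Two shortcuts make the genome-wide computation tractable and are proven
output-equivalent to the unoptimized computation in the test suite: a gene
with mappability 1 contributes nothing (all its k-mers are unique), and
within an ambiguous gene only k-mers with mappability < 1 need be
considered.  Counting is once-per-target: a k-mer hitting gene B at several
positions adds 1 to $\mathrm{crossmap}(A,B)$; the same k-mer may also count
toward other targets.  Hits landing back inside the source gene are
ignored.  Hits inside genes whose genomic spans overlap the source gene are
*kept* in the resource; the co-expression ranking excludes span-overlapping
pairs downstream instead, so the resource remains analysis-agnostic.
Membership is tested on the hit's start position only (half-open
containment), a literal reading of "alignment starts within" the target's
regions.

## The association screen

The trans-eQTL scan tests inter-chromosomal variant–gene pairs with an
ordinary least-squares model (expression ~ dosage + covariates +
intercept), computed through the Frisch–Waugh–Lovell closed form: both
matrices are residualized against the covariates once and the genotype
t statistic comes from the residual correlation with
$df = n - q - 1$ (q = covariates + intercept).  The single-pair
`linear_association()` is validated against `stats::lm` in the tests.
Pairs on the same chromosome beyond the cis window are "other" and excluded
from both cis and trans summaries.  Benjamini–Hochberg adjustment is the
standard step-up rule; after removing flagged tests the FDR must be
recomputed on the reduced set — `refilter_and_reassess()` returns both
significant sets, and the filtered set can lose unflagged hits that were
only significant in the company of the flagged ones.

For replication, the best variant per discovery gene (lowest p, ties broken
by lexicographic variant id) is carried into the replication set, and the
replication fraction is reported per flag class.  For co-expression,
expression is residualized against all covariates, pairs are scored by
absolute Pearson correlation, cross-mappable pairs are sampled with
probability proportional to their cross-mappability (sequential conditional
draws without replacement, so the sample is a set of distinct pairs
spanning the whole cross-mappability range), and the flag classes are
compared with a one-sided Wilcoxon rank-sum test (exact enumeration up to a
combined n of 20 without ties, normal approximation with tie correction
otherwise).

## What the synthetic fixtures emulate — and what they do not

The generator draws i.i.d. uniform ACGT chromosomes, plants
single-transcript genes (1–3 exons, optional UTRs at the gene ends), and
copies segments between genes at controlled Hamming distances.  Expected
cross-mappability counts for every planted pair and every mismatch budget
up to 3 are derived with the brute-force oracle at build time, so
`compute_crossmap()` can be compared to ground truth *exactly*.  Two
deliberate generator choices:

* In i.i.d. sequence of the fixture sizes used here ($\le$ 50 kb), the
  probability of an accidental (non-planted) 36- or 75-mer duplication is
  astronomically small ($\approx L^2 \cdot 4^{-k+O(m)}$), so truth counting
  is restricted to k-mers overlapping planted segments; any violation of
  this assumption would surface as a truth/resource mismatch in the exact
  equality tests.
* The single base flanking each planted copy on either side is forced to
  differ from the corresponding source flank.  Without this, a k-mer
  overhanging the segment by one base extends a chance match with
  probability 1/4 and the planted count would be
  $L - k + 1 + \mathrm{Binomial}$; with it, exact-match counts follow the
  closed form (e.g. a 100 bp copy at k = 75, m = 0 yields exactly 26
  k-mers in each direction).

The expression model is deliberately minimal: source genes receive
independent standard-normal expression, a contaminated target measures
$\alpha \cdot \mathrm{source} + \mathcal{N}(0, \sigma^2)$, and a cis
variant adds $\beta \cdot \mathrm{dosage}$ to the source (hence
$\alpha\beta \cdot \mathrm{dosage}$ to the target).  The population
source–target correlation is $\alpha / \sqrt{\alpha^2 + \sigma^2}$, which
the tests recover.  Simulation defaults — $n = 500$ samples,
$\alpha = 0.5$, $\beta_{cis} = 1$, MAF 0.3, unit noise — give the spurious
trans association comfortable power at desk scale, while $\alpha = 0$
reduces the scan to an exactly calibrated null (uniform p-values), which is
also tested.

What the fixtures do *not* emulate: real read sampling (FASTQ level,
coverage, fragment effects), splice junctions (k-mers are genomic, so
junction-spanning reads are invisible — alignment to the transcriptome is
out of scope), library-size and count-distribution effects (expression is
Gaussian, not negative-binomial), linkage disequilibrium, and population
structure.  Passing tests therefore demonstrate the correctness of the
metric and screening logic, not the real-data magnitude of the artifact.

## Numerical and tie-break conventions

* Interval arithmetic is half-open throughout; abutting intervals merge.
* Association ranking breaks p-value ties by (variant id, gene id).
* Weighted sampling uses `sample.int(prob = ...)`, i.e. successive draws
  proportional to remaining weights.
* The quantile grouping of pairs by cross-mappability builds the upper
  groups by fixed counts from the top of the distribution (default 2,000
  ×5, 5,000, 10,000, 25,000, 50,000), splits the remaining positive-weight
  pairs into equal quantile groups, and reserves group "0" for
  non-cross-mappable pairs; requesting more pairs than exist truncates with
  a warning.
* Degenerate inputs error early: zero-variance genotypes (skipped with a
  log message in the batch scan), rank-deficient covariates, empty k-mers,
  counts $\le 0$ in a resource file.

## Problem sizes

The shipped tests and the acceptance script run entirely on generated
fixtures: genomes of 8–24 kb across two chromosomes, genes of 100–400 bp,
200 randomized aligner/oracle comparison cases, 20 planted-duplication
fixtures, trans scans of up to 10,000 null tests at 200–500 samples, and
3,000 simulated co-expression pairs.  These sizes were chosen so the whole
battery completes in minutes on one CPU while still exercising every code
path, including both k classes and all mismatch budgets 0–3.  The same
functions scale to a real genome + GTF (hours of compute; the resource for
a mammalian genome is best built per chromosome batch), which is why the
`compute-crossmap` CLI exposes `--k-exon`, `--k-utr` and `--mismatches`.

## Known limitations

* Hamming distance only: indels and quality-aware alignment are not
  modelled, matching the read-proxy abstraction of the metric.
* Genomic k-mers cannot capture splice-junction reads; transcriptome-space
  alignment would be a natural extension.
* Cross-mappability flags *potential* artifacts.  Sequence-similar genes
  can be genuinely co-regulated; the resource is a screening tool, and
  flagged hits deserve inspection (coverage plots, functional context)
  rather than automatic deletion.
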