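---
title: "Methods: chromosome-quotient classification and repeat divergence landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromosome-quotient classification and repeat divergence landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cqscan)
```

# The problem

In species with heteromorphic XX/XY sex chromosomes, a draft assembly built
from pooled male DNA contains autosomal, X-linked and Y-linked contigs mixed
together, and short fragmented contigs carry no cytological signal about
which is which. What they do carry is a copy-number signature: females have
two copies of X and none of Y, males one of each. Sequencing one female pool
and one male pool to comparable depth and asking, contig by contig, "how
often do female versus male reads align here?" separates the three classes.

`cqscan` implements that analysis — the chromosome quotient (CQ) — together
with the two companion analyses that typically accompany a draft-genome
report: transposable-element (TE) accumulation landscapes based on Kimura
2-parameter (K2P) divergence, and standard assembly statistics (N50, AT
content, N density). A simulator generates sexed genomes and read pools so
the full pipeline is testable end to end without any external download.

# The chromosome quotient

For contig $c$, with $f_c$ female and $m_c$ male alignment counts and
library totals $F$ and $M$:

$$\mathrm{CQ}_c = \frac{f_c / F}{m_c / M}$$

Alignment here means the **whole read matches with zero mismatches and no
indels**, on either strand. This deliberately stringent criterion is the
point of the method: tolerant alignment lets X-derived female reads land on
diverged gametologs or repeats on other contigs and dilutes the copy-number
signal, whereas exact matching keeps reads on the sequence they came from.
Under it the expectations are CQ ≈ 1 for autosomes, ≈ 2 for X (two female
copies vs one male copy), and ≈ 0 for Y (no female copies).

Decision rule, applied per contig:

* **Y** if CQ < `y_max` (default **0.05**, half-open band $[0, 0.05)$);
* **X** if `x_min` ≤ CQ ≤ `x_max` (default closed band $[1.9, 2.5]$ —
  "between 1.9 and 2.5" is read inclusively, and the boundary case 1.9 is
  labeled X);
* otherwise **unassigned**;
* **low-evidence** (no CQ at all) if the male count is below
  `min_male_hits` (default **20**). The ratio's denominator is the male
  count; with a handful of male hits, Poisson noise alone can push an
  autosomal contig into the X band, and a zero male count would make CQ
  infinite. Published descriptions of the statistic are silent on this
  regularization, so the floor is exposed as an ordinary parameter rather
  than hidden.

Library-size normalization (`normalize = TRUE` by default) makes the
statistic portable across unequal sequencing efforts; when the two sexes are
sequenced with equal effort it reduces to the raw count ratio.

## Matching machinery

Counting is one pass of an Aho–Corasick dictionary scan
(`Biostrings::PDict`/`vwhichPDict`) of the reads over each contig and its
reverse complement. Reads are chunked (500,000 per dictionary by default) to
bound memory, and grouped by length since dictionaries are constant-width.
Conventions, chosen once and tested:

* a read occurring at several positions in one contig counts **once** for
  that contig (damps within-contig repeat inflation) but may count once in
  each of several contigs;
* `N` matches nothing on either side — a read containing `N` can never
  match, and an `N` in a contig can never be matched — which is the
  conservative reading of a zero-mismatch contract;
* no mismatch budget, no soft clipping, no quality use at any point.

A naive $O(nm)$ substring scan, written independently in the test suite,
serves as the oracle: on randomized instances the indexed counts must equal
it exactly.

# Kimura 2-parameter repeat landscapes

Each TE insertion is compared with its family consensus, treated as the
ancestral state. From the pairwise alignment we count, over columns with a
standard base on both rows (gap and `N` columns leave the denominator), the
transition proportion $P$ (A↔G, C↔T) and transversion proportion $Q$, and
compute

$$K = -\tfrac{1}{2}\,\ln\!\big((1 - 2P - Q)\sqrt{1 - 2Q}\big).$$

$K$ estimates substitutions per site, correcting the raw mismatch fraction
$P + Q$ upward for multiple hits at one site. When $1 - 2P - Q \le 0$ or
$1 - 2Q \le 0$ the correction diverges; such saturated alignments are
reported in a separate bucket, never clamped into the oldest bin, because
clamping would silently inflate exactly the bins where ancient elements
accumulate.

The landscape bins each insertion's aligned columns (bp) by $100K$ percent
divergence. Aligned columns, not genomic span, are the weight, so an
insertion aligned over 500 columns contributes 500 bp wherever its
divergence falls. Bins of width 1 percentage point partition $[0, 55)$ by
default — old dipteran TE landscapes concentrate in the 20–45 % range, so
55 % leaves headroom — with one overflow bin $[55, \infty)$ so that binned
bp always equals the aligned bp of defined-divergence insertions (an exact
bookkeeping identity the tests assert). Divergence is plain K2P; no
CpG-adjusted variant is offered.

Inputs can be (a) a canonical TSV with both gapped alignment rows inline,
(b) a best-effort parse of cross_match/RepeatMasker-style `.align` blocks,
or (c) alignments computed in-package by global affine-gap alignment
(match +2, mismatch −2, gap open −5, gap extend −1; a gap of length $L$
costs $5 + L$). Repeat fractions of a sequence set merge overlapping
annotation intervals per contig before summing, so nested repeat calls are
never double-counted.

# Assembly statistics

Definitions are fixed and bit-reproducible:

* **N50**: sort lengths descending; the length at which the cumulative sum
  first reaches half the total. The contig crossing the boundary resolves
  the tie (QUAST's convention).
* **%AT** is computed over A/C/G/T calls only. `N` is excluded from the
  denominator because N content is reported separately; including it would
  shift %AT by well under 0.1 % at typical N densities, but the two
  conventions are not interchangeable and ours is stated.
* **N per 100 kb** = $10^5 \cdot \#N / \text{total bp}$ (total includes N).

# The simulator: what it emulates, and what it does not

The generator's defaults are the package's reference study conditions, used
by the acceptance tests and `cq_reference_run()`:

| Parameter | Default | Why |
|---|---|---|
| contigs | 140 A / 30 X / 30 Y | fragmented draft with substantial sex-linked content |
| contig length | 5–50 kb uniform | short-read draft contig scale |
| GC | 0.28 | AT-rich (72 % AT) dipteran genome composition |
| depth | 20× per sex | enough that CQ noise is small but misclassification is still observable |
| read length | 100 bp | Illumina short-read scale |
| substitution error | 0.005/bp | typical raw Illumina error; with exact matching, ~0.995^100 ≈ 61 % of reads survive |
| ts:tv event ratio | 2 | typical genome-wide transition bias |
| TE divergences | 0.05 / 0.15 / 0.30 | young, middle-aged, old element cohorts |

Contigs are i.i.d. random sequence generated independently per class —
fragmentation is simulated directly rather than by fragmenting chromosomes,
because the CQ method is strictly per-contig and uses no linkage. Reads are
drawn uniformly over a copy-number-weighted template (female A=2, X=2, Y=0;
male A=2, X=1, Y=1), both strands equiprobable, and each sex is sequenced to
the same fold-coverage **relative to its own copy-weighted genome length** —
the analogue of giving each pool equal lane share — which is what makes the
expected autosomal CQ exactly 1. Read counts are
$\mathrm{round}(\text{depth} \times W / \ell)$, conserving coverage to
within one read. Errors are substitutions only, uniform over positions:
under a zero-mismatch whole-read criterion, any error whatsoever unmaps a
read, so indel and quality modelling would add realism the statistic cannot
see.

Planted TE copies evolve from their consensus under a continuous-time K2P
process: `target_divergence` is the expected number of substitution
*events* per site, and sites can be hit more than once. This is the
generative model the K2P estimator inverts, so recovered divergence is
compared against the target directly; the raw mismatch fraction of a copy at
divergence 0.30 is expectedly lower (≈ 0.26). Realized per-copy $P$ and $Q$
are recorded in the truth table so estimator and generator can be checked
against each other without re-alignment.

What the simulator does **not** model — and therefore what passing tests do
not demonstrate about real data: allelic variation within pooled
individuals (real pools of several diploid individuals put heterozygous
mismatches on the male reference, pushing some true-X contigs' CQ off 2),
GC-coverage bias, indels and structural variation, paired-end structure,
and real repeat families with internal deletions. On real data the CQ bands
were tuned by its original authors against these effects; here they are
validated against the idealized copy-number signal only.

# Numerical and design choices

* **Determinism.** Every stochastic operation takes an explicit seed and
  restores the caller's RNG state; the pipeline derives per-stage seeds
  from one top-level seed, so stages are reproducible independently.
  Reruns with identical config produce byte-identical TSV/JSON artifacts,
  and the run manifest records parameters, package version, seed and
  checksums of all inputs and outputs.
* **Alignment tie-breaks** follow the fixed traceback order of the
  dynamic-programming implementation; scores are what the tests pin down
  (against an independent quadratic-space Gotoh implementation), since
  equal-scoring alignments yield the same $P + Q$ up to column placement.
* **Degenerate inputs.** Empty assemblies, zero-contig specs, reads longer
  than every contig, annotation intervals beyond contig ends, and saturated
  divergences all fail loudly (or route to explicit buckets) rather than
  silently.
* **Problem sizes in the test suite.** The reference recovery experiment
  uses the 200-contig, 20× conditions above (~1.9 M reads per sex, ~80 s);
  matcher oracles run on ≤ 100 kb instances where the naive scan is
  feasible; alignment oracles on ≤ 200 bp pairs; divergence recovery on
  20 × 5 kb copies per cohort. These sizes make the binomial/Poisson noise
  terms small relative to the asserted tolerances, which were derived from
  the closed-form error models before running anything.

# Known limitations

* CQ classification inherits the method's arbitrary-threshold character:
  the 0.05 and [1.9, 2.5] bands are the published convention, not estimated
  from the data at hand; contigs that are partly X-linked (chimeric) land
  wherever their mixed counts put them.
* The exact matcher is built for assemblies in the hundreds of Mb and read
  sets in the tens of millions on a desktop; it is not a general-purpose
  aligner and emits no SAM/BAM.
* The `.align` parser is deliberately tolerant and best-effort; the
  canonical TSV is the supported interchange format.
* Per-chromosome repeat percentages on real genomes depend on the repeat
  library snapshot used for annotation; the package computes fractions from
  whatever annotations it is given and makes no claim about library
  completeness.
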