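# cqscan

Coverage-based identification of sex-chromosome contigs in fragmented
genome assemblies, plus transposable-element divergence landscapes and
standard assembly statistics.

## What it does, and for whom

Draft assemblies of species with heteromorphic XX/XY sex chromosomes mix
autosomal, X-linked and Y-linked contigs, and short contigs carry no
cytological clue about which is which. If separate female and male read
pools are available, copy number does the work: X sequence is present twice
in females and once in males, Y sequence is absent from females. `cqscan`
is for genome-assembly groups who have such sex-pooled short reads and want
per-contig sex-linkage calls, repeat accumulation profiles, and QC metrics,
all reproducibly scriptable in R.

The core statistic is the **chromosome quotient (CQ)**. For contig *c*,
with female/male whole-read zero-mismatch alignment counts *f_c*, *m_c* and
library totals *F*, *M*:

    CQ_c = (f_c / F) / (m_c / M)

Alignment is deliberately stringent — the entire read must match with zero
mismatches, either strand — so reads stay on the sequence they came from
and the copy-number signal is not diluted by diverged paralogs. Expected
values are ≈1 on autosomes, ≈2 on X, ≈0 on Y. Default calls: **Y** if
CQ < 0.05, **X** if 1.9 ≤ CQ ≤ 2.5, **low-evidence** when the male count is
below 20 (denominator regularization), otherwise unassigned.

Around the classifier the package provides:

* **Kimura 2-parameter repeat landscapes** — per-insertion divergence from
  the family consensus, `K = -1/2 ln((1-2P-Q) sqrt(1-2Q))` with transition
  proportion P and transversion proportion Q counted over aligned non-gap
  columns, binned into the classic bp-per-percent-divergence accumulation
  profile; saturated alignments go to an explicit bucket, never clamped.
* **Assembly statistics** — N50, %AT (over ACGT calls only), N per 100 kb,
  contig counts/length at a 1 kb floor, with fixed tie conventions.
* **A sexed-genome simulator** — autosomal/X/Y contigs, female and male
  read pools drawn from copy-number-weighted templates at configurable
  depth and error rate, and TE copies planted at target K2P divergences
  with realized substitutions recorded in a truth table. Every analysis
  stage is testable end to end with no external data.

See `vignette("cq-landscape-methods", package = "cqscan")` for the model,
parameter rationale, and the simulator's scope and limits.

## Worked example

```r
library(cqscan)

g <- simulate_genome(genome_spec(20, 6, 6, c(5000, 20000), seed = 42))
lib <- make_te_library(seed = 42)
g <- plant_te_copies(g, lib, te_plant_spec("Jockey-like#LINE",
  n_copies = 8, target_divergence = 0.30, seed = 43
))
female <- simulate_reads(g, read_sim_spec("female", depth = 20, seed = 44))
male <- simulate_reads(g, read_sim_spec("male", depth = 20, seed = 45))

idx <- exact_index(g$contigs)
rec <- compute_cq(
  count_exact_matches(idx, female),
  count_exact_matches(idx, male),
  cq_thresholds()
)
head(rec, 3)
#>   contig_id length female_count male_count    cq      label
#> 1  ctg00001  18723         4689       4527 1.047 unassigned
#> 2  ctg00002  19057         4608       4581 1.017 unassigned
#> 3  ctg00003   9292         2276       2208 1.042 unassigned
```

Autosomal contigs sit at CQ ≈ 1 and stay unassigned. Summing per label:

```r
summarize_chromosomes(rec)
#>          label n_contigs total_bp
#> 1            X         6    83624
#> 2            Y         6    91913
#> 3   unassigned        20   283947
#> 4 low-evidence         0        0

table(truth = g$truth$class, label = rec$label)
#>      label
#> truth unassigned  X  Y
#>     A         20  0  0
#>     X          0  6  0
#>     Y          0  0  6
```

All six X-linked and six Y-linked contigs are recovered with no autosomal
false positives; the `total_bp` column is the putative chromosome size
obtained by adding member contig lengths. Assembly QC on the same contigs:

```r
assembly_stats(g$contigs)
#> Assembly statistics
#>   contigs:           32
#>   total length:      459484 bp
#>   N50:               16064 bp
#>   mean / max contig: 14359 / 19834 bp
#>   %AT (ACGT only):   71.29
#>   >=1 kb:            32 contigs, 459484 bp
#>   N per 100 kb:      0.00
```

The %AT reflects the simulator's AT-rich default (GC = 0.28). For the
repeat side, `repeat_divergence()` + `build_landscape()` turn alignment
rows (canonical TSV, `.align` files, or in-package `align_copy_to_consensus()`)
into the binned landscape; `plot_landscape()` and `plot_cq()` draw the
standard figures.

`run_pipeline()` stitches everything into one reproducible run (YAML
config, derived per-stage seeds, JSON report with a truth confusion matrix
in simulation mode, and a checksum manifest); `inst/cli/cqscan` exposes the
same stages as `simulate` / `count` / `cq` / `landscape` / `stats` / `run`
subcommands.

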