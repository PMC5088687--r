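# loop4c

Integrative analysis of a single genomic viewpoint's chromatin contacts:
4C-seq profile construction and significant-interaction calling, interval
annotation and enrichment, network connectivity of gene hit sets,
knockout differential-expression criteria, and Hi-C cross-validation — with
a synthetic-data module that generates every input the pipeline consumes.

The package is aimed at regulatory-genomics analysts who have (or simulate)
viewpoint-based contact data and want the full chain from aligned read
positions to tiered interaction calls and the downstream integrative
statistics, as composable tibble-first R functions.

## The methods in brief

* **Virtual fragment library.** The genome is digested in silico at the
  primary enzyme motif (DpnII `GATC`); fragments without an internal
  secondary site (NlaIII `CATG`) are "blind" and masked from statistics.
  Reads map to fragments; viewpoint self-ligation and undigested neighbors
  are excluded and tallied.
* **Profile.** Counts are normalized to reads per million, replicates
  averaged, and the cis distance decay removed with a fixed slope −1 fit on
  the log-log scale: expected density `exp(â)/d` with
  `â = mean(ln ρ + ln d)`; trans fragments are scaled by their mean
  background.
* **BRICK calling.** Corrected densities are rank-transformed genome-wide
  and every window of width 1..W is scored by the Irwin–Hall upper tail of
  its rank sum (exact ≤ 12, Lugannani–Rice saddlepoint above). Windows below
  p < 0.01 are selected greedily into non-overlapping BRICKs, and FDR tiers
  (≤ 1%, ≤ 10%) are calibrated by genome-wide value permutation with the
  add-one convention `FDR(θ) = ((1 + Σ perm counts)/(B+1)) / observed`.
* **Annotation & enrichment.** Cis/trans classification against the
  viewpoint, overlapping plus closest flanking genes within ±500 kb,
  midpoint window/cytoband counts with binomial enrichment (BH-adjusted),
  and hypergeometric gene-set overlap with odds ratios.
* **Knet connectivity.** For vertex hit weights `p` with mean `p̄`,
  `K(s) = (2/(n p̄)) Σ_i p_i Σ_{j≠i} (p_j − p̄) 1[d(i,j) ≤ s]` over
  shortest-path distances; AUK = Σ_s K(s); significance by weight
  permutation (Monte-Carlo or exhaustive).
* **Differential expression.** Pass = |log2 fold change| > 0.5 (ratio of
  group means on the intensity scale) AND t-test p < 0.05 (pooled variances
  by default) AND not low-expression; chromosome bias of the pass set by
  Pearson chi-square against the universe composition.
* **Hi-C.** KR-style matrix balancing, normalization-vector application,
  observed/expected with the expected vector clamped below at 1, 10×10
  block-sum coarsening, virtual-4C row extraction, and a Welch t-test of
  mean Hi-C signal in selected (FDR 1%) versus non-selected BRICKs.

See `vignettes/loop4c-methods.Rmd` for assumptions, parameter rationale, and
numerical choices.

## Worked example

The bundled demo configuration simulates a 460 kb two-chromosome genome
with a viewpoint on chr1, two replicate 4C libraries of 50,000 reads with
three planted fold-20 contact blocks, a 60-vertex network with a planted
8-gene module, a 3-vs-3 expression experiment with 30 planted effects, and
a biased Hi-C matrix — then runs the full analysis:

```r
library(loop4c)
s <- run_pipeline(list(seed = 1), out_dir = "demo_run", quiet = TRUE)
```

With seed 1 this prints (via the summary object):

```
BRICKs total: 3 | FDR<=1%: 3 | cis: 3 (100%)
replicate Spearman: 0.973
Knet AUK: 5.8 p: 0.000999
DE up/down: 30 / 5 | chi-square: 2.5 p: 0.114
```

Reading the numbers: all three planted contact blocks are recovered as
FDR ≤ 1% BRICKs on the viewpoint chromosome (cis fraction 100%); the two
replicate profiles agree at Spearman 0.97; the planted network module is
significantly more connected than permuted hit sets (p at the Monte-Carlo
floor for 1,000 permutations); 30 up-regulated probes recover the planted
effects, with 5 false positives from the unmoderated per-probe criteria.
`demo_run/` holds every intermediate in plain-text formats (FASTA, BED,
bedGraph, TSV, JSON summary), each re-loadable with the package's readers.

Individual stages compose directly:

```r
genome <- simulate_genome(sim_config(seed = 1))
lib    <- flag_validity(digest(genome), genome)
reads  <- simulate_4c_reads(lib, sim_config(seed = 1))
prof   <- normalize_profile(assign_reads(reads, lib, "chr1:512000"))
fit    <- fit_decay(prof)
fdr    <- estimate_fdr(correct_profile(prof, fit), n_perm = 50, seed = 1)
glance(fdr)   # tier thresholds and BRICK counts
```

A thin command-line wrapper is installed at `exec/loop4c`
(`loop4c run --config config.yaml --out DIR`, `loop4c simulate --what genome ...`).

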