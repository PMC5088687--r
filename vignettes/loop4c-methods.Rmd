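---
title: "Methods: viewpoint interaction calling, network connectivity, and Hi-C integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: viewpoint interaction calling, network connectivity, and Hi-C integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loop4c)
```

loop4c implements an integrative regulatory-genomics workflow around a single
genomic viewpoint: 4C-seq contact profiling and significant-interaction
(BRICK) calling, annotation and enrichment of the called intervals, a network
connectivity test for gene hit sets, knockout differential-expression
criteria with a chromosome-bias test, and Hi-C cross-validation. This
vignette explains each model, its assumptions, the tunable parameters, and
the numerical choices, in the order the pipeline runs them.

## The virtual fragment library

4C-seq signal lives on restriction fragments, not base pairs. The genome is
digested in silico with the primary enzyme's motif (DpnII's `GATC` by
default), cutting at the 5' start of every occurrence, so each fragment
begins with a motif occurrence and the fragments tile each chromosome
exactly. A secondary digestion (NlaIII, `CATG`) is required for template
circularization: fragments without an internal secondary site are "blind" —
they are retained with their counts but masked out of every rank statistic,
because they cannot be observed efficiently in the assay. On uniform random
sequence roughly half of all DpnII fragments are blind, which matches the
genome-wide intuition that blind fragments are common, not exotic.

The cut convention (fragment starts at the motif) is one of several
consistent choices; every downstream statistic depends only on fragment
order and membership, so the convention does not affect results.

Aligned reads arrive as mapped 5' coordinates. Reads on the viewpoint
fragment are tallied as self-ligation products, reads within
`exclusion_radius` fragments (default 1) as undigested carry-over; both are
excluded from the profile but conserved in the exclusion tally, so read
totals always reconcile.

## From counts to a corrected profile

Counts are normalized to reads-per-million over unmasked fragments, and
replicates are combined by averaging densities. Replicate concordance is
summarized by Spearman rank correlation, globally and in local windows
(default 29 fragments, matching the smoothing window).

Cis contact frequency decays with distance from the viewpoint
approximately as a power law with slope −1 on the log-log scale. With the
slope pinned at −1, the least-squares intercept on the natural-log scale has
a closed form: over fitted fragments (cis, unmasked, nonzero),

$$\hat a = \overline{\ln \rho_i + \ln d_i}, \qquad
  \mathbb{E}[\rho](d) = e^{\hat a} / d,$$

where `d` is the fragment rank distance (index difference) to the
viewpoint. Rank distance rather than bp distance keeps the decay model in
the same units as the fragment-domain smoothing and the domainogram; bp
distance is available as an option in the simulator. The fit excludes
zero-count fragments (log of zero) — a free-slope diagnostic fit is reported
alongside but never used for correction. Cis fragments are divided by the
fitted expectation; trans fragments by the global mean trans density (the
data carry no trans distance structure to model). A profile generated
exactly from the fitted model corrects to 1 everywhere, to machine
precision.

**Order of smoothing and correction.** The 29-fragment running mean is
applied to the *corrected* profile for visualization and concordance, not
before fitting. Smoothing a 1/d curve before fitting biases the
near-viewpoint expectation low by up to ~1.6x over roughly two window
widths, which manufactures guaranteed false positives there; the order is
config-exposed (`smooth_before_correct` semantics via the profile functions,
which are freely composable) but the default is correct-then-smooth.

## Domainogram BRICK calling

Corrected densities are rank-transformed genome-wide — cis and trans
fragments share one pool, so a single threshold governs both — and every
window of width 1..`w_max` is scored by the upper tail of its rank sum under
the null that ranks are independent uniforms (the Irwin–Hall distribution).
The exact alternating-sum closed form is used for widths up to 12; wider
windows use the Lugannani–Rice saddlepoint approximation to the same tail,
which is strictly positive, monotone, and accurate to well under 1% relative
error into the far tail (a plain Gaussian with matching mean and variance
errs by more than 30% already at p ~ 1e-4 for width 30, and an
Edgeworth-corrected Gaussian goes negative in the deep tail).

Two numerical details matter at desk scale:

* **Midranks.** The scan uses `(rank - 0.5)/n` rather than `rank/n`. With
  the latter the maximum fragment has scaled rank exactly 1 and its width-1
  window gets p = 0 in every dataset *and every permutation* — a guaranteed
  artifact call. The midrank gives the top fragment its honest discrete
  tail probability of about `0.5/n`.
* **Greedy selection.** Candidate windows below the calling threshold
  (default p < 0.01) are accepted by ascending p (ties: wider, then
  leftmost); each acceptance removes overlapping candidates. The accepted
  set at a tighter threshold is by construction a subset of the set at a
  looser one, so FDR tiers nest.

### Permutation FDR and its resolution

False discovery tiers are calibrated by shuffling unmasked values
genome-wide and re-running the entire chain (including re-smoothing, if a
pre-ranking smoother is configured — shuffling post-smoothing values would
destroy the autocorrelation the smoother induces and make the null
anti-conservative). The estimate uses the add-one convention:

$$\widehat{\mathrm{FDR}}(\theta) =
  \frac{(1 + \textstyle\sum_b C_b(\theta)) / (B + 1)}{C_{\mathrm{obs}}(\theta)},$$

capped at 1 and monotonized along the threshold grid. The add-one term
prevents a single extreme observed window from certifying itself against a
finite permutation sample (with the plain ratio the false-tier rate under
the null is about `1/(B+1)`, i.e. ~9% at 10 permutations — we measured 15%).
The flip side is a resolution bound: certifying FDR ≤ f requires at least
`1/(f (B+1))` observed BRICKs, so placing two or three BRICKs in a 1% tier
needs on the order of 50 permutations. The pipeline default is therefore
`n_perm = 50`; `estimate_fdr()` itself defaults to 20, suitable for 10%
tiers and exploration.

The tier threshold is the largest grid threshold with estimated FDR at or
below the tier; BRICKs carry the smallest tier they satisfy, and an
undefined tier (no qualifying threshold) yields an empty tier set rather
than an error.

## Annotation, windows, and set overlap

BRICKs are cis/trans-classified against the viewpoint chromosome (the cis
fraction is reported as a rounded percentage), annotated with overlapping
genes and the closest non-overlapping gene on each side within ±500 kb
(coordinate order, not gene strand — the flanking-gene notion is positional),
and counted into fixed windows or cytobands by midpoint, which prevents
double counting across boundaries. Per-window enrichment is a binomial upper
tail with success probability proportional to window length, BH-adjusted
across windows — a transparent count model standing in for web-service
enrichment statistics, which are out of scope. Gene-set overlap uses the
hypergeometric upper tail (one-sided enrichment, two-sided available), with
the Haldane–Anscombe +0.5 correction applied to the odds ratio only when a
zero cell occurs, and flagged.

## Network connectivity (Knet)

For an undirected network with vertex hit weights `p_i` (mean `p̄`), the
K-function over shortest-path distances is

$$K(s) = \frac{2}{n\,\bar p}\sum_i p_i \sum_{j \ne i}
  (p_j - \bar p)\,\mathbf 1[d(i,j) \le s],$$

summed over `s = 1..D` (AUK), with `D` the largest finite distance.
Unreachable pairs never satisfy the indicator, so fragmented hit sets dilute
connectivity — the intended behavior for a statistic about direct *and*
indirect connections. Constant weights give K ≡ 0 exactly. Significance
comes from permuting weights over vertices with the graph fixed (the
add-one Monte-Carlo p-value, lower-bounded by `1/(n_perm+1)`), or from
exhaustive enumeration of all hit-set placements when there are at most a
million. Edge rewiring is deliberately not offered: it changes the graph
topology the statistic conditions on.

## Differential expression and chromosome bias

The regulated-gene criteria are a |log2 fold change| above 0.5 — computed as
the log ratio of group means on the intensity scale, with
difference-of-log-means as an option — a per-probe t-test p below 0.05, and
a low-expression filter (default: the 20th percentile of overall probe
means) that no fold change can override. The default t-test pools variances:
at the 3-vs-3 design the pooled test is exactly calibrated under the
equal-variance log-normal model, while Welch's test is measurably
conservative there (type-I ~3.5% at nominal 5%); `welch = TRUE` restores the
unequal-variance test. No multiple-testing correction gates the pass set (a
BH column is emitted for information), matching the workflow the criteria
come from. The threshold is a parameter because the source describes both
"log ratio > 0.5" and "over twofold" conventions; 0.5 is the default.

Chromosome bias of the regulated set is a Pearson chi-square
goodness-of-fit against the universe's chromosome composition, pooling
chromosomes with expected count below 1, with the per-chromosome fractions
reported alongside.

## Hi-C operations

Matrices are symmetric with explicit `NA` for missing bins — zeros are real
contacts. `kr_balance()` finds the positive scale vector `x` making
`diag(x) M diag(x)` doubly stochastic by the symmetric fixed-point iteration
`x <- x / sqrt(rowsums)`, after masking all-zero rows; convergence is to a
configurable row-sum tolerance and non-convergence is an error carrying the
residual. `apply_normalization()` is the fidelity path for published
normalization vectors. Observed/expected divides by the per-distance
expected value clamped below at 1, the convention that avoids inflating
long-range ratios where expected counts are tiny. Coarsening sums
factor-by-factor blocks (partial trailing blocks as-is; fully missing blocks
stay missing), virtual-4C extraction reads one viewpoint row with the
viewpoint bin masked, and the selected-vs-non-selected BRICK comparison uses
per-BRICK mean track signal (bins assigned by midpoint) in a Welch two-sided
t-test, with per-bin comparison available by flag. Identical groups return
t = 0, p = 1 rather than a zero-variance error.

## The synthetic-data generators

Every input the pipeline consumes can be generated with the statistical
structure the analysis assumes: uniform random genomes; multinomial 4C reads
with cis weights proportional to rank-distance^slope (slope −1), planted
enrichment blocks multiplying those weights, and a uniform trans background
calibrated in expected reads per trans fragment; 3-vs-3 log-normal
expression with planted log2 effects and configurable chromosome
proportions; Erdős–Rényi or preferential-attachment networks with a planted
connected module (grown by seeded BFS) or a random hit set; and Hi-C
matrices `bias_i bias_j (1+|i-j|)^{-1}` with log-uniform biases and
symmetric planted peaks. Multinomial totals (rather than independent
Poisson) make conservation exact, which the tests exploit. Every generator
is a pure function of its config including the seed.

What the simulations do *not* emulate: sequencing error, PCR duplication,
mappability and GC structure, the heavy-tailed fragment-length distribution
of real digests, distance-dependent trans structure, and array
normalization artifacts. Passing the recovery and calibration suites
therefore demonstrates the statistical machinery is correct under its own
assumptions, not that real libraries satisfy those assumptions.

## Problem sizes and defaults

The calibration and recovery studies run on a ~1.3 Mb two-chromosome genome
(~5,000 DpnII fragments, half blind), 1e5 reads per library, trans
background 2 reads per fragment, domainogram width cap 101, threshold grid
1e-2..1e-12, and 50 permutations — sizes chosen so a full study (100 null
seeds, 50 planted seeds) completes in minutes on one CPU while every
fragment-level effect (blind masking, heteroscedastic far-cis counts,
discrete trans counts) is present. The pipeline demo in
`pipeline_defaults()` uses a 460 kb genome and completes in seconds.

Known limitations: the count-ratio FDR needs several true BRICKs before a
1% tier is certifiable (see the resolution bound above); the domainogram
null assumes exchangeable corrected values, so gross uncorrected covariates
(GC, mappability) would need covariate correction upstream; and trans
calling inherits the discreteness of low trans counts — with very low trans
background, trans ranks are tie-dominated and conservative.
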