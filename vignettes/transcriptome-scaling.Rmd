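---
title: "Methods: scaling digital transcriptomes and judging the result"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scaling digital transcriptomes and judging the result}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txscale)
```

## The problem and the model

Digital transcript counting measures each gene relative to the total
sequencing output of its sample. Comparing expression across samples
therefore requires a per-sample scaling factor `f_k`; every method in this
package except quantile normalization is of this form, multiplying all of
sample `k` by one positive number. A factor set is only meaningful up to a
common constant, so we canonicalize to `prod(f_k) = 1` by dividing by the
geometric mean (`adjust_factors()`). This keeps the global scale of the
data set, preserves all factor ratios exactly, and is idempotent.

The scientific assumption behind the data-driven methods is that a large
*core* of genes is expressed in a mutually consistent pattern across
samples, even across very different tissues. If such a core exists, genes
belonging to it are (a) nonzero everywhere, (b) never at extreme ranks in
any sample, and (c) approximately proportional to one another across
samples. The package operationalizes (a)+(b) as *ubiquitous genes* and (c)
as the ratio-dispersal network of NCS. The alternative hypothesis — that
most genes are differentially regulated and no stable core exists — would
show up as a small, unstable set of uniform genes; the methods here would
then disagree with one another rather than converge.

## Gene selection

`trimmed_set()` ranks the nonzero genes of one sample ascending (ties
broken by gene id for determinism) and keeps ranks `r` with
`lower * n < r <= upper * n`. This rank convention is exactly testable and
reproduces "30th to 85th percentile" for the default band (0.30, 0.85).
The wide band (0.05, 0.95) feeds the Stability and NCS pools, which
benefit from more candidates and are less sensitive to extreme genes.
Whether percentile boundaries are inclusive at both ends is a genuinely
open convention; we chose half-open `( , ]` once and use it everywhere.

`ubiquitous_genes()` intersects the trimmed sets of all samples. The
intersection can legitimately be empty; callers may relax membership to a
fraction of samples (e.g. 0.8), but the package never relaxes silently —
only `normalize_ncs()` retries at 0.8 by itself, with a message, because
the pool is an internal stage there rather than a user-visible result.

*Specific* genes (one sample strictly above the sum of all others, nonzero
in at least half the samples) are reported as a companion statistic:
successful scaling should not manufacture them.

## The scaling methods: parameters that matter

* `normalize_percentile(q)`: `q = 0.75` (upper quartile) and `0.90` (upper
  decile) are the standard choices. The percentile is the nearest-rank
  value of the ascending sorted column — deterministic, no interpolation —
  and the target is the arithmetic mean of the per-sample values, the most
  literal reading of "the average across all samples". A zero percentile
  value is a hard error suggesting `nonzero_only = TRUE`, because sparse
  matrices make low quantiles meaningless.
* `normalize_guide()` combines guides by a *weighted* geometric mean
  `exp(sum(W ln Y) / sum(W))`. With equal weights this is the classic
  geNorm combination; the weighted form degrades gracefully and is
  scale-equivariant, which is why the same code serves housekeeping,
  geNorm, Stability, Random-Ubiquitous and NCS.
* `genorm_select()` uses the cited gene-stability measure (mean of
  standard deviations of pairwise log2 ratios) with iterative exclusion —
  quadratic cost, intended for candidate panels of ~10 genes.
  `stability_select()` replaces the iteration with a single pass against a
  seeded 100-gene reference subsample so that pools of thousands of genes
  stay linear; the selected genes are the `n = 100` lowest-`M`.
* `normalize_tmm(reference, trim_m = 0.30, trim_a = 0.05)`: the trim
  fractions are removed from *each* end of the `M` and `A` distributions.
  Logs are natural; the weighted mean of `M` is base-invariant, so the
  base is a pure implementation detail. Weights are inverse delta-method
  variances `(N_k - Y_gk)/(N_k Y_gk) + (N_r - Y_gr)/(N_r Y_gr)`;
  real-valued coverage is accepted as pseudo-counts. Fewer than 3
  surviving genes is a degenerate-input error.
* `normalize_quantile()`: zeros participate in the ranking, so a gene that
  is zero in one sample may become nonzero — a documented consequence of
  normalizing whole columns. Ties within a column receive the average of
  the rank-means they span, so equal inputs map to equal outputs; note
  this means the *sorted* column vectors are identical across samples only
  when tie patterns agree (always true for tie-free data). The grand sum
  is conserved exactly either way.

## Network Centrality Scaling

Stage defaults: wide trim (0.05, 0.95); pool capped at the `pool_cap =
2000` highest-geometric-mean genes (the pairwise stage is quadratic);
dispersal cutoff `d_cutoff = 1`, i.e. a pair is admitted when its largest
per-sample expression ratio is at most twice its smallest, giving edge
weights `sim = 1/(1+D)` in `(0.5, 1]`; PageRank damping 0.85 (the classic
default), L1 tolerance `1e-9`, at most 1000 iterations with
non-convergence an error. The undirected network is realized as symmetric
directed edges with weight-proportional transition probabilities; nodes
without edges are dangling and their mass is redistributed uniformly, so
PageRank sums to 1 exactly.

The combination step deserves a flag: the per-sample factor is defined
here as the equalizer of the `W`-weighted geometric mean of the guide
genes (product-1 adjusted). This is the single largest design inference in
the package — it is the unique combination rule consistent with the
geometric-mean convention of every other guide-based method, and it makes
NCS with all-equal weights coincide with All-Ubiquitous scaling. A
perfectly symmetric network (every pair exactly proportional, as in
noise-free simulations) gives every node the uniform centrality `1/G`, so
all weights `W = PR * G - 1` clamp to zero; `normalize_ncs()` then falls
back to equal weights over the pool, with a message, since in that case
every pool gene is an equally good guide.

## Evolution Strategy

Fitness is the number of uniform genes (CoV < `cov_cutoff`, default 0.25)
after scaling by the candidate vector; it is invariant to a global
rescaling of the vector, which justifies the product-1 canonicalization of
every individual. Mutation multiplies each coordinate by `2^u`,
`u ~ U(-delta, delta)` with `delta = 0.02` — multiplicative, because
factors live on a ratio scale. Recombination is per-coordinate uniform
crossover (the operator is otherwise unconstrained). The population starts
from 10 random vectors plus the identity (so the fitness trace starts at
the unnormalized count), grows by 20 offspring per round in four classes
(5 mutants of the best, 5 of parents ranked 2–10, 5 of the remainder, 5
recombinants), and is truncated stably to 200 — parents and offspring
compete together, ties resolved by insertion order, so the whole
trajectory is bit-reproducible under a seed and the best fitness never
decreases. Convergence is declared after 100 improvement-free rounds; a
wall-clock budget is available for long runs. When the population holds
fewer than 11 individuals the offspring classes collapse gracefully to
sampling whatever ranks exist.

A structural limitation worth stating plainly: a counting objective is
flat wherever no gene's CoV crosses the cutoff. When the data are much
cleaner than the cutoff (per-gene CoVs well below 0.25), *every* factor
vector within a broad neighborhood of the truth yields the same count, and
the search cannot localize factors inside that plateau — the ES then
matches the deterministic methods in fitness but not in factor precision.
The metric discriminates best when many genes sit near the cutoff, which
is the situation in real, biologically noisy transcriptomes. This is a
property of the objective, not of the optimizer; the deterministic
methods (Total-Ubiquitous, Stability, NCS) are the right tools when exact
factor recovery at low noise matters.

## Evaluation metrics

`count_uniform()` uses the `n-1` standard deviation (the denominator is
unspecified in common usage; the sample form is the conservative choice)
and requires a positive mean. The cutoff 0.25 is strict enough to separate
methods without emptying the count; 0.15–0.5 are reasonable sensitivity
checks. `ranking_decorrelation()` Spearman-correlates the sample rankings
induced by gene pairs: 100,000 sampled pairs by default, exact enumeration
automatically when cheaper, ranks with average ties. Genes constant across
samples induce no ranking and are dropped with a message rather than
propagating `NaN`. The decorrelation pool defaults to the wide-trim
ubiquitous set. `compare_factor_sets()` correlates log2 factor vectors
(Pearson), which makes the statistic invariant to the arbitrary global
scale of each solution.

`cutoff_grid_scan()` evaluates Total-Ubiquitous scaling on every cutoff
pair from the grid `{res, 2*res, ..., 1}` with `lower < upper` (at
resolution 0.25 that is 6 combinations; at the default 0.05, 190). The
choice to pin grid points at multiples of the resolution, excluding a
zero lower cut, keeps the grid finite and contains the default band
(0.30, 0.85) as an interior point.

## The synthetic generator

`simulate_expression()` builds the structure the methods assume, with full
ground truth: core genes as a shared log-normal profile (log2 mean 4, sd
2 — several orders of magnitude, as real transcriptomes show) times the
sample factor times `2^N(0, sigma)` noise; specific genes with a constant
baseline and one owner sample at `specific_ratio = 3` times the summed
baseline of the others (so they pass the specificity test after correct
normalization), owners drawn with Zipf(1) weights so that specific-gene
mass concentrates in a few samples — the configuration under which
total-count scaling fails; and *variable* genes whose per-gene log2
dispersion is drawn log-uniformly on [0.1, 2], emulating the continuum of
gene-level biological variability in real data (from near-core stability
to effectively independent profiles), with 10% dropout zeros. True factors
default to `2^U[-0.5, 0.5)`, commensurate with the mock-normalization
range.

What the generator does *not* emulate: gene-length and GC effects,
count-level sampling noise (values are continuous coverages), correlated
gene modules, and replicate structure. Passing the recovery tests
therefore demonstrates correctness of the estimators under the package's
own data model, not performance on any particular real data set.

The test suite exercises recovery at 16 samples and 2,700 genes (2,000
core + 200 specific + 500 variable, `sigma = 0.05`), a size chosen so the
full suite runs in well under a minute while keeping the pairwise NCS
stage (millions of gene pairs) non-trivial; unit tests use matrices of
tens to hundreds of genes where the oracle computations (dense PageRank
solves, brute-force Spearman ranks) are exact and cheap.

## Degenerate inputs and numerical conventions

Zeros encode absence; `NA` is rejected at the door (`check_expression()`).
All-zero samples, zero percentile values, guide genes with zeros, empty
ubiquitous pools, and all-zero weights raise typed errors naming the
offending gene or sample rather than propagating `NaN`. Ties are broken by
gene id wherever an order matters (trimming, top-expression capping,
quantile sorting), making every deterministic method exactly reproducible;
every stochastic method (mock scaling, random-ubiquitous draws, stability
subsampling, ES, pair sampling) takes an explicit integer seed. The
command-line wrapper runs each subcommand as a single in-memory pipeline;
intermediate results are not cached on disk, since every stage at
practical sizes is a matter of seconds and caching would add a staleness
hazard for no measurable gain.
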