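---
title: "Reference-free tumor cell phylogenetics from k-mer spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-free tumor cell phylogenetics from k-mer spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kmerphylo)
```

## The problem and the model

Single-cell whole-genome sequencing of tumors promises a cell-by-cell view
of clonal evolution, but the dominant mutation class in solid tumors —
segmental copy-number change — is awkward to call by aligning massively
rearranged genomes to a reference. `kmerphylo` sidesteps alignment
entirely. Each cell is summarized by its *k-mer spectrum*: the vector of
counts of every length-`k` DNA word in its reads. If a genomic segment is
present in `c` copies, every k-mer inside it is sequenced roughly `c` times
as often, so differences in normalized k-mer frequencies between two cells
act as a proxy for differences in genome copy-number content, and hence for
evolutionary distance.

The pipeline is: count k-mers per cell; merge into a k-mers × cells count
matrix; correct for noise and normalize; then branch into (a) distance-based
phylogenetics with bootstrap support and a permutation test of class
separation, and (b) supervised feature selection plus cross-validated
classification of cells by progression stage.

## Noise model and matrix preparation

Three noise sources shape the matrix-level corrections:

* **Sequencing error** creates k-mers seen only a handful of times. Entries
  below `min_count` (default 2) are zeroed per sample and k-mers left with
  no support anywhere are dropped. The threshold is deliberately mild:
  an erroneous k-mer must recur to survive, while genuine single-copy
  k-mers at realistic coverage are counted many times.
* **Whole-genome amplification (WGA) unevenness** means a region may
  amplify in one cell and not another. The strict correction keeps only
  k-mers with positive count in *every* cell (`presence_fraction = 1`).
  This preferentially retains amplified and ploidy-shifted regions at the
  cost of truly deleted ones — an accepted bias, since the retained,
  commonly covered fraction of the genome still carries abundant
  copy-number signal. For protocols without WGA, a relaxed
  `presence_fraction < 1` is available.
* **Library duplicates**: cells with byte-identical count vectors are
  detected on the raw counts (exact equality, no tolerance) and all but the
  lexicographically first member of each group dropped.

Sequencing-depth differences are removed by Total Sum Scaling: each count is
divided by its cell's total over the *retained* k-mer set, so TSS runs after
both filters and every column of the abundance matrix sums to 1. Quantile
normalization is deliberately avoided: tumor cells genuinely differ in
genomic content, and forcing identical count distributions would erase
ploidy signal.

## Feature selection

Two stages reduce the retained k-mers to an informative set for
classification:

1. **IQR filter.** Each k-mer's interquartile range of relative abundance
   across cells is computed with the type-7 (linear interpolation) quantile
   convention; k-mers whose IQR falls at or below the first quartile of all
   IQR values are removed — about 25% when IQRs are distinct. Ties at the
   boundary are removed (inclusive rule); if every IQR is identical nothing
   is removed, with a warning, since no feature is less variable than
   another.
2. **Differential abundance.** Every remaining k-mer is tested between the
   two class labels with the two-sided Wilcoxon rank-sum test, and kept when
   its raw p-value is at most `alpha / m` (Bonferroni, default
   `alpha = 0.001`, `m` = k-mers tested). The scalar
   `wilcoxon_rank_sum()` uses the exact null distribution for pooled sizes
   up to 20 without ties and the tie- and continuity-corrected normal
   approximation otherwise. The matrix-scale path in
   `select_differential()` uses the exact distribution whenever both
   classes have fewer than 50 cells and a row has no ties (the
   `wilcox.test()` convention), computed from a single shared CDF. This
   matters numerically: with 20 + 20 cells the normal approximation cannot
   produce two-sided p-values below ~7e-8, so a Bonferroni threshold of
   `0.001 / m` with tens of thousands of k-mers would be unreachable by
   construction, while the exact tail extends to `2 / choose(40, 20)`.

The test is two-sided because differential abundance is directionless here:
either clone may have gained copies.

## Distances, trees, and support

Phylogenies are built from Euclidean distances between TSS-normalized
abundance columns — comparing fractions of the genome occupied by each
k-mer. Distances are computed on the presence-filtered, normalized matrix
*before* differential selection: supervised selection belongs to the
classification branch, and letting class labels shape the tree metric would
bias the very separation the permutation test later assesses
(`--use-selected`/`build_phylogeny()` on a selected matrix remains
possible). Bray-Curtis dissimilarity is provided for ordination-style
surveys; on compositional columns it equals half the L1 distance, and any
embedding tool can consume the resulting matrix.

`neighbor_joining()` implements the Saitou–Nei agglomeration directly. Ties
in the Q-criterion are broken by the lexicographically smallest pair of node
labels (an internal node inherits the smallest leaf label in its cluster),
so results are reproducible; tie handling matters because consensus supports
can shift at ties. Negative branch lengths, which arise on non-additive
input, are kept and flagged; `clamp_negative = TRUE` zeroes them and
transfers the length to the sister edge. On any additive matrix the
implementation recovers the generating tree's topology and path lengths to
1e-9 — the standard correctness oracle, exercised in the test suite against
both path-sum reconstruction and the independent `ape::nj()`.

Split support comes from bootstrapping k-mer features: each replicate
resamples rows with replacement (implemented as multinomial feature weights,
which is the same distribution and lets each Euclidean replicate reduce to
one weighted cross-product), recomputes distances, and rebuilds the tree.
Read-level resampling would require recounting every cell and is not
offered. The consensus keeps splits occurring in more than half the
replicates and, by default, extends greedily with compatible minority splits
in decreasing-support order — the extended majority rule, matching the
default behavior of the classic consensus tools this workflow descends
from. The default of 1,000 replicates estimates a support of 0.95 with a
standard error under 0.007; production analyses on real cell panels
typically raise it to tens of thousands, at linear cost.

## The separation statistic and its permutation test

Given a distance matrix and class labels, the statistic is

\[
T = \frac{\text{mean } d(i,j) \text{ over same-class pairs}}
         {\text{mean } d(i,j) \text{ over different-class pairs}},
\]

pooled over all classes; `T < 1` indicates class cohesion. Averages, not raw
pair sums, are the default: with unequal class sizes only the average form
has a permutation-null center near 1, which is what makes the reported null
means interpretable; the sum variant is available as `method = "sums"` for
comparison experiments. The test shuffles labels uniformly
(default 10,000 times) and reports the one-sided empirical p-value
`(1 + #[null <= observed]) / (1 + n_permutations)`; the add-one convention
means p is never 0 and has a floor of about 1e-4 at 10,000 permutations.
One-sidedness encodes the alternative of interest — cells of the same stage
clustering more tightly than chance.

## Classification harness

The learners are deliberately off-the-shelf — a linear-kernel maximum-margin
classifier (`e1071::svm`) and a CART decision tree (`rpart`), both at
library defaults — because the package's contribution is the feature
pipeline and the evaluation harness, not the classifiers. Folds are
stratified by class (necessary for valid folds under the roughly 3:1
class imbalance typical of primary/metastatic designs) and re-drawn for
each of the default 10 replicates of 10-fold cross-validation; a
replicate's error is the mean of its fold misclassification rates
(fold-averaged, not pooled — the aggregation is stated since the
alternative convention differs slightly with uneven folds).
`balance_by_subsampling()` downsamples the majority class uniformly to the
minority size so accuracy is not inflated by imbalance.

## What the simulator does and does not emulate

`simulate_two_clone_dataset()` and the underlying generator exist so the
whole pipeline is testable without any external download. The model:

* a uniform-random reference partitioned into near-equal segments (default
  100 kb in 20 segments — large enough that 15- to 20-mers are mostly
  unique, small enough for minutes-scale runs);
* clones as integer copy-number vectors over segments, forming a rooted
  clone tree (the standard benchmark uses two clones differing 3-fold on 5
  of 20 segments);
* cell genomes as copy-number-weighted segment concatenations;
* WGA unevenness as a per-cell, per-segment log-normal factor
  `exp(N(0, wga_sigma^2))` multiplying the segment's read-sampling weight.
  The log-normal is an artifact choice (the phenomenon is only described
  qualitatively in the WGA literature as region-specific amplification
  dropout); it is positive, right-skewed, and one parameter. The default
  `wga_sigma = 0.3` gives factors with roughly 30% coefficient of
  variation — strong enough that per-cell coverage of a segment visibly
  varies, weak enough that present-in-all filtering retains a usable core;
* reads of fixed length (default 48 bp) with uniform starts within a
  segment copy, reverse-complemented with probability 0.5, exactly
  `round(coverage × genome_length / read_length)` per cell, and iid
  per-base substitution errors (default 0.005). Default coverage for the
  benchmark is 20× (the package's tests use 10× for speed); qualities are
  constant because no stage consumes them.

Not emulated: PCR chimeras and adapters, indels, structural-variant
breakpoint reads, quality-score structure, GC bias, or reference repeats.
Passing tests therefore demonstrate correct behavior of the statistical
machinery under a clean copy-number-plus-WGA-noise model, not robustness to
every artifact of real single-nucleus libraries; on real data the absolute
filter losses and error rates will differ even though the pipeline's
contracts (bookkeeping, normalization, calibration of the permutation null)
carry over.

## Numerical and degenerate-input choices

* k is limited to 31 by the 2-bit rolling encoder; `kmer_space_size()` is
  exact up to `k = 26` (below 2^53) and errors beyond rather than losing
  precision silently.
* Windows containing any non-ACGT symbol are skipped during counting (the
  simplest rule, and the common behavior of k-mer counters); reverse
  complements are distinct keys unless `canonical = TRUE`.
* A zero-sum sample makes TSS undefined and raises an error naming the
  sample; an all-zero filter result warns.
* `detect_duplicates()` compares raw counts exactly — normalized values
  could collide after rounding.
* Permutation p-values use the add-one convention (never exactly 0);
  statistic preconditions (a within-class pair and a between-class pair
  must exist) are validated.
* NJ ties and negative branches: see above; both are deterministic and
  surfaced rather than hidden.

## Problem sizes used in the tests

The test suite runs entirely on simulated data: a shared small benchmark
(8 kb, 12 cells, k = 9) for fast module tests, and the standard two-clone
benchmark (100 kb, 40 cells, k = 15, 10× coverage, 300 bootstrap
replicates, 10,000 permutations) for the end-to-end checks. These sizes
were chosen so the whole suite completes in minutes while leaving every
statistical margin (support ≥ 0.95, p at the permutation floor, median
cross-validated error ≤ 0.05) comfortably wide at the benchmark's effect
size.

## Known limitations

* The present-in-all filter discards genuinely deleted regions, so losses
  are invisible to the downstream tree; this is inherited from the WGA
  noise model, not incidental.
* Euclidean distance on compositions is a pragmatic proxy, not an
  evolutionary model; branch lengths have no substitution-rate
  interpretation.
* The k-mer counter is in-memory; the intended envelope is desk-scale
  simulated genomes (megabases) and moderate k, not 3-Gb genomes at
  k = 25, which demand disk-backed counters.
* Bonferroni control with exact Wilcoxon tails is conservative; a
  Benjamini–Hochberg switch is provided for exploratory use but is not the
  default.
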