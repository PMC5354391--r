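---
title: "Methods: broad H3K9me2 domain scoring, conserved zones and differential LOCKs"
author: "lockscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: broad H3K9me2 domain scoring, conserved zones and differential LOCKs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lockscape)
```

# The problem

H3K9me2 is a repressive histone mark that organizes into **LOCKs**
(large organized chromatin K9 domains): contiguous blocks from tens of
kilobases to megabases. Unlike punctate marks, LOCKs are compared
between cell types at the *block* level: which territories are
methylated in every sample of a panel, which vary, and which blocks
differ systematically between two biological categories (e.g.
progenitors versus differentiated cells, or normal versus leukemic
cells). lockscape implements that comparison pipeline downstream of
domain calling: the inputs are per-sample *scored domain intervals*
(each with its mean read depth per nucleotide), not reads.

# Window scoring model

The genome is tiled with fixed windows (10 kb for all classification
steps; 50 kb–1 Mb for correlation). A domain `d` with mean depth `c_d`
contributes `c_d` for each of its nucleotides falling in window `w`,
after removal of low-alignability **deadzones**:

```
score(w) = sum_d  c_d * | (d \ deadzones) ∩ w |        [read-count · bp]
```

Three deliberate choices:

* **Raw sums, not per-bp means.** The subsequent mean normalization
  absorbs any constant factor, while summation makes coarsening exact:
  `coarsen(10 kb track, R)` equals direct scoring at resolution `R`
  bit-for-bit (tested against a per-nucleotide oracle). Truncated
  terminal windows therefore carry proportionally smaller raw scores,
  consistent with the nucleotide-wise definition.
* **Deadzones are subtracted from the data**, not modeled: deadzone
  nucleotides contribute nothing, and a window is masked only when it
  has *no* alignable bp. No coverage threshold is invented.
* **Normalization precedes replicate averaging.** Each track is divided
  by the mean of its unmasked scores (mean exactly 1 afterwards, checked
  to 1e-9), then technical replicates are averaged element-wise with
  mask union.

An optional per-sample flag doubles raw chrX/chrY scores for male
samples, for inputs whose domain calling did not already duplicate the
single-copy sex chromosomes; it is off by default because deposited
domain files typically reflect that duplication already.

# Conserved and variable zones

For every 10 kb window, the threshold is `sigma(w)`: the sample standard
deviation (n−1 denominator) of the panel's normalized scores at `w`. A
sample is **high** when its score exceeds `sigma(w)`, otherwise **low**
(`score <= sigma`). A window is

* **GREEN** (conserved low): at most 2 samples high, at most 1 high per
  category;
* **RED** (conserved high): at most 2 samples low, at most 1 low per
  category;
* **YELLOW** otherwise.

The strict comparisons have two consequences we keep and test rather
than hide: a window where all samples agree at any positive value has
`sigma = 0`, everyone "high", hence RED; an all-zero window is GREEN.
Only male samples enter `sigma` and the counts on chrY.

Two genuinely open readings exist for `sigma`: per-window (the literal
reading of a standard deviation *of the window scores*) and one global
value pooled over all windows. Per-window is the default; `sigma_rule =
"global"` selects the alternative. Note a subtlety of the per-window
rule: raising one sample's score at a window also raises `sigma(w)` and
can demote *other* samples from high to low, so labels are not monotone
in a single score. Labels are, however, strictly local to the window —
a property the tests assert.

# Differential LOCKs

For an ordered category pair (c1, c2):

1. **LOCK bases** are found in c1: a contiguous stretch of 10 kb windows
   is a base when every c1 sample has a positive score in ≥ 50% of the
   stretch's windows. Candidate stretches are by default maximal runs of
   unmasked windows in which at least one sample is positive
   (`lock_base_rule = "positive-runs"`): an all-zero window ends a
   candidate, which keeps the decision local and independent of distant
   geometry. The `"stretch"` alternative lets all-zero windows sit
   inside a candidate (they count against the 50% rule, and the
   candidate is kept or rejected whole). We default to the local rule
   because under `"stretch"` a candidate's fate depends on the
   LOCK/gap ratio of an entire masked-window-delimited region, which can
   span megabases.
2. **SLR window scores** on base windows:
   `SLR(w) = (1/N) Σ_{i∈c1, j∈c2} −log(max(s_i(w),ε) / max(s_j(w),ε))`,
   natural log, N the number of pairs. Positive SLR means c2 is higher.
   The floor `ε = 1e-6` (configurable) handles zeros while preserving
   exact antisymmetry under category swap, which the tests assert
   bit-for-bit. On chrX/chrY only same-sex pairs enter the sum; a window
   with no same-sex pair is undefined and excluded, with a warning.
   Using any other log base rescales all scores and thresholds together,
   so the flagged sets are base-invariant (tested).
3. **Segmentation**: within each base, maximal runs of strictly
   same-sign SLR become one dLOCK with `total_score = Σ SLR(w)`.
   Windows with SLR exactly 0 terminate runs and join no dLOCK — with
   the ε floor, two all-zero windows give exactly 0, so domain-free
   stretches inside a base never join a block.
4. **Ranking**: thresholds are type-7 (linear interpolation) sample
   quantiles of the total scores of all non-chrY dLOCKs of the
   comparison, pooled across signs; a positive dLOCK passes level p when
   `total_score > Q(p)`, a negative one when `total_score < Q(1−p)`,
   strict at the threshold. chrY dLOCKs inherit the autosomal
   thresholds. Pooling (rather than per-sign score distributions) is the
   default reading of "the 90th / 10th percentile" applied to one score
   distribution.

The ten standard comparisons run CD34+ and granulocytes against each
other and against AML clusters A and B (assigned in the sample sheet,
reproducing an unsupervised correlation-clustering split that
`hcluster_samples()` can propose), plus the two K562 treatment
directions. Bases always come from the first-listed category, so a
comparison and its reverse share window scores (negated exactly) but not
necessarily coverage.

# Enrichment

Feature densities are binned per window — covered bp for interval
features (overlaps collapsed first), counts for point features, both on
non-deadzone territory — and fold enrichment of a window set is the
set's density over the genome-wide density. By construction the set of
all unmasked windows has fold exactly 1. No significance model is
attached; folds are reported raw.

One statistical consequence matters for recovery experiments: the
genome-wide denominator *contains* the enriched region, so for a factor
`k` planted in a block of `B` bp of a `G` bp genome the raw fold
converges to `k / (1 + (k−1)·B/G)`, not `k`. The experiment helper
reports both the raw fold and the inverted, consistent estimate
`k_hat = fold·(G−B)/(G−fold·B)`.

# The synthetic cohort generator

`simulate_domains()` emulates exactly the statistical structure the
zone and dLOCK statistics assume:

* a **shared LOCK skeleton** (category-shared domain geometry): gaps are
  exponential and LOCK lengths log-uniform between 50 and 500 kb, with
  genome LOCK coverage 0.5 by default — a realistic share for a broad
  repressive mark panel in myeloid cells;
* **multiplicative lognormal depth noise**, one draw per (sample,
  domain) with sd `sigma = 0.25`. Window-level noise within a domain is
  deliberately *not* modeled, because the score pipeline is
  domain-mean-based: every window of a domain shares its sample's draw;
* **planted blocks**: conserved-high (all samples elevated),
  conserved-low gaps (no domains), and differential blocks whose depth
  is multiplied by `exp(delta)` for one category. Planted blocks are
  carved out of the random skeleton with a 20 kb isolation margin so
  each is exactly one domain in every sample — zero-noise closed forms
  (window scores, SLR = delta on the block, 0 elsewhere) then hold to
  machine precision, and recovery is unambiguous to define;
* **deadzones** drawn as random 2–20 kb intervals covering 2% of the
  genome, and **features** placed by a Poisson process with intensity
  `k`-fold higher inside a named block.

Everything derives from one integer seed; identical configs give
byte-identical fixture files (hash-tested).

What the generator does **not** emulate — and hence what green tests do
*not* establish about real data: within-domain score variation and
boundary uncertainty from the upstream domain caller, platform and
batch effects beyond replicate noise, mappability structure beyond
random deadzones, sample-specific domain geometry (all samples share
the skeleton support), and copy-number or ploidy artifacts. The
calibration results below are statements about the statistic under its
own noise model.

# Calibration experiments and problem sizes

`planted_block_experiment()` simulates 3-vs-3 cohorts on a 2 × 50 Mb
genome (≈ 250 LOCKs, so empirical 1% quantiles rest on hundreds of
dLOCK scores), plants one 500 kb block at log-fold `delta = 1`
(`sigma = 0.25`), and asks whether a positive dLOCK flagged at alpha
0.99 covers at least half of the planted bp. Over 200 seeds the
recovery rate is ≥ 95% (99.5% at the default seed) and the mean SLR over
the block estimates `delta` within three standard errors; the residual
≈ 1.7% shortfall is the mean-normalization shift a 500 kb elevated
block induces on a 50 Mb LOCK territory, which shrinks with genome
size.

For the null calibration (`delta = 0`, 500 seeds) the marked block's
length is drawn from the same log-uniform LOCK length distribution, so
it is exchangeable with the skeleton; it then lands in a sign-matched
1% tail at the nominal ≈ 2% rate (two tails), within Monte-Carlo error.

Both ensembles, the 100-seed enrichment recovery, the per-nucleotide
windowing oracle over 100 random ≤ 1 Mb genomes, and the exhaustive
3^6-pattern enumeration of the zone rules run inside the ordinary test
suite; `scripts/acceptance.R` re-runs the headline quantities from
scratch at any seed.

# Numerical and degenerate-input conventions

* Coordinates are 0-based half-open throughout (BED convention); an
  interval abutting a dLOCK end does not overlap it.
* All-zero tracks refuse normalization ("degenerate sample"); an empty
  dLOCK set refuses ranking; fewer than 3 jointly unmasked windows
  refuse a correlation; zero-variance tracks yield NA correlations
  rather than errors.
* Zone labels partition unmasked windows exactly; fractions are
  bp-weighted and sum to 100 within 1e-9.
* Identical distance ties in clustering are broken deterministically by
  ordering tracks lexically by sample id before `hclust`.
* Pipeline stages are idempotent; outputs carry no timestamps, so
  re-runs are byte-identical and hash-comparable, and the run manifest
  records input hashes and output row counts.

# Known limitations

The LOCK-base delimitation and the per-window versus global `sigma` are
genuinely ambiguous points of the method's definition; both readings
are implemented and switchable, and conclusions that depend on the
switch should be checked under both. Fold enrichments carry no confidence
measure. The pipeline consumes domain calls as given: errors of the
upstream domain caller propagate untouched.
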