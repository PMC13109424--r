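---
title: "Mutational-signature stratification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mutational-signature stratification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigstrata)
```

## The problem

Tumor cohorts can be stratified by the mutational processes that shaped
their genomes. Each process leaves a characteristic *signature*: a
probability distribution over mutation *channels* — single-base
substitutions in pyrimidine-normalized form (C>A, C>G, C>T, T>A, T>C,
T>G), annotated with their 5' and 3' flanking bases (96 channels) and,
optionally, a transcription-strand category (288 or 384 channels). A
cohort is summarized as a samples × channels count matrix (the mutation
catalog); signature analysis factorizes it, attributes per-sample
activities, and clusters patients by their signature make-up.

`sigstrata` implements this pipeline end to end for multi-caller somatic
call sets, together with a synthetic-cohort simulator that provides
ground truth for every stage.

## Catalog construction

`classify_sbs()` assigns each substitution its channel. When the
reference base is a purine, the call is reverse-complemented so the
mutated pyrimidine defines the representation; the trinucleotide context
is read on the pyrimidine strand. Strand categories follow the usual
convention: `U` when the pyrimidine lies on the coding (untranscribed)
strand of an overlapping gene, `T` when on the template strand, `B` when
genes on both strands overlap the site, `N` when intergenic. Calls with
ambiguous context (an `N` base, or a contig edge) are excluded from the
catalog and tallied in an `unclassified` ledger, so row sums stay
interpretable. Variant coordinates are 1-based (VCF convention); interval
overlap is computed with `GenomicRanges`.

Schema collapses (`collapse_catalog()`) go from 384 to 288 and/or 96
channels. The 384→288 direction must do something with the `B` category,
which has no slot in the 288 convention; we assign `B` to `N`. This
conserves per-sample totals exactly, which we consider non-negotiable
(the alternative — splitting `B` across `T` and `U` — double-counts or
halves mutations). `B` sites are rare in real annotations, so the choice
is numerically minor; it is still a declared convention rather than an
established one.

Multi-caller call sets are reconciled by `consensus_filter()`: a variant
keyed by (sample, chrom, pos, ref, alt) is retained when at least two
distinct callers report it, and the reported VAFs are averaged
arithmetically.

## Rare-spectrum screening

Joint NMF extraction can ascribe a signature present only in a few
hypermutated samples to the whole cohort (signature bleeding). Before
extraction we therefore screen samples with more than 600 mutations
(strict inequality) on their relative 96-channel spectra: pairwise cosine
similarity, average-linkage hierarchical clustering on the distance
1 − cosine, and a tree cut at a fixed height (default 0.25). Samples in
groups smaller than 5 are flagged rare and removed. The linkage and the
cut criterion are our choices — the number of distinct spectra should be
an outcome of the screen, not an input — and both are exposed in
`run_config()`. A cut at 0.25 means members of a group agree with cosine
≥ 0.75 on average, a loose enough net that genuine process groups stay
together at these burdens. `annotate_groups()` reports each group's best
cosine match against a reference catalog for human review only; removal
is never decided by etiology.

## De novo extraction

`nmf_kl()` factorizes the channels × samples count matrix `V ≈ W H`,
minimizing the generalized Kullback–Leibler divergence — the natural
objective for (approximately Poisson) count data — by multiplicative
updates, which guarantee a non-increasing objective. Initialization is
either nonnegative double SVD (deterministic) or seeded random; columns
of `W` are normalized to sum to one with the compensating scale moved
into `H`. Convergence is declared at a relative objective change below
`tol` (default 1e-6), checked every 10 iterations.

`extract_signatures()` wraps this in the standard consensus scheme: for
each candidate number of signatures k, it runs `n_replicates` fits on
bootstrap-resampled catalogs (each sample's counts redrawn from a
multinomial with its own total — totals conserved, and each sample gets
its own seed stream so results do not depend on sample order), pools the
replicate signature profiles, and partitions them into k clusters by
k-medoids (`cluster::pam`) on 1 − cosine. The renormalized medoids are
the consensus signatures; the partition's mean silhouette width is the
stability of that k. The medoid partitioning makes a separate
replicate-alignment step unnecessary: medoids are already one-per-cluster
representatives. Exposures are refit on the *un-resampled* catalog by
NNLS for determinism, and goodness of fit is the mean per-sample cosine
between observed and reconstructed spectra.

`select_k()` picks the largest k whose stability reaches a floor
(default 0.8) and whose fit improves on the previous candidate by more
than a minimum cosine gain (default 0.01); the smallest candidate is
exempt from the gain rule, and if nothing qualifies the most stable k is
returned with a warning. The two thresholds are package defaults: the
underlying criteria (stability plus sample cosine) are standard, but no
canonical numeric rule exists.

At k = 1 the silhouette is undefined; we report the mean pairwise cosine
of the pooled replicate profiles instead, which plays the same role
(near 1 when a single process explains the data). With a single
replicate, stability is reported as the sentinel 1 with a `degenerate`
attribute.

## Sample clustering and cross-caller consensus

Samples are clustered on relative exposures with K-means
(`kmeans_exposures()`, 50 restarts by default — exposure space is
low-dimensional, so restarts are cheap insurance). The number of clusters
defaults to the chosen number of signatures. Per-caller clusterings are
reconciled by `align_and_intersect()`: labels are aligned to the first
caller by maximum-overlap assignment (a hand-rolled O(n³) Hungarian
solver, exercised against brute-force enumeration in the tests), and
samples whose aligned label agrees across all callers form the stable
set; downstream analyses use only those.

## Reference attribution with CI pruning

Plain NNLS refitting against a large reference catalog over-attributes:
with many candidate profiles, sampling noise is absorbed by whichever
flat-ish signatures are available, and the distortion grows as the
mutation burden shrinks. `attribute_with_ci()` limits this with a
bootstrap pruning rule: the observed spectrum is resampled
multinomially (`n_bootstrap` times, totals conserved), each resample is
refit, and percentile confidence intervals are formed per signature. All
signatures whose interval reaches zero are removed *simultaneously* and
the reduced set refit, iterating until every retained signature's CI
excludes zero; simultaneous removal keeps the procedure deterministic and
order-free, at the cost of being slightly more aggressive than
one-at-a-time elimination. Final CIs are recomputed on the final set.

`benchmark_overattribution()` quantifies the phenomenon: samples are
simulated from uniform-random mixtures of a signature pool *excluding*
one designated signature, and both a plain-NNLS and the CI-pruned fitter
then fit the full pool. The attributed activity of the absent signature,
relative to burden, is the over-attribution. On the package's default
pool the NNLS curve falls monotonically from about 5% of mutations at
burden 50 to about 1% at burden 1000, and the pruned fitter sits strictly
below it everywhere — the motivating observation for using CI pruning in
the first place.

## APOBEC context dissection

Among APOBEC-like mutations (C>T or C>G at TCW), the base two positions
5' of the mutated C separates the two main deaminases: APOBEC3A prefers
YTCA (pyrimidine at −2), APOBEC3B prefers RTCA (purine). `count_tetra()`
reads the −2 base on the pyrimidine strand, consistent with catalog
normalization, and splits only TCA-context mutations (the motifs are
literally YTCA/RTCA); TCT-context APOBEC mutations are tallied in the
total but not split. Mutations whose −2 base falls off the contig are
excluded and counted.

## The synthetic-data generator

The generator is the package's ground-truth instrument, and its defaults
are the study conditions of the analyses above:

* **Spectra.** Signature contributions are drawn uniformly on (0,1) and
  normalized to sum to one (or planted: a cluster's dominant process
  takes a fixed share, default 0.7, the rest split randomly); channel
  probabilities are the weighted sum of the pool profiles; counts are
  drawn multinomially to a fixed burden.
* **Cohort structure.** Four clusters of 50 samples with median burdens
  150 / 350 / 250 / 700 and log-normal spread (sd 0.35 on the log scale)
  emulate a few-hundred-sample cohort with heterogeneous burdens whose
  cluster medians span roughly the range seen in exome cohorts.
* **Pool.** `simulate_signatures()` builds hand-designed profiles
  sketching familiar processes (clock-like C>T at XCG, APOBEC TCW,
  smoking-like C>A, alcohol-associated T>C, near-flat, UV-like,
  MMR-deficient-like), with process-specific transcription-strand
  asymmetry for the stranded schemas (damage-type processes get a
  T-skewed split, replication-linked ones are symmetric). The four
  default planted processes have pairwise cosine below 0.2.
* **Positions.** A synthetic genome (default 10 contigs × 100 kb,
  uniform base composition) carries four non-overlapping genes per
  contig on alternating strands plus one opposite-strand overlapping
  pair, so every (trinucleotide, strand-category) combination has sites.
  Each emitted channel count is realized at uniformly drawn
  context-matching sites. There are no positional hotspots: placement
  exists so the positional stages (context lookup, strand assignment,
  caller reconciliation) are testable, not to model chromatin.
* **Callers.** Three pseudo-callers report each true variant
  independently with sensitivities 0.95/0.92/0.90 and add ~2% uniform
  false calls; reported VAFs are the true Beta(2,5) VAFs plus N(0, 0.02)
  noise. No read-level or alignment simulation.
* **Ledger.** True weights, channel counts, cluster labels, outlier
  flags and emitted variants are recorded exactly; every oracle test
  compares against the ledger.

What passing tests on this generator do **not** show: robustness to
sequencing artifacts, FFPE damage, copy-number-distorted VAFs, regional
mutation-rate covariates, or real caller error profiles — the simulator
has none of these. Results on synthetic cohorts certify the algebra and
the statistical behavior of the methods, not their performance on any
particular real cohort.

## Numerical choices and degenerate inputs

* NNLS is a Lawson–Hanson active-set solver in compiled code
  (RcppArmadillo); attribution loops refit hundreds of thousands of
  bootstrap spectra, so a compiled solver matters.
* Zero-total samples: preserved as zero rows in catalogs, dropped with a
  warning from factorization and cosine screening, skipped in
  attribution.
* CI pruning uses `ci_low ≤ 1e-9` as "interval reaches zero" — NNLS
  returns exact zeros, so this is a numerically safe test.
* Tie-breaks: k-medoids and K-means ties are resolved by their seeded
  implementations; consensus alignment ties resolve to the
  first-best assignment found by the Hungarian sweep.
* Seeding: every randomized stage derives an independent 32-bit stream
  from `(seed, stage-name)`, so stages are reproducible in isolation and
  identical configurations reproduce results bit-for-bit.

## Problem sizes used in the shipped checks

The test-suite and `scripts/acceptance.R` run: a 200-sample 384-channel
cohort (4 planted processes, shares 0.7, burdens 150/350/250/700) with
extraction over k = 2..6 and 8 NMF replicates (max_iter 300, tol 1e-5);
50 three-signature NNLS subproblems at burden 2000 against a
grid-search oracle; 200 two-signature mixtures at burden 1000 with 200
bootstrap resamples for CI calibration; an over-attribution scan over
burdens 50–1000 with 500 samples per burden and 100 bootstrap resamples;
and a 49-sample rare-spectrum screen with 9 planted outliers across 6
artificial spectra. These sizes are the package's chosen benchmark
scales; the defaults in `run_config()` (k 2..10, 30 replicates, 200
bootstraps) remain the recommended settings for real analyses.

## Known limitations

* No indel (ID83) or doublet (DBS) catalogs: indels enter only the
  consensus variant set and the motif tally.
* The 384→288 `B→N` convention and the rare-spectrum tree cut are
  declared package conventions, not community standards.
* KL-NMF finds local optima; replication plus medoid consensus
  mitigates but does not eliminate this.
* The CI-pruning rule controls false-positive attributions; it does not
  correct the downward bias that pruning can introduce for genuinely
  small activities near the detection limit.
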