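---
title: "Quantifying graded T cell activation: the models behind actisig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying graded T cell activation: the models behind actisig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actisig)
```

CD4+ T cells read the strength of T cell receptor (TCR) engagement — set by
both the dose and the affinity of the presented peptide — and translate it
into gene expression and enhancer activity that scale with that strength.
`actisig` implements the quantitative toolkit for studying this behaviour:
an expression-derived **activation axis** and score, a permutation test for
gene-group trends, and a set of enhancer-level analytics including
super-enhancer calling.  This vignette explains each model, the tunable
parameters, and the numerical decisions, in enough detail that a reader can
judge what the package's passing tests do and do not establish.

## The activation axis

The starting point is a genes × samples RPKM matrix collected across an
ordered series of stimulation conditions (an unstimulated reference followed
by conditions of increasing nominal signal strength).  Two observations
motivate the model:

1. Among genes that respond at all, most respond **gradedly**: expression is
   approximately monotone in signal strength.
2. Because all responsive genes ride the same underlying signal, the sample
   cloud is nearly one-dimensional: a single principal component captures
   nearly all between-condition variance.

`filter_variable_genes()` first restricts to responsive genes: the maximum
condition mean must exceed `min_rpkm` (default 10 RPKM) and the ratio of the
extreme condition means must reach `min_fold` (default 2).  The fold
denominator is floored at a pseudo-count of 1 RPKM so genes silent in one
condition remain finite; 1 RPKM sits well below any sensible expression
floor, so the floor only rescues zeros and never changes a call among
expressed genes.  Replicates are collapsed to condition means *before* the
rules apply, so the filter sees biology rather than replicate noise.

`fit_pc1()` computes the first principal component with **samples as
observations and genes as features**.  Genes are mean-centered but not
scaled to unit variance: the RPKM scale carries the effect-size information
the axis is supposed to capture, and variance-scaling would let thousands of
near-flat genes dilute it.  (A `scale = TRUE` switch exists for
sensitivity analyses.)  The loadings are the unit-norm first right-singular
vector of the centered matrix; sample scores are the projection onto it, and
`variance_explained` is the share of total variance along the axis.  Since a
singular direction has arbitrary sign, the sign is fixed by a biological
convention: the reference condition's mean score must not exceed the
highest-signal condition's mean score, so larger scores always mean more
activated.

## Deriving a replicate-consistent signature

The extreme deciles of the PC1 loadings — genes pushing samples up or down
the axis hardest — form the **activation signature**.  `derive_signature()`
makes the sets robust in three ways:

* PC1 is fitted separately on each replicate dataset and on the combined
  dataset, and a gene must fall in the same extreme fraction in **every**
  fit;
* genes weakly expressed in the reference condition (mean below
  `min_ref_rpkm = 100` RPKM) are removed — their fold changes are dominated
  by shot noise;
* genes whose reference-condition level varies across replicate datasets by
  more than `max_ref_cv = 20%` of its mean are removed as irreproducible.

One design point deserves a note.  The extreme-fraction cut could be sized
either on the full fitted gene list or on the post-filter list.  We size the
rank window on the **full fitted universe** and let the filters veto
membership afterwards.  The alternative couples the two steps: every gene
the reference filters drop shrinks the rank window for all remaining genes,
so the signature loses members that were, by loading rank, unambiguous —
with a 10% window, the achievable coverage of a gene class occupying 10% of
the matrix drops below 90% by construction, before any noise enters.  The
decoupled reading keeps "top 10%" meaning "loading above the 90th
percentile of the fitted genes" regardless of how aggressive the
reproducibility filters are.  When no gene is filtered the two readings are
identical.

Ties in loadings are broken lexicographically by gene id, so derivation is
fully deterministic.  An empty intersection is a warning, not an error: on
weakly structured data the honest answer is an empty signature.

## The activation score

`score_samples()` projects new samples onto the signature model: expression
is restricted to the model's genes, mean-centered gene-wise, and dotted
with the loadings; dividing by the maximum absolute raw score maps the
scores into $[-1, 1]$ with the most extreme sample at $\pm 1$.

Centering defaults to the gene-wise mean **of the samples being scored**
rather than the training means.  The score is routinely applied to external
datasets — other platforms, other laboratories — where absolute levels are
not comparable to the training matrix; centering within the scored set makes
the score a within-experiment ranking, which is also why
`rank_experiment_groups()` refuses cross-experiment comparisons.  Training
means remain available via `center = "model"`, and `center = "none"`
supports pre-centered input.  Signature genes missing from a scored matrix
are dropped, never imputed; scoring errors out when fewer than half of the
model genes are present, since a heavily truncated dot product changes
meaning silently.

## Permutation test for group trends

Is the mean change of a gene group between two conditions larger than a
randomly composed group of the same size would show?
`permutation_trend_test()` computes the per-gene difference of condition
means, averages it over the group, and compares that statistic with its
distribution over `n_permutations` random gene sets drawn **without
replacement** from the matrix universe (sets of distinct genes, matching
how a gene group is composed).  A normal distribution is fitted to the null
and the two-tailed tail area $2\Phi(-|z|)$ is reported, floored at machine
precision; the empirical permutation rank p-value is reported alongside.
The normal approximation is what allows p-values far below $1/n_{\rm perm}$
for strongly trending groups; its cost is accuracy on tiny universes, where
our tests bound the deviation from exact enumeration at about 0.1.  If the
null has zero spread and the observed statistic equals the null mean (the
group *is* the universe), the test degenerates gracefully to $z = 0, p = 1$;
any other zero-spread null is an error.

## Enhancer analytics

All coordinates are BED-convention (0-based, half-open) and all tag counts
are assumed depth-normalized on entry (`tags_per_ten_million()` rescales raw
counts when needed).  Numerical conventions, chosen once and applied
everywhere:

* **Overlap** means at least one shared base pair, in half-open arithmetic.
* **Thresholding** at `min_tags = 40` is inclusive ("at least 40").
* **Fold-change** labels use a strict inequality ("more than two-fold") on
  pseudocounted ratios (`pseudocount = 1` normalized tag guards zero
  denominators).
* **Promoter windows** are TSS ± 1,000 bp; **gene-body spreading** compares
  tag *density* in the strand-aware window TSS+1,000..TSS+4,000 bp against
  the promoter window, so uniform coverage gives exactly 1 and the ratio is
  invariant to sequencing depth.  An empty promoter window falls back to a
  pseudo-density of $10^{-6}$ tags/bp with a warning.
* **Nearest-gene assignment** uses peak-midpoint to TSS distance; exact
  ties go to the smaller TSS coordinate so results are reproducible.
* **Proximity enrichment** is a Pearson chi-squared on the 2×2 table
  (peak in subset?) × (nearest gene in signature?), one degree of freedom,
  no continuity correction; expected cells below 1 raise an error rather
  than a fragile statistic.

The digital/analog classifier (`classify_digital_analog()`) separates
all-or-none induction from graded response in a sorted-cell series: digital
requires the weakest treated condition to reach `induction_fold = 4` times
the reference with a treated-condition CV of at most 0.15; analog requires
strictly monotone treated means spanning at least two-fold.  These two
thresholds are package defaults — the source analyses never published exact
membership rules for the all-or-none cluster — and are exposed as arguments.

## Super-enhancer calling

`stitch_peaks()` merges peaks within `stitch_distance = 12,500` bp
(transitively, inclusive boundary) and sums constituent tags exactly.
Regions are ranked by total tag count, and the super-enhancer cutoff is the
point where **the tangent to the min–max-normalized rank-score curve has
slope one**.

We locate that point through its support-line characterization: after
normalizing both axes to $[0,1]$, the tangency point of a slope-1 line on a
convex increasing curve is exactly the minimizer of $y - x$.  This form is
preferred over local slope estimates because it is global: finite
differences on a sorted-score curve measure spacings between order
statistics, which are dominated by sampling noise precisely in the sparse
upper tail where the decision is made, whereas the argmin of $y - x$
depends only on the curve's large-scale geometry.  On $y = x^k$ the rule
lands within one rank of the analytic tangent point
$x^\ast = (1/k)^{1/(k-1)}$; on an exactly linear curve ($y - x \equiv 0$,
ties resolved to the highest rank) it calls nothing, and a single outlier
above a flat background is called alone.  Regions whose score strictly
exceeds the threshold score are flagged super.  The windowed
centered-difference slope is still computed and returned in the `curve`
table for diagnostics and plotting.

Two calls are compared (`compare_se_sets()`) by ≥1 bp overlap of their
super regions, with counts reported from both sides since overlap is not
one-to-one.  `se_group_gain()` then asks whether shared super-enhancers
near signature genes gain more tags upon stimulation than the rest,
refusing the t comparison when a split has fewer than two regions.

## What the synthetic data emulates — and what it does not

`simulate_expression()` generates the study conditions: five conditions
with signal strengths $(0, 0.45, 0.55, 0.6, 1)$ — the two middle conditions
nearly tied, mimicking a low-dose/high-affinity versus high-dose/low-affinity
pair of near-identical potency — with 10% graded-up, 10% graded-down, 5%
all-or-none and 75% unresponsive genes.  Graded means follow
$b\,(1 + (e-1)s_c)$; the all-or-none class jumps from baseline to
$b \cdot e$ in every treated condition.  Baselines are log-normal
(median 300 RPKM, $\sigma_{\log} = 0.4$) for expressed classes — signature
derivation presumes robust reference expression, and the 100-RPKM reference
filter would otherwise be the binding constraint rather than the biology —
while all-or-none genes draw low baselines (median 20 RPKM), matching genes
near-silent before stimulation.  Effect sizes are Uniform(2, 8): two-fold is
the conventional responsiveness floor and order-of-magnitude inductions are
typical of strong activation genes.  Noise is multiplicative log-normal
with CV 0.10, the scale of replicate scatter in well-controlled bulk
RNA-seq; expression is positive and heteroscedastic, which an additive
Gaussian would misrepresent.  With `noise_cv = 0` the matrix equals its
closed-form means exactly, which the tests exploit.

`simulate_peaks()` plants three kinds of structure on a three-chromosome
assembly: background peaks with tags shared across conditions up to noise,
a subset multiplied by a known fold in the stimulated condition, and
super-enhancer clusters of ten high-tag peaks within 8 kb.  Background tags
are a light-tailed gamma (mean 100, shape 50) and background peaks are
placed beyond stitching range of each other and of the planted clusters, so
region-level ground truth is unambiguous: each background peak is its own
region and each planted cluster stitches into exactly one.

These choices are deliberately idealized, and passing tests should be read
accordingly.  Real tag distributions are heavy-tailed; there the rank-score
elbow falls **inside** the continuum of strong enhancers, the "shared
versus gained" division is fuzzier, and super-enhancer counts depend
visibly on the stitching distance.  The expression generator plants
population-level patterns only: it does not simulate per-cell responder
frequencies, the bimodality of activation markers, batch or platform
effects, or count-level (negative-binomial) noise at low expression.  A
method that recovers planted structure here has demonstrated correctness of
its computation, not robustness to every pathology of real data.

All generators are pure functions of their parameters and a seed (a single
RNG stream per call, no global state), so every downstream result in the
package's tests is reproducible byte-for-byte.

## Problem sizes and test design

The test-suite checks run at sizes chosen to make the statistical
assertions sharp while keeping the whole suite quick on a laptop: the axis
recovery property uses 3,000-gene matrices across 100 seeds; signature
recovery 20 seeds; null calibration 1,000 random groups at 400
permutations each; the interval-engine equivalence 1,000 random intervals
across three chromosomes against an $O(nm)$ brute-force oracle; and
super-enhancer recovery 2,000 background peaks with 20 planted clusters.
The acceptance script (`scripts/acceptance.R`) recomputes the same
quantities from scratch at comparable sizes.

## Known limitations

* The activation score is a **within-experiment** ranking; absolute values
  are not comparable across experiments, and the API enforces separate
  invocations rather than offering a cross-experiment mode.
* Signature derivation assumes a shared gene universe across replicate
  datasets; no imputation is attempted.
* The permutation null randomizes gene identity, not inter-gene
  correlation; for strongly co-expressed groups the null is
  anti-conservative, a property shared by all competitive gene-set tests of
  this form.
* Tag libraries are accepted as positions/counts or per-base coverage; the
  package does not read alignments, call peaks, or subtract input — those
  belong to upstream tools.
* `find_se_threshold()` presumes an overall convex rank-score curve (true
  of tag-total rankings); on non-convex curves the support-line form picks
  the global tangency, which may not match a local slope-1 crossing.
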