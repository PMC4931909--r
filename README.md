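# actisig

Activation-signature scoring and enhancer analytics for CD4+ T cell
stimulation series.

## The problem

CD4+ T cells respond to T cell receptor (TCR) engagement whose strength is
set jointly by the dose and the affinity of the presented peptide.  At the
population level, the expression of a large set of genes rises (or falls)
*gradedly* with that signal strength, and enhancer acetylation follows the
same gradient on a largely pre-established enhancer landscape.  `actisig`
is for researchers who have bulk RPKM matrices and/or normalized ChIP-seq
tag tables across an ordered stimulation series and want to:

* derive the one-dimensional **activation axis** that orders samples by
  TCR signal strength, and the signature gene sets at its extremes;
* **score and rank** arbitrary CD4+ T cell samples (including external
  datasets) by activation state on a \[-1, 1\] scale;
* test whether a gene group's expression **trend** between two conditions
  beats a permutation-constructed null;
* analyse enhancer landscapes: peak-overlap tables at a tag floor,
  activation fold-change classes, tag aggregation at binding sites (e.g.
  AP-1), promoter-to-gene-body spreading of H3K4me2, promoter-window
  binding frequencies, nearest-gene proximity enrichment, and
  **super-enhancer calling** by the rank-score tangent threshold.

A synthetic-data module generates expression matrices and peak landscapes
with full ground truth (planted graded/all-or-none genes, planted gained
peaks and super-enhancer clusters), so the whole pipeline is testable
without any external download.

## The core model

Let $X$ be the genes × samples RPKM matrix restricted to variable genes
(max condition mean > 10 RPKM and ≥ 2-fold between extreme condition
means).  With gene-wise centering $\tilde X = X - \bar x$, the activation
axis is the first right-singular direction $w$ of $\tilde X^\top$ (samples
as observations), and a sample $j$ scores

$$ s_j = \tilde x_j \cdot w, \qquad \text{scaled}_j = s_j / \max_k |s_k| \in [-1, 1]. $$

Signature sets are the extreme deciles of $w$, kept only when a gene lands
in the same decile in every replicate fit and survives
reference-expression filters (reference mean ≥ 100 RPKM; cross-replicate
reference SD ≤ 20% of the mean).  Group trends are tested by comparing the
group's mean condition difference with a normal fit to the same statistic
over random gene sets.  Super-enhancers are called by stitching peaks
within 12.5 kb, ranking regions by normalized tag total, and thresholding
where the tangent to the min–max-normalized rank-score curve has slope 1
(located as the minimizer of $y - x$).  See
`vignettes/activation-signature.Rmd` for assumptions, parameters and
numerical choices.

## Worked example

```r
library(actisig)

# A 3,000-gene stimulation series: 5 conditions, 2 replicates, planted truth
sim <- simulate_expression(n_genes = 3000, seed = 42)

# Derive the replicate-consistent activation signature
reps <- split_replicates(sim$expr, sim$sample_info)
sig  <- derive_signature(reps, sim$expr, sim$sample_info)
sig
#> <signature_model>
#>   genes: 2695   samples: 10
#>   PC1 variance explained: 0.9375
#>   reference condition: C1
#>   signature sets: 280 top / 276 bottom (fraction 0.1)

# Score the samples on the activation axis
score_samples(sim$expr, sig)
#> # A tibble: 10 x 4
#>   sample raw_score scaled_score  rank
#>   <chr>      <dbl>        <dbl> <int>
#> 1 C1_r1    -18460.       -0.990     9
#> 2 C1_r2    -18642.       -1        10
#> 3 C2_r1     -2707.       -0.145     7
#> 4 C2_r2     -2746.       -0.147     8
#> # i 6 more rows

# Does the top signature set trend upward more than random gene groups?
permutation_trend_test(sim$expr, sim$sample_info, sig$top_set,
                       "C1", "C5", n_permutations = 5000, seed = 7)
#> <perm_trend_test>
#>   observed mean difference (C5 - C1): 1352
#>   null: mean 10.2, sd 38.45 over 5000 permutations
#>   z = 34.895, two-tailed p = 8.93e-267 (empirical 0.0002)

# Super-enhancer calling on a synthetic landscape with 20 planted clusters
pk <- simulate_peaks(n_gain = 0, seed = 42)
call_super_enhancers(pk$peaks, "stimulated")
#> <se_call>
#>   condition: stimulated
#>   regions: 2020   super-enhancers: 21
#>   threshold score: 152.2 (rank 21)
```

The `2695` fitted genes are those shared across datasets; the variance
explained (`0.94`) says the ten samples are essentially one-dimensional;
the scaled scores order the five conditions by planted signal strength with
the reference at −1.  The trend test's `z = 34.9` means the signature
set's average rise from `C1` to `C5` sits ~35 null standard deviations
above randomly composed gene groups (the empirical p is floored at
1/(n+1); the normal fit is what resolves smaller tails).  The
super-enhancer call flags 21 regions, which here cover all 20 planted
clusters.

Fitted objects follow broom conventions (`tidy()`, `glance()`) and have
`autoplot()` methods (score-by-condition plot, rank-score curve,
permutation-null histogram); `plot_gene_trends()` draws the classic
normalized-expression trend fan.  A thin command-line front end over the
same functions ships in `inst/cli/actisig.R` (subcommands
`simulate expression|peaks`, `signature derive|score`, `trend test`,
`enhancer overlap|foldchange|aggregate|spreading|proximity`,
`se call|compare`), writing result TSVs plus a JSON run manifest; reruns
with the same seed are byte-identical.

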