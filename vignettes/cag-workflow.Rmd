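---
title: "Co-abundance group analysis of matched microbiome cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-abundance group analysis of matched microbiome cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cagnet)
```

## The problem

Gut bacteria do not vary independently: groups of genera rise and fall
together across people, reflecting shared ecological niches and cross-feeding.
A *co-abundance group* (CAG) is a cluster of genera whose relative abundances
covary across samples. cagnet implements a complete matched case-control
workflow around this idea, as used in 16S studies of irritable bowel syndrome
(IBS) subtypes: build fully paired disease/control cohorts, cluster the genus
correlation structure into CAGs, test CAGs for differential abundance, relate
CAGs to predicted metabolic pathways, and screen discriminative CAGs with a
random forest plus Shapley attribution.

Every stage can be driven either by real tables (genus relative abundances,
sample metadata, optionally a predicted-pathway table with a category map) or
by the bundled synthetic generator, which plants known CAG structure so each
stage is testable without any sequencing data.

## Cohort matching

Matching covariates (age, BMI, height, weight, sex, alcohol frequency, five
dietary frequencies) are encoded numerically (sex: female = 0, male = 1;
frequency scales 0–4), then centered and scaled to mean 0 and variance 1 over
the pooled case+control sample (sample standard deviation, $n-1$). One-to-one
matching minimizes Euclidean distance in this standardized space:

$$ d(i,j) = \sqrt{\sum_k (x_{ik} - y_{jk})^2}. $$

Two algorithms are provided. The default, `"optimal"`, solves the linear
assignment problem with a shortest-augmenting-path (Hungarian) solver and
minimizes total matched distance; `"greedy"` repeatedly takes the globally
closest remaining pair (ties broken by lowest case index, then lowest control
index), mirroring common ad hoc matching scripts. Optimal matching never has
a larger total distance than greedy, and with a surplus control pool it
demonstrably reduces planted covariate imbalance; with an exactly 1:1 pool no
pairing can change group means, so balance restoration requires surplus
candidates — this is a property of the design, not of the algorithm. Balance
is reported as standardized mean differences and paired *t*-tests per
covariate, plus a one-way ANOVA across case subtypes when several subtypes
are present.

## CAG construction

Genera are first filtered: raw count tables drop features that are present in
fewer than 30 samples *and* carry fewer than 10 reads in total (a feature
passing either threshold is kept; the opposite, OR-exclusion, reading is
available via `rule = "or"` and is echoed in the filter log). Relative
abundance tables then keep genera present in at least 20% of samples with
mean relative abundance at least 0.05%. Survivors are deliberately *not*
re-closed to sum 1, so downstream statistics operate on the original scale.

Within each cohort group, all genus pairs are Spearman-correlated, p-values
are Benjamini–Hochberg adjusted over the full set of pairs, and network edges
retain pairs with $q < 0.05$ and $\rho > 0.4$ (positive-only by default,
matching displays that show only positive co-abundance; `positive_only =
FALSE` switches to $|\rho| > 0.4$).

CAGs come from Ward clustering (Ward.D2) of $d = 1 - \rho$ on the *pooled*
case+control Spearman matrix, cut at $k = 8$. Two choices here were genuinely
open and are worth making explicit:

* **Pooled vs per-group clustering.** The partition must be shared between
  groups for any between-group CAG comparison to make sense, so the pooled
  matrix is clustered; per-group networks use the same partition.
* **Unthresholded input.** The 0.4 edge rule applies to network edges only.
  Ward linkage on a thresholded (hence partially missing) distance matrix is
  ill-defined, so clustering uses the full correlation matrix.

The expected 2–10 genera per CAG is treated as a quality report: sizes
outside the bounds are flagged, never silently re-clustered, because no
principled re-clustering rule exists.

Per-CAG differential abundance uses the mean member-genus abundance per
sample and a two-sided Wilcoxon rank-sum test per CAG, with stars at
0.05/0.01/0.001/0.0001. Cross-subtype genus overlaps are summarized as full
Venn region counts.

## Pathway association

Predicted pathway tables (e.g. MetaCyc pathway abundances predicted from 16S
profiles) are related to genera by Spearman correlation of every genus ×
pathway pair; the bipartite network keeps $|\rho| > 0.2$ with sign. For the
per-(CAG, category) contrasts, the *unthresholded* correlation values of all
member-genus × category-pathway pairs enter a two-sided Wilcoxon rank-sum
test of disease vs control. Thresholding inside cells would give the two
groups unequal, selection-biased vectors, so the 0.2 rule affects only the
displayed network. No multiplicity correction is applied across cells by
default (per-cell stars are reported raw); a BH-across-cells switch exists.

Focal pathway groups — acetate, propionate and butyrate biosynthesis
(short-chain fatty acids), LPS-associated, tryptophan-associated — are tested
by summing member-pathway abundances per sample, forming case-minus-control
differences over matched pairs, and applying a paired *t*-test. Summation is
the additive-abundance reading; a per-pathway mode is available. An empty
bipartite network (no $|\rho| > 0.2$ anywhere, which does occur in real
subtypes) is a valid outcome and flows through without special-casing.

## Classifier and Shapley attribution

CAG-summed abundances feed a 500-tree random forest on a stratified 70/30
split (per class, $\lfloor 0.7\,n \rfloor$ training samples). Reported
metrics: confusion-matrix accuracy/sensitivity/specificity at probability
threshold 0.5, the empirical ROC with its rank-based AUC (computed on
test-set scores only), mean-decrease-Gini importance, and stratified 10-fold
cross-validated accuracy on the training set. All other forest
hyperparameters stay at randomForest defaults and are echoed in the result.

Shapley values are estimated from scratch by Monte-Carlo permutation
sampling: for each explained instance, each of 50 random feature
permutations is combined with a random background (training) row into a
chain of hybrids, and feature $j$'s contribution is the prediction
difference between consecutive hybrids. Per-permutation totals telescope to
$f(x) - f(z)$, so

$$ \sum_j \phi_j = f(x) - \text{baseline} $$

holds up to Monte-Carlo error, which is reported per feature and per
instance; the package asserts the identity within four combined standard
errors. A constant model yields exact zeros and an ignored feature gets an
exactly zero attribution, because hybrids differing only in that feature
produce identical predictions. The "sample size" of the attribution protocol
is interpreted as the number of Monte-Carlo permutations per instance (50);
both the permutation count and the number of explained instances (100) are
configurable.

## The synthetic generator

`sim_config()` defines the emulated study; `simulate_study()` draws it. The
generative model is a Gaussian copula with log-normal marginals:

1. a latent multivariate normal with block covariance — correlation
   `within_block_rho` inside each planted block, `between_block_rho` (default
   0) across blocks, background genera independent;
2. exponentiation with per-genus base log-abundance $\mu_g \sim N(0, 1.2^2)$,
   giving the dominance structure typical of genus tables;
3. multiplicative case effects $e^{\text{effect}}$ on effect-block genera,
   applied *before* compositional closure, so closure induces a small
   negative spillover on all other genera (kept, and worth remembering when
   reading differential results);
4. per-sample closure to sum 1.

Because Spearman correlation is invariant to monotone transforms, the
realized rank correlation tracks the latent Pearson value, slightly below it
($6/\pi \cdot \arcsin(\rho/2)$ for a bivariate normal; 0.79 at latent 0.8).
Compositional closure pulls it down a little further, noticeably so when the
table has only a handful of genera — with a few dozen genera, as in the
defaults, the distortion is small.

Defaults emulate the diarrhea-predominant sub-cohort: 365 cases, a 2:1
candidate pool of 730 controls (matching selects 365, and the pipeline
analyzes matched samples only), 44 genera in 8 blocks of sizes 9..2
(within the 2–10 band), latent within-block correlation 0.8, and log-fold
effects $-0.5, -0.5, +0.5$ on blocks 1–3 — moderate effects that give a
clearly significant Wilcoxon signal but only moderate single-split
discriminability, which is the interesting regime for the classifier stage.
Covariates plant a mild imbalance (age +0.3 SD, BMI +0.2 SD in cases) for
the matching stage to reduce. The pathway layer is a nonnegative linear map
of genus abundances (`abundance %*% contribution`, weight density 0.15) times
multiplicative log-normal noise (sd 0.3), with categories assigned
round-robin from the six standard metabolic classes and focal groups carved
from the leading pathway ids.

One master seed feeds named substreams (table / metadata / pathways / match /
rf / shap), so any table can be regenerated independently and full runs are
byte-identical under a fixed configuration.

What the generator does *not* emulate: zero inflation and sequencing
sparsity, taxonomic assignment error, read-depth variation, and any real
pathway ontology. Passing tests therefore demonstrate correctness of the
statistical machinery under a known compositional model with planted
structure — not robustness to every artifact of real 16S data.

## Numerical and degenerate-input policy

* Constant vectors make rank correlations undefined; the result carries an
  explicit undefined marker, never a silent zero.
* Wilcoxon p-values are exact (full enumeration) when the combined sample
  size is at most 12 with no ties, otherwise normal approximation with tie
  and continuity correction; the route taken is recorded. All-tied data give
  $p = 1$ with a note.
* Paired *t* on zero-variance differences and ANOVA on degenerate groups
  return undefined markers.
* Ward clustering is deterministic; ties in the greedy matcher break by
  lowest case then control index; the assignment solver resolves cost ties
  to the lowest column index.
* Single-pair association cells (1 genus × 1 pathway) cannot carry a rank
  test and are marked undefined; cells with no members are marked empty.

## Problem sizes used in the test suite

The packaged checks run the clustering-recovery study at 8 planted blocks
(sizes 2–10), latent correlation 0.8 and 400 samples per group over 20
seeds; matching against exhaustive search on 100 instances of up to 7×7;
Wilcoxon type-I calibration on 10,000 null draws of 30 vs 30; cell-test
calibration on 1,000 simulated studies of 40 vs 40 samples; BH
false-discovery control on 10,000 vectors of 100 nulls; classifier null
calibration on 100 seeded forests; and one full-protocol end-to-end run
(365 matched pairs, 500 trees, 10-fold CV, 100 × 50 Shapley). These sizes
were chosen so each property is measured with comfortable Monte-Carlo margin
while the whole suite stays quick on a laptop.

## Limitations

Spearman networks are not compositionality-aware (no SparCC/SPIEC-EASI
style correction) — by design, to mirror the plain-Spearman workflow this
package implements. The per-cell Wilcoxon contrasts compare dependent
correlation estimates within a cell; the global-null calibration of this
construction is verified by simulation in the test suite rather than assumed
from theory. Shapley estimates are Monte-Carlo, not exact TreeSHAP, and
their error decreases only as $1/\sqrt{\text{permutations}}$.
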