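# cagnet

Co-abundance group (CAG) analysis for matched case-control gut-microbiome
cohorts.

Groups of gut bacterial genera rise and fall together across people; a CAG is
a cluster of genera whose relative abundances covary. cagnet implements the
full workflow used to compare such co-abundance structure between disease
subtypes (e.g. IBS-C / IBS-D / IBS-U) and matched non-disease controls:

1. **Cohort matching** — one-to-one case/control pairing by Euclidean
   distance on covariates standardized to mean 0 / variance 1 (age, BMI,
   height, weight, sex, alcohol and dietary frequencies), with an optimal
   assignment solver (Hungarian) and a greedy alternative, plus covariate
   balance reports (standardized mean differences, paired *t*, cross-subtype
   ANOVA).
2. **CAG construction** — genus filtering (presence in ≥ 20% of samples,
   mean relative abundance ≥ 0.05%), per-group Spearman co-abundance
   networks with Benjamini–Hochberg control (edges: q < 0.05 and ρ > 0.4),
   Ward (Ward.D2) clustering of the pooled correlation matrix
   (d = 1 − ρ) into k = 8 CAGs with 2–10-genus size reporting, and per-CAG
   two-sided Wilcoxon rank-sum contrasts.
3. **Pathway association** — genus × pathway Spearman networks
   (|ρ| > 0.2), per-(CAG, metabolic category) disease-vs-control contrasts
   of the correlation values, and paired *t*-tests on focal pathway groups
   (acetate / propionate / butyrate biosynthesis, LPS-associated,
   tryptophan-associated).
4. **Feature screening** — a 500-tree random forest on CAG-summed
   abundances (stratified 70/30 split, 10-fold CV, mean-decrease-Gini
   importance, rank-based ROC/AUC) and a from-scratch Monte-Carlo
   permutation Shapley attributor with per-feature error estimates and an
   asserted efficiency identity `sum(phi) = f(x) − baseline`.
5. **Synthetic studies** — a generator (Gaussian copula, log-normal
   marginals, planted block correlation, case effects, confounded matching
   covariates, a linear genus→pathway layer) providing ground truth for
   every stage.

## Worked example

```r
library(cagnet)

cfg <- run_config(simulate = sim_config(seed = 1), seed = 1)
res <- run_pipeline(cfg, outdir = "cagnet_out")

res$cohort
#> <matched_cohort> 365 pairs (optimal), total distance 746.8822, 0 unmatched case(s)
res$partition
#> <cag_partition> 44 genera in 8 CAGs (ward.D2 linkage); sizes: 9, 8, 7, 6, 5, 4, 3, 2
res$cag_tests[, c("cag", "p_value", "direction", "stars")]
#>    cag      p_value direction stars
#> 1 CAG1 1.025879e-10      down  ****
#> 2 CAG2 5.842718e-13      down  ****
#> 3 CAG3 9.957743e-13        up  ****
#> 4 CAG4 5.240780e-02        up
#> 5 CAG5 7.053104e-02        up
#> 6 CAG6 7.788480e-01      down
#> 7 CAG7 4.791514e-01        up
#> 8 CAG8 1.684893e-01        up
res$rf
#> <cag_rf> 500 trees; accuracy 0.605, sensitivity 0.655, specificity 0.555, AUC 0.659, CV accuracy 0.672 +/- 0.067
```

What this shows: the simulated study plants 8 correlated genus blocks
(sizes 9..2) with multiplicative case effects on blocks 1–3 (two down, one
up). The matcher pairs all 365 cases against the best of 730 candidate
controls; Ward clustering recovers the planted blocks exactly (sizes 9..2,
all within the 2–10 band); the Wilcoxon contrasts flag exactly the three
effect CAGs at `****`; and the forest separates groups moderately
(AUC ≈ 0.66) — the planted ±0.5 log-fold effects are strong in rank tests
over 365 pairs but intentionally moderate for single-sample classification.

`run_pipeline()` writes every report (pairs, balance, networks as edge-list
TSV + GraphML, partition, per-CAG tests, RF metrics/importance/ROC, Shapley
values, cell tests, focal tests) plus `manifest.json`, which echoes all
parameters, seeds and interpretation switches needed to reproduce the run
byte-identically. Real tables are supplied via
`run_config(paths = list(genus = ..., metadata = ..., pathways = ...,
category_map = ...))`; a thin command-line wrapper lives in
`inst/cli/cagnet.R`.

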