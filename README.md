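# duplicability

Tools for studying gene duplicability in the vertebrate lineage: why some
genes keep duplicates created by whole-genome duplication (2R ohnologs)
while others duplicate by small-scale duplication (SSD), and which gene
features separate the two classes once the confounding effect of duplicate
age is removed. The package is aimed at molecular-evolution analyses that
start from paralog tables and macrosynteny maps rather than raw sequence.

It implements, as a tested R package plus a numbered analysis workflow:

* **Duplicate classification** — ohnolog pair calling from 2R macrosynteny
  (blocks of ≥ 3 linking pairs, ≤ 8 genes between anchors on a segment),
  retroduplication filtering by intron counts with a ±5-gene microsynteny
  check, per-gene labels (WGD / SSD / singleton / excluded), and
  majority-rule consensus across three ohnolog data sets.
* **Feature engineering** — tissue specificity
  τ = Σᵢ(1 − xᵢ)/(N − 1) on TPM (0 = housekeeping, 1 = single-tissue),
  duplicate age as the oldest duplication node per vertebrate gene family in
  50 MY units, %GC3 from CDS, longest-transcript selection.
* **Group statistics** — Mann–Whitney comparisons with Bonferroni
  correction; OLS models `feature ~ age + type` with the transformation
  (none / log / Box–Cox) chosen by the Jarque–Bera statistic of the
  residuals and an age × type interaction kept iff it improves AIC by ≥ 2.
* **Importance protocol** — repeated 80/20 random-forest fits with balanced
  class weights, held-out permutation importance (accuracy drop per
  permuted feature), raw and age-controlled (features residualized on age),
  plus a feature-dependence matrix and a correlated-feature isolation
  re-ranking.
* **Enrichment overlap** — two-sided hypergeometric term enrichment against
  the whole-gene background with BH FDR, and concordant/opposed overlap
  fractions between the classes' significant term sets.
* **Synthetic data** — a generator that plants all of the above structure
  (synteny blocks, retro pairs, age-confounded features, class-specific
  expression breadth) with a recoverable ground truth, so the entire
  pipeline is testable without external genome resources.

## Worked example

```r
library(duplicability)

sim  <- simulate_genome(simulation_config(seed = 7))
reps <- simulate_ohnolog_replicates(sim)
res  <- classify_genes(sim$genes, sim$pairs, reps)
classification_summary(res)$gene_counts
#>    data_set WGD SSD SINGLETON EXCLUDED
#> 1         1  24  20       190        6
#> 2         2  24  20       190        6
#> 3         3  24  20       190        6
#> 4 consensus  24  20       190        6
```

The planted genome has 12 two-gene ohnolog families (24 genes), 10 SSD
families, 3 retroduplicated pairs (6 excluded genes) and 190 singletons;
the consensus recovers every planted label (240/240 here).

```r
ft  <- simulate_feature_table(sim)
tau <- tissue_specificity(ft$expression)
round(tapply(tau, sim$truth$gene_truth$true_class, median), 2)
#> RETRO_EXCLUDED      SINGLETON            SSD            WGD
#>           0.82           0.75           0.93           0.63
```

SSD genes are the most tissue-specific (median τ 0.93) and ohnologs the
most broadly expressed (0.63), the planted dosage/expression structure.

```r
dup <- sim$truth$gene_truth$true_class %in% c("WGD", "SSD")
cc  <- classifier_config(n_iterations = 20, seed = 1)
ctl <- run_age_controlled_protocol(ft$features[dup, ], ft$features$age[dup],
                                   sim$truth$gene_truth$true_class[dup], cc)
ctl
#> Duplicate-type importance protocol (age_controlled), 44 genes, 20 iterations
#>   accuracy 0.7111 (95% CI 0.6555-0.7667)
#>         feature mean_importance sd_importance mean_rank
#>      cds_length      0.08888889    0.11169438     4.900
#>            dnds      0.06111111    0.12732567     5.925
#>  ...
#>  age_only_score      0.01666667    0.08279554     7.150
```

After residualizing every feature on duplicate age, the planted pure age
proxy (`age_only_score`) falls to the bottom of the ranking — the same
feature tops the raw (non-age-controlled) protocol. On this small 44-gene
example the classifier still separates the classes at 0.71 held-out
accuracy from the genuinely class-linked features.

The numbered scripts under `analysis/` run the same pipeline at larger
scale (720 genes, 50 + 50 families) end to end — simulation,
classification, derived features, group statistics and regressions,
raw vs age-controlled importance with dependence and isolation tables, and
enrichment overlap — writing their tables under `results/tables/`:

```sh
for f in analysis/0*.R; do Rscript "$f"; done
```

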