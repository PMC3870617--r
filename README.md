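# syndromirnet

Serum miRNA profiling of disease subgroups — moderated differential
testing, SVM subgroup classification, target-prediction consensus,
weighted miRNA-target networks, and gene-set enrichment — as one
reproducible R pipeline.

## What problem this solves

Clinical subtyping studies on serum miRNA arrays work with very small
groups: here, three patient subgroups of 3 samples each against 7
healthy controls, on an array of hundreds of miRNAs. The package
implements the full analysis chain such studies use:

1. **Differential expression** with the random-variance-model (RVM)
   moderated t-test. Each miRNA's variance is shrunk toward an
   inverse-gamma prior fitted across all miRNAs
   (σ̃² = (f·s² + 2/b)/(f + 2a)), and the statistic
   t = (x̄ − ȳ)/√(σ̃²(1/n₁ + 1/n₂)) is referred to a t law with f + 2a
   degrees of freedom — recovering power that 3-vs-7 designs otherwise
   lack. Calls use the conjunction rule: fold change > 1.5 **and**
   P < 0.05.
2. **Hierarchical clustering** with one-minus-Pearson distance and
   average linkage (UPGMA), with deterministic leaf ordering.
3. **SVM binary-tree class prediction**: at each node the class
   bipartition maximizing repeated 10-fold × 10 cross-validated accuracy
   is chosen, with t-test feature selection (P = 0.01) re-run inside
   every training fold; a .632 bootstrap score is reported alongside.
4. **Target consensus**: genes predicted by ≥ 2 of nine binary
   prediction programs (the union of all pairwise intersections,
   "Data A") intersected with genes scoring > 60 in a score-valued
   program ("Data B"); validated interactions are unioned in, flagged.
5. **Weighted bipartite networks** per comparison: miRNA nodes weighted
   by |log2 fold change|, gene nodes by degree; hub extraction
   (degree ≥ 5), up-regulation subnetworks with the percent of
   up-regulated miRNAs, and cross-network comparison by shared nodes and
   Spearman weight-rank similarity with a permutation p-value.
6. **Enrichment**: exact hypergeometric over-representation of the
   up-subnetwork's target genes against a GMT collection, with BH-FDR
   and the retention rule overlap ≥ 5 & p < 0.05 & FDR < 0.05.

Because studies of this kind rarely deposit raw arrays, the package
ships a synthetic-study generator (`simulate_study()`) producing all
inputs — expression matrix, per-program prediction tables, validated
interactions, gene sets — with known ground truth, so the entire
pipeline is testable end to end.

## Worked example

```r
library(syndromirnet)

cfg <- simulation_config(seed = 7)   # 400 miRNAs, 3+1 groups, 40 DE/group
res <- run_pipeline(pipeline_config(cfg), out_dir = "demo_run")

summary_of <- res$de$LGDHS
sum(summary_of$significant)
#> [1] 47
attr(summary_of, "rvm_fit")
#> RVM variance prior: a = 3.3152, b = 2.6430 (f = 8, n = 400, logLik = 372.38)

res$tree
#> classification_tree over {LDSDS, LGDHS, LKYDS}
#>   node 1: {LDSDS} vs {LGDHS,LKYDS}, score = 100 (CV 100.0%, .632 100.0%)
#>   node 2: {LGDHS} vs {LKYDS}, score = 100 (CV 100.0%, .632 100.0%)

res$networks$LGDHS
#> mirna_target_network [LGDHS/Normal]: 47 miRNAs, 192 genes, 320 edges
res$up$LGDHS$up_fraction
#> [1] 46.8

res$comparisons[["LGDHS_vs_LDSDS"]]
#> network_comparison LGDHS/Normal vs LDSDS/Normal
#>   shared miRNAs: 6 (up in both: 3)
#>   weight-rank Spearman r = 0.395 (permutation p = 0.0001)

head(subset(res$enrichment$LGDHS, retained,
            c(set_id, category, k, K, p, fdr_p)), 3)
#>   set_id category  k  K            p        fdr_p
#> 1 SET001       GO 21 72 8.536855e-09 7.256327e-08
#> 2 SET002     KEGG 21 86 2.710313e-07 1.248964e-06
#> 3 SET003 BIOCARTA 19 54 1.383041e-09 2.351170e-08
```

Reading the output: 47 of 400 miRNAs pass the fold-change/p conjunction
for the LGDHS-vs-Normal comparison (40 were planted, and the fitted
variance prior (a ≈ 3.3, b ≈ 2.6) recovers the generator's (3, 3)); the
classification tree separates all three subgroups with perfect
cross-validated node scores at this effect size; the LGDHS network links
those 47 miRNAs to 192 consensus target genes; 46.8% of its miRNAs are
up-regulated; six miRNAs are shared with the LDSDS network; and the five
planted gene sets (SET001–SET005) head the retained enrichment results.
Every file (DE tables, Newick dendrograms, classification tree JSON,
edge lists, GraphML graphs, enrichment tables, cross-comparison report)
is written under `out_dir` together with a `manifest.json` of MD5 hashes
that reproduce exactly on re-run with the same seed.

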