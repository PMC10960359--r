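# propforest

Network-propagation features and random-forest ranking of disease genes.

## The problem

Molecular studies of a complex disease each produce their own candidate
gene list — differential expression here, rare-variant association
there, methylation changes elsewhere. The lists disagree, overlap
sparsely, and individually miss most of the biology. `propforest`
consolidates them using a protein–protein interaction (PPI) network:
genes close in the network to *many* evidence lists are better
candidates than genes flagged by any single study.

It is aimed at computational biologists doing gene prioritization for
a heritable disease who have (a) an interaction network as an edge
list, (b) several evidence-derived gene lists, and (c) a curated set of
high-confidence disease genes to train on.

## The method

**Stage 1 — propagation features.** For each seed list, mass $1/s$ is
placed on each of its $s$ in-network genes and diffused by a random
walk with restart over the network's main connected component:

$$F \leftarrow \alpha\,WF + (1-\alpha)\,Y, \qquad W = D^{-1/2}AD^{-1/2},\ \alpha = 0.8,$$

iterated to a fixed point (equivalently
$F=(1-\alpha)(I-\alpha W)^{-1}Y$). Raw scores are then divided by each
gene's score under the *uniform* seed — an eigenvector-centrality-like
baseline — so that hub genes do not score highly for every list merely
by virtue of their degree. The normalized score of gene $v$ for list
$k$ is feature $X_{vk}$.

**Stage 2 — classification.** A random forest (100 trees, unlimited
depth, nodes split to purity) is trained on curated positives versus an
equal number of negatives sampled outside an exclusion list, and every
network gene receives the positive-class vote fraction as its
association score. Evaluation is stratified 5-fold cross-validation
with per-fold and mean AUROC/AUPRC; operating cutoffs (maximizing
specificity×sensitivity, or precision+recall) are chosen on the
out-of-fold scores; gene groups can be compared against random controls
with Wilcoxon rank tests. A degree-preserving edge-swap null provides
the negative-control arm, and a planted-module synthetic benchmark
makes every stage testable without external data.

## Worked example

Entirely self-contained: the synthetic benchmark plants a 100-gene
disease module in a 2,000-node scale-free network, draws ten seed lists
that each overlap the module by 50%, and labels 50 module genes as
training positives.

```r
library(propforest)

bench <- generate_benchmark(benchmark_config(rng_seed = 7))
net   <- bench$network
net
#> <gene_network> 2000 nodes, 5994 edges

fm <- build_feature_matrix(net, bench$seed_sets)
fm
#> <feature_matrix> 2000 genes x 10 seed sets (alpha=0.8, symmetric)

labels <- label_spec(bench$positives, bench$exclusion, rng_seed = 7)
cv <- cross_validate(fm, labels, forest_config(rng_seed = 7))
cv
#> <cv_result> 5-fold CV on 100 labeled genes: mean AUROC 0.959, mean AUPRC 0.970

model  <- train_full(fm, labels, forest_config(rng_seed = 7))
scores <- predict_scores(model, fm)     # one score in [0,1] per network gene

optimal_cutoff(cv$oof_scores, cv$labels, "spec_times_sens")
#> <cutoff_result> spec_times_sens: cutoff 0.49 (criterion value 0.828); 51 selected; tp=46 fp=5 tn=45 fn=4

# do unlabeled module genes (never seen in training) outscore random genes?
held_out <- setdiff(intersect(bench$module, names(scores)),
                    bench$positives$genes)
group_rank_test(scores, held_out, rng_seed = 7)
#> <group_rank_test> rank_sum: group of 50 scores higher than 50 controls, p = 5.59e-15
```

Reading the numbers: mean AUROC 0.959 / AUPRC 0.970 say the forest
separates planted disease genes from background almost perfectly under
these conditions; the cutoff 0.49 is the out-of-fold score threshold
maximizing specificity×sensitivity (0.828, i.e. 92% sensitivity ×
90% specificity here); and the rank test shows the model generalizes to
module genes that were *never labeled* — the analog of validating on a
curated database's weaker-evidence tiers.

`run_pipeline()` wires all stages (including the degree-randomized
negative-control arm) and writes scores, per-fold metrics, mean curves
and a manifest; `inst/cli/propforest.R` exposes the same stages as
shell subcommands (`simulate`, `propagate`, `build-features`, `cv`,
`run`, `cutoff`, `group-test`, `randomize-network`).

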