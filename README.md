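# netmodule

Disease-module expansion on protein-interaction networks by heat propagation.

Genome-wide association studies yield sets of risk genes that are individually
informative but collectively hard to interpret. A recurring observation in
network medicine is that disease genes cluster in specific neighbourhoods of
the interactome; starting from the mapped risk genes ("seeds") one can
therefore recover the wider disease module — the seeds plus the genes that are
significantly closer to them in network space than degree-matched chance
allows. `netmodule` implements that analysis end to end for any scored
undirected gene network (e.g. a STRING-style edge list), any seed list, and
optional differential-expression and cell-type expression data:

1. **Propagation.** Heat diffusion on the symmetric degree-normalized
   adjacency `W' = D^{-1/2} A D^{-1/2}`, iterating

   `F_t = α W' F_{t-1} + (1 − α) Y`

   to its fixed point, where `Y` places `1/S` on each of the `S` seed genes
   and `α` (default 0.5) is the fraction of heat retained on the network per
   step.
2. **Degree-matched null.** Seeds are replaced by random genes from the same
   degree bins (bins hold ≥ 10 nodes of similar degree); propagation scores
   are log-transformed and each gene receives
   `z = (log F − ⟨log F_rand⟩) / σ(log F_rand)`. The disease module is the
   seed set plus every gene with `z > 2`.
3. **Localization.** The number of edges interconnecting a gene set, compared
   with 5,000 degree-matched random sets, with an 80%-subsampling robustness
   check against hub dominance.
4. **Clustering.** Louvain modularity maximization of the module subgraph,
   with the ≥ 10-gene reporting filter and deterministic cluster ordering.
5. **Enrichment statistics.** Hypergeometric overlap tests, Fisher's exact
   test with sample odds ratio, Benjamini–Hochberg FDR, two-sample
   Kolmogorov–Smirnov, per-cluster transcriptomic dysregulation calls
   (adjusted p < 0.05, |beta| > 0.5), and a random-seed cluster control that
   reruns the whole pipeline from degree-matched random seeds.
6. **Cell-type profiles.** Cluster-by-cell-type mean FPKM summaries and
   one-sided Wilcoxon rank-sum tests of preferential expression.

A planted-community synthetic generator (`generate_network()`,
`generate_seeds()`, `generate_de_table()`, `generate_celltype_fpkm()`)
produces benchmark inputs with known ground truth, and `run_pipeline()`
drives every stage from one YAML/list configuration with a reproducible
manifest.

## Worked example

Expand a synthetic seed set into a module, test its localization, cluster
it, and score the clusters for transcriptomic dysregulation:

```r
library(netmodule)

sim   <- generate_network(rng_seed = 42)          # 600 genes, 12 communities
seeds <- generate_seeds(sim$truth, rng_seed = 43) # 40 seeds, 90% in 4 communities
g     <- largest_component(sim$graph)

fit <- netprop(g, seeds, n_null = 500, rng_seed = 44)
summary(fit)
#> Network-propagation disease module
#>   genes: 600; seeds used: 40 (0 absent from network)
#>   alpha = 0.5, null replicates = 500, z threshold = 2
#>   module: 44 genes = 40 seeds + 4 proximal (z > 2); 0 undefined z
```

The module holds the 40 seeds plus 4 genes whose propagation score exceeds
the degree-matched expectation by more than two null standard deviations
(log scale). The seeds themselves are far more interconnected than chance:

```r
localization_test(g, seeds, n_samples = 999, n_subsamples = 500, rng_seed = 45)
#> network localization: 40 genes, 42 internal edges
#>   degree-matched null (999 sets): mean 26.17, sd 4.63
#>   z = 3.423; empirical p = 0.001; normal-tail p = 0.00031 (approximate)
#>   80%-subsample medians: observed 27 vs null 17
```

The empirical p (add-one rule, never zero) says no random degree-matched set
out of 999 reached the observed 42 internal edges; the subsample medians show
the excess is not carried by a few hubs. Clustering and dysregulation:

```r
part <- louvain_cluster(module_subgraph(g, fit$module), rng_seed = 46)
part
#> cluster partition: 44 genes in 10 clusters (Q = 0.4523)
#>   1 large (>= 10 genes), 4 small (2-9), 5 orphans

de    <- generate_de_table(sim$truth, rng_seed = 47)
bg    <- intersect(igraph::V(g)$name, de$gene)
cluster_dysregulation(part, de, bg)
#>   cluster n_bg n_de n_up n_down       p       q     p_up p_down direction
#> 1       1   12   12   12      0 1.8e-06 1.8e-06 3.76e-10      1        up
```

The one reportable cluster (12 genes) is entirely up-regulated
(hypergeometric q = 1.8e-06, BH-adjusted across the tested clusters), as
planted: the generator placed the differential-expression signal in the
seed-enriched communities.

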