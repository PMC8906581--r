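---
title: "Disease-module expansion by network propagation: models and methods"
author: "netmodule"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disease-module expansion by network propagation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netmodule)
```

## The model

`netmodule` asks a single statistical question in several guises: *is a set
of genes closer together on an interaction network than degree-matched
chance allows?* The core object is a heat-diffusion fixed point on the
thresholded, unweighted network. Let $A$ be the binary adjacency after
keeping edges with confidence strictly above the score threshold (default
0.7 on the unit scale; STRING-style 0–1000 integer scores are rescaled), let
$D$ be the degree diagonal, and

$$W' = D^{-1/2} A D^{-1/2}.$$

With seed indicator $Y$ ($Y_i = 1/S$ for each of the $S$ seed genes, 0
otherwise) the propagation iterates

$$F_t = \alpha W' F_{t-1} + (1-\alpha) Y$$

from $F_0 = Y$ to its fixed point
$F = (1-\alpha)(I - \alpha W')^{-1} Y$. Because $W'$ is symmetric with
spectral radius at most 1, the iteration contracts geometrically for every
$\alpha < 1$; convergence is declared when the max-norm change drops below
`tol` (default $10^{-8}$, reached in a few dozen iterations at
$\alpha = 0.5$). Edge confidence scores are used only for thresholding, not
as propagation weights: the score scale of evidence-accumulation databases
is not calibrated as a transition probability, and binary adjacency keeps
the null model exact.

$\alpha$ is the fraction of heat retained on the network per step; 0.5 is
the package default, in the regime where diffusion rankings are known to be
insensitive to the exact value.

## Degree-matched null and the proximity z-score

Propagation scores are strongly degree-driven, so significance is always
relative to random seed sets of the same degree profile. Nodes are sorted by
degree and packed greedily into bins of at least `min_bin_size` (default 10)
nodes, never splitting a degree value across bins; an undersized trailing
bin is merged into its predecessor. Each null replicate replaces every seed
with a uniform draw from the seed's bin, without replacement within the
replicate; the original seeds stay in the candidate pool (excluding them
would bias the degree matching). Scores are log-transformed — they are
approximately log-normal — and each gene gets

$$z_n = \frac{\log F_n - \langle \log F_{n,\mathrm{rand}} \rangle}
            {\sigma(\log F_{n,\mathrm{rand}})}$$

with the natural logarithm and the sample standard deviation
(denominator $N-1$). The base of the logarithm cancels between numerator
and denominator, so the choice is immaterial as long as it is applied
consistently. Genes with a zero observed or null score (possible only off
the largest component) or a zero null standard deviation are flagged
undefined, reported, and excluded from the module rather than silently
dropped; `run_pipeline()` restricts the analysis to the largest connected
component up front for this reason. The disease module is the seed set plus
every gene with $z$ strictly above the threshold (default 2, the upper
$\approx 2\%$ tail of a standard normal — `pnorm(2, lower.tail = FALSE)` is
0.0228, conventionally quoted as $p = 0.02$). Seeds are retained regardless
of their own $z$, and no per-gene multiple-testing correction is applied
across the genome — the $z > 2$ rule is a module-definition convention, not
a familywise claim. Default null size is 5,000 replicates; the benchmark
and tests use 300–1,000, which changes the Monte-Carlo error of the null
moments, not the statistic.

## Localization

For a gene set the localization statistic is simply the number of edges with
both endpoints in the set, compared against degree-matched random sets of
the same size and per-bin composition. Two p-values are reported: the
add-one empirical tail $p = (1 + \#\{\mathrm{null} \ge \mathrm{obs}\}) /
(1 + N)$, which is never zero, and the normal-tail approximation from the
null mean and standard deviation, labelled approximate — extreme quoted
values (far beyond $1/N$) can only come from the latter. A robustness check
re-counts edges on random 80% subsets (size $\lceil 0.8\,|set|\rceil$) of
the observed set and of fresh null sets; if the excess is carried by a few
hubs the subsample distributions collapse toward each other.

## Clustering

The module subgraph is partitioned by Louvain modularity maximization
(two-phase local moving and aggregation, resolution 1, unweighted — matching
the binary-adjacency decision). Louvain's node visiting order is randomized,
so the partition is made reproducible by seeding the RNG; cluster ids are
then re-assigned deterministically (decreasing size, ties broken by the
lexicographically smallest member) so output tables are stable. Clusters are
reported in three size classes: *large* ($\ge$ 10 genes by default, the
reporting filter used for downstream statistics), *small* (2–9), and
*orphans* (singletons). Modularity is the Newman–Girvan
$Q = \sum_c (e_c/m - (d_c/2m)^2)$; $Q$ of the returned partition is checked
in the tests against exhaustive search over all partitions on small
instances, and against the trivial one-community and all-singleton
partitions on random ones.

## Enrichment statistics

All set-level statistics use strict inequalities mirroring the conventional
thresholds: a gene is up-regulated when adjusted $p < 0.05$ and
$\beta > 0.5$, down-regulated when $\beta < -0.5$. Per-cluster
dysregulation is the hypergeometric upper tail of the all-DE overlap within
the background (genes present in both the network and the DE table),
BH-adjusted across exactly the tested ($\ge$ 10-gene) clusters. The
direction tag is descriptive (up / down / mixed by majority); directional
hypergeometric p-values are reported unadjusted as secondary evidence,
because a cluster can be called on the all-DE statistic while its direction
split carries the biology. Fisher's exact test reports the sample odds ratio
$(ad)/(bc)$ — infinite when $bc = 0$, undefined with $p = 1$ on a zero
margin — with the two-sided p from summing hypergeometric probabilities not
exceeding the observed table's. The two-sample Kolmogorov–Smirnov p is exact
(enumeration over the pooled sample) when both samples have at most 10
observations and asymptotic otherwise. The random-cluster control reruns
propagation, module assembly, clustering, and dysregulation from
degree-matched random seed sets; all replicates share one null-score
ensemble, which is statistically equivalent because every replicate seed set
has the same per-bin composition, and keeps 50 replicates affordable.

## Cell-type expression

Cluster profiles are arithmetic means of FPKM over the cluster's genes per
cell type. The preferential-expression test compares the cluster genes' FPKM
in the focal cell type against the *same genes'* FPKM pooled across all
other cell types, one-sided (greater), by Wilcoxon rank-sum — exact when
both groups are small and untied, otherwise the normal approximation with
midranks and tie-corrected variance. The contrast definition is stated in
the output (`comparison` field) because the alternative framing — cluster
genes against other clusters' genes within the focal type — is equally
defensible; only the within-gene framing is implemented, as it controls for
each gene's baseline expression level. FPKM rescaling leaves the test
invariant; complete ties return $p = 1$.

## The synthetic benchmark

The generator emulates the statistical structure of the real inputs without
shipping any of them: a planted-partition network (600 genes, 12 equal
communities, within-pair probability 0.25, between 0.01) whose edge scores
are uniform on (0.7, 1]; a 5% hub fraction with extra random edges
(one-tenth of the node count each) to produce the heavy degree tail that
stresses degree matching; 40 seed genes drawn 90% from 4 designated
seed-enriched communities; a DE table whose planted effects
($\beta \sim N(\pm 2, 0.5)$, small adjusted p) sit entirely inside the
seed-enriched communities (half up, half down), over a background of
$\beta \sim N(0, 0.3)$ with a 2% significance spike — setting the effect
mean to 0 yields a no-signal tissue control; and a log-normal FPKM matrix in
which each community's genes are 10-fold elevated in one of 5 cell types.
Every generator is a pure function of its configuration and seed.

Why 40 seeds? The real analyses this emulates seed ~1% of a 15,000-node
interactome and expand to a ~5% module whose clusters hold tens of genes. A
600-node benchmark cannot match all three proportions at once: with very few
seeds the module's clusters fall below the 10-gene reporting size and the
downstream statistics go degenerate, while with many seeds the null model
changes character (see below). Forty seeds — about 9 per enriched community,
6.7% of the network — is the compromise that keeps every pipeline stage
exercised and the null calibration in its nominal range.

### What desk scale does and does not show

One scale artifact deserves emphasis. In a 600-node network a non-trivial
fraction of null replicates draw the *focal gene itself* as a seed
(probability $S/n$ per replicate), and a seed's own score is larger by about
$\log(n/S)$; the per-gene null log-score distribution is therefore bimodal,
which inflates its standard deviation several-fold relative to the
15,000-node regime (where $S/n \approx 1\%$ makes the effect negligible).
Meanwhile the maximal log-scale signal available to a planted
non-seed gene is the seed-density contrast of the benchmark design,
$\log(0.9 / (4/12)) \approx 0.99$, independent of the seed count.
Consequently the median proximity $z$ of planted genes sits near 0.5–1.3
at this scale and the $z > 2$ rule recovers only a small fraction of
planted community members — the recovery benchmark documents this honestly
rather than relaxing the threshold. What the passing tests *do* establish is
that the solver is exact against the direct linear solve, the null is
calibrated (null-drawn seeds produce a $z > 2$ fraction near the nominal
tail), false positives in neutral communities are rare, localization
p-values are exact and uniform under the null, and the dysregulation
contrast separates true from random seeds by more than an order of
magnitude. Sensitivity of module recovery at realistic interactome scale is
a property of the full-size analysis, not of this benchmark.

Real interactomes also differ in ways the generator does not emulate:
identifier namespaces (the package treats ids as opaque strings and never
maps between protein and gene symbols), evidence-channel structure behind
the confidence score, correlated degree and annotation biases, and
linkage-disequilibrium structure among GWAS-mapped seeds.

## Numerical and reproducibility choices

Tolerances: propagation `tol` $10^{-8}$ in max norm, iteration cap 1,000
(an error, never a silent truncation). Strictness: every threshold
comparison is strict (`>` / `<`), so boundary values are excluded
everywhere — score exactly 0.7, $z$ exactly 2, $\beta$ exactly 0.5. Tie
handling: degree bins never split a degree value; Louvain ties are resolved
by the seeded visiting order and the deterministic relabeling; rank ties use
midranks. Degenerate inputs: empty edge files, thresholds that kill every
edge, malformed rows (reported with line numbers), edgeless module
subgraphs (all orphans, modularity undefined), clusters absent from the
expression matrix (NA row), and complete expression ties ($p = 1$) all have
defined behaviour covered by tests. Randomness: every stochastic step takes
an explicit `rng_seed`; `run_pipeline()` takes one seed per stage and
records them, with input and output checksums, in its JSON manifest, making
reruns byte-identical.

Benchmark problem sizes used by the test suite and the acceptance script:
20 random graphs of up to 60 nodes for the solver oracle; 1,000 null
replicates for calibration; 500 for recovery; 999 localization nulls for the
planted clique and 500 × 199 for null uniformity; all 115,975 partitions of
the 10-node two-clique instance for the modularity optimum; 100 random
instances per combinatorial oracle; and 51 random-seed replicates (17 on
each of three independent benchmark draws) for the dysregulation contrast —
three draws because Louvain occasionally splits a ~45-gene module just under
the 10-gene reporting size, and a single draw would make the contrast
needlessly noisy.

## Limitations

The package computes statistics, not biology: module membership at $z > 2$
is a screening convention without genome-wide error control; the normal-tail
localization p is an approximation reported alongside the exact empirical
tail; Louvain is a heuristic whose optimum is verified only on small
instances; and the desk-scale benchmark bounds what the recovery tests can
demonstrate, as discussed above. Hierarchical or multiscale community
detection, diffusion variants (personalized PageRank, kernels), weighted
propagation, and identifier mapping are out of scope.
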