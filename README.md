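# hcsym — dendrogram leaf reordering by bilateral symmetric distance

Agglomerative hierarchical clustering of *n* samples fixes a cluster
hierarchy but not a display: every one of the *n−1* internal nodes can be
drawn with its children in either order, giving 2^(n−1) leaf orders that all
encode the same clustering. Off-the-shelf implementations pick one
arbitrarily, so in expression heatmaps and sample dendrograms two highly
similar samples can land far apart just because they sit at the adjoining
edges of sibling clusters drawn the wrong way around — and samples absorbed
into the wrong cluster early drift to where the error is most visible.

`hcsym` is for anyone reading clustered heatmaps or dendrograms of
high-dimensional profiles (bulk or single-cell expression, or any
sample-by-feature matrix): it picks the display that puts similar objects at
cluster boundaries, without touching the clustering itself.

## The method

At a selected node with displayed left cluster L = {x₁…x_m} and right
cluster R = {y₁…y_n}, the **bilateral symmetric distance** is

    B = Σ_{i=1..k} d(x_{m−i+1}, y_i),   k = min(m, n),

the total distance over symmetric pairs taken inward-out across the
boundary. HC-SYM greedily pairs the globally closest (x, y) first, so pair
distances are nondecreasing from the boundary outward; surplus members of
the larger cluster are placed outward by mean distance to their cluster's
paired block. Internal nodes are then flipped toward this target ordering
(a node flips iff its right subtree's mean target rank precedes its left's).
The procedure runs top-down over nodes at depth < `level` that pass a
balance filter (`br`, min/max subtree ratio, default 0.3) and a size filter
(`sr`, smaller-subtree share of all leaves, default 0.03).

Orderings are scored supervised by the **seriation rate**
SR = Σ_c S(c) / Σ_c S_max(|c|) with S(c) = Σ_{pairs in c} 1/ld (ld = position
gap), so SR = 1 exactly when every class is a contiguous block; and
unsupervised by **generalized anti-Robinson scores** GAR(w), counting
violations of Robinson form (similarity nondecreasing toward the diagonal)
within index windows of span w. An HC-PCA baseline (node flipping against
the first principal component) and synthetic-data generators are included.

## Worked example

```r
library(hcsym)

# two-class expression-like data: 45 + 32 samples, 20 features,
# class centers 3 standard deviations apart (moderate overlap)
sim <- make_clustered_data(class_sizes = c(45, 32), dim = 20,
                           separation = 3, noise = 1, seed = 8)
fit <- hcsym(sim$data, labels = sim$labels)   # average linkage, 1 - Pearson r
fit
#> Leaf-reordered hierarchical clustering ('hcsym')
#>   method: hc-sym  leaves: 77
#>   params: level = 1  br = 0.3  sr = 0.03
#>   nodes flipped: 41
#>   seriation rate: 0.8494
summary(fit)
#> Reordering method: hc-sym  ( 77 leaves )
#> Seriation rate: 0.8494 (default order: 0.7990)
#>  class size     score max_score
#>     c1   45 133.33710 152.77267
#>     c2   32  79.57141  97.87185
```

Reordering lifted the seriation rate from 0.7990 (the clustering's own
deterministic display) to 0.8494: the same tree, redrawn so that each class
sits more nearly in one block. `fit$order` is the displayed leaf sequence,
`plot(fit, proximity = TRUE)` draws the dendrogram over the permuted
similarity heatmap, and `fit$log` records every visited node — for the root,
`k = 29` symmetric pairs with total `B = 19.405` and inward-out pair
distances starting `0.437, 0.438, 0.453, ...` (nondecreasing by
construction).

The building blocks are exported individually (`cluster_average_linkage()`,
`hc_sym()`, `sym_order()`, `greedy_symmetric_pairing()`, `seriation_rate()`,
`gar_profile()`, `pc1_scores()` + `order_by_reference()`, `write_newick()` /
`read_newick()`), and a command-line wrapper lives at `inst/cli/hcsym.R`
with subcommands `cluster`, `reorder`, `evaluate`, `gar`, `simulate`,
`render`:

```sh
Rscript inst/cli/hcsym.R simulate --out-dir sim --seed 11
Rscript inst/cli/hcsym.R reorder  --input sim/data.tsv --out-dir run
Rscript inst/cli/hcsym.R evaluate --order run/order.txt --labels sim/labels.tsv --out report.json
```

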