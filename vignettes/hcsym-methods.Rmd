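---
title: "Reordering dendrogram leaves by bilateral symmetric distance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reordering dendrogram leaves by bilateral symmetric distance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hcsym)
```

## The problem

Agglomerative hierarchical clustering of $n$ objects fixes a nested cluster
hierarchy, but not a display: at each of the $n-1$ internal nodes the two
children can be drawn in either order, so $2^{n-1}$ leaf orders are equally
faithful to the same clustering. Standard implementations pick one
arbitrarily. In expression-profile dendrograms and their heatmaps this
matters: two samples that are highly similar can end up far apart simply
because they sit near the adjoining edges of two sibling clusters drawn the
wrong way around, and samples that were absorbed into the "wrong" cluster
early (hierarchical clustering never revisits a merge) drift to positions
where the mistake is maximally visible.

`hcsym` chooses among the $2^{n-1}$ displays by *seriation*: flipping internal
nodes so that the most similar objects of adjacent clusters meet at the
cluster boundary, without ever changing the hierarchy itself.

## The reordering procedure

Write $L = \{x_1,\dots,x_m\}$ and $R = \{y_1,\dots,y_n\}$ for the displayed
leaf sequences of the left and right subtree at a node. The *symmetric pairs*
join leaves at mirrored offsets from the boundary, and their total

$$B \;=\; \sum_{i=1}^{k} d(x_{m-i+1},\, y_i), \qquad k = \min(m, n),$$

is the *bilateral symmetric distance* between the two clusters. $B$ is small
when similar objects face each other across the boundary, with the most
similar pair innermost.

A single reordering step at a node (`sym_order()`) works in three stages:

1. **Greedy pairing** (`greedy_symmetric_pairing()`): repeatedly select the
   globally closest still-unpaired pair $(x, y)$ with $x \in L$, $y \in R$,
   $k$ times. Because each selected distance is a minimum over a shrinking
   candidate set, the pair distances are nondecreasing from the boundary
   outward by construction — the configuration that minimises $B$ among
   orderings of the chosen pairs. Greedy selection is deliberate: it costs
   one matrix scan per pair instead of solving a minimum-weight bipartite
   matching, and its inward-out monotonicity is exactly the display property
   wanted. It does not in general minimise $B$ over *all* perfect matchings;
   that stronger problem is out of scope.
2. **Unpaired placement** (`order_unpaired()`): when $m \neq n$, the surplus
   members of the larger cluster have no symmetric counterpart. Each is scored
   by its mean distance to its own cluster's paired block and placed outward
   from it, most similar innermost. Scoring against the *own* cluster is the
   default (`unpaired_mode = "own"`); scoring against the whole adjacent
   cluster is available as `unpaired_mode = "adjacent"`. The two agree often
   but not always; "own" keeps outliers of a cluster at its outer rim, which
   is the triangular display the method aims at.
3. **Flipping** (`apply_sym_flips()`): stages 1–2 yield a target ordering
   (the *SYM vector*). Every internal node below the reordered node is
   flipped iff the mean SYM rank of its right subtree is strictly smaller
   than that of its left subtree. Since flipping never changes subtree
   membership, the decisions are independent and the result is the orbit
   member closest to the SYM vector under this mean-rank rule. Equal means
   leave a node untouched, so the identity reordering is a fixed point.

`hc_sym()` applies this step recursively, top-down. Candidate nodes are the
internal nodes at depth $<$ `level` (root = depth 0); a candidate is visited
only if it passes two filters:

* **balance ratio** `br`: $\min(|L|,|R|)/\max(|L|,|R|) \ge br$ — reordering a
  grossly unbalanced node mostly reshuffles the big side against a tiny
  reference and adds little;
* **size ratio** `sr`: $\min(|L|,|R|)/n \ge sr$ with $n$ the *whole* tree's
  leaf count — subtrees that are a negligible share of the display are not
  worth visiting. (Reading the denominator as the full tree makes the default
  meaningful at depth: 3% of 504 samples ≈ 15, a sensible floor; a local
  denominator would make `sr` redundant with `br`.)

Defaults are `level = 1`, `br = 0.3`, `sr = 0.03`. Level 1 reorders the whole
tree once at the root; higher levels repeat the procedure inside the root's
descendants, refining boundaries between sub-clusters. Parents are always
visited before children, and the target set is computed once up front —
membership is flip-invariant, so later flips can swap a target's left/right
roles but never its eligibility.

Because every operation is a composition of child swaps, the cluster
hierarchy — the set of leaf sets under internal nodes, `clade_signature()` —
is preserved exactly, and every output order lies in the $2^{n-1}$ flip orbit
of the input. Both facts are asserted property-style in the test suite.

## Evaluation

**Supervised.** With known class labels, grouping quality of a displayed
order is measured per class and normalised. For leaves numbered $1..n$ left
to right, the *linear distance* $ld$ of two leaves is their position gap. The
*seriation score* of class $c$ is

$$S(c) = \sum_{\{u,v\} \subset c} \frac{1}{ld(u, v)},$$

the sum of reciprocal gaps over within-class pairs, and the *seriation rate*

$$SR = \frac{\sum_c S(c)}{\sum_c S_{\max}(|c|)}, \qquad
  S_{\max}(m) = \sum_{g=1}^{m-1} \frac{m-g}{g},$$

where $S_{\max}$ is the score of a contiguous block. $SR \in [0,1]$, is
invariant under reversal of the display, and equals 1 exactly when every
class is contiguous. The reciprocal-gap form is this package's concrete
rendering of a pairwise adjacency statistic; it is the simplest choice that
is positive, maximised exactly at adjacency (verified by brute force over
all placements in the tests), and normalisable to those endpoints. It is
isolated behind `seriation_score()` so an alternative decay could be swapped
in without touching anything else.

**Unsupervised.** A symmetric similarity matrix is *Robinson* when
similarities never decrease toward the diagonal along any row or column
($r_{ij} \le r_{ik}$ for $j < k < i$, mirrored above the diagonal). The
*generalized anti-Robinson score* $GAR(w)$ counts violations of that form in
the matrix permuted by the displayed order, restricted to index triples
spanning at most $w$ positions. Ties are compliant — only strict inversions
count — and counts are raw (unnormalised). Small windows probe local
smoothness, large windows global shape; the profile is nondecreasing in $w$
because larger windows only add triples.

## The synthetic generator

`make_clustered_data()` emulates a labelled expression study: class $c$'s
samples are drawn from $N(\mu_c, \sigma^2 I)$ with centers on orthogonal
coordinate axes, every pair of centers exactly $\delta\sigma$ apart. Defaults
are two classes of 45 and 32 samples — the size structure of a two-tissue
malignancy panel — with $\delta = 3$, $\sigma = 1$ and 20 features.

Two generator choices deserve justification:

* **Dimension 20.** With centers a fixed $\delta\sigma$ apart, the
  *relative* separation shrinks as dimension grows: same-class distances
  concentrate around $\sigma\sqrt{2\,dim}$ while the between-class excess
  stays $\delta^2\sigma^2$. At 20 features, $\delta = 3$ produces the
  intended regime — most samples cluster with their class, a minority is
  misplaced — which is the situation leaf reordering exists to mitigate. At
  microarray-like dimension (hundreds of features) the same $\delta$ would
  be statistically invisible and every method would score at chance.
* **Randomised storage order.** Samples are written into the matrix in
  seeded random order rather than class blocks. The clustering's default
  display uses a deterministic convention (the cluster containing the lower
  input index becomes the left child), so a class-blocked layout would leak
  the labels into the *unordered* baseline through input positions alone and
  bias any method comparison. With randomised positions the baseline's order
  is uninformative about class beyond what the tree itself provides, which
  is what a fair benchmark requires.

What the generator does *not* emulate: intensity-dependent variance,
correlated genes, batch effects, or heavy-tailed noise. Passing the
comparison tests therefore shows the method behaves as designed on clean
geometric class structure; it does not certify effect sizes on real
microarray data.

`make_robinson_similarity()` produces exact Robinson matrices
($s_{ij} = e^{-\lambda |t_i - t_j|}$ for points on a line) for GAR ground
truth, and `random_flips()` scrambles a tree's display (each node flipped
independently with probability $p$) for recovery experiments.

## Numerical and degenerate-case choices

* Average linkage is computed with Lance–Williams size-weighted updates.
  Merge ties (within relative $10^{-12}$) select the pair whose smaller
  original index is least; the cluster containing the lower original index
  becomes the left child. This pins down one reproducible "default" display
  to reorder against, on every platform.
* Greedy pairing breaks distance ties by the lexicographically smallest
  (x id, y id); unpaired-member score ties break by id.
* Mean-rank ties in flipping (both in `apply_sym_flips()` and in the PC1
  baseline `order_by_reference()`) mean *no* flip.
* Distance matrices must be symmetric within $10^{-8}$ with zero diagonal;
  the validator names offending cells. The Pearson correlation distance is
  $1 - r$ across features; constant rows are rejected rather than given an
  arbitrary correlation.
* PC1 scores fix the axis sign so the largest-magnitude loading is positive;
  the baseline uses centering only by default (standardising is an option),
  since expression profiles are usually already on a common scale.
* Newick branch lengths are merge-height differences with leaves at height 0;
  child order in the file is the display order; non-binary input is rejected.
* A singleton class contributes 0 to both numerator and denominator of SR;
  an all-singleton labelling yields SR = 1 (trivially error-free). The
  degenerate constant similarity matrix is Robinson under every order, so
  GAR ≡ 0 there.

## Problem sizes used in the checks

The property suite runs at sizes chosen to keep the whole suite fast while
still exercising every regime: structure preservation over 200 random trees
of up to 64 leaves; orbit exhaustiveness ($2^{n-1}$ orders) verified
exhaustively for $n \le 8$; pairing monotonicity over 1000 random instances;
metric extremes exhaustively over all $8!$ (two classes) and $6!$ (three
classes) permutations; the two-class method comparison over 100 seeds at
$n = 77$; the eight-class level study over 15 seeds at $n = 504$ with
tissue-panel-style class sizes (82, 133, 69, 39, 101, 10, 58, 12); recovery
from randomly flipped trees over 100 seeds. `scripts/acceptance.R` recomputes
the headline comparisons at the same sizes.

## Known limitations

* The pairing is greedy, not an optimal bipartite matching, and the flip
  rule matches the SYM vector in mean rank, not in any global loss — both by
  design, but neither is optimal for, say, minimising $GAR$.
* Only binary (agglomerative) trees are supported; multifurcations are
  rejected at the Newick boundary.
* Built-in distances are Euclidean and $1 -$ Pearson; anything else enters
  as a precomputed matrix.
* The exact algebraic form of $S(c)$ is a package choice (see above); SR
  values are comparable within this package, not across tools that define
  the score differently.
* Optimal leaf ordering (maximising adjacent similarity) is intentionally
  not reimplemented; at small $n$ the tests approximate its objective by
  exhaustive search over the flip orbit when a reference is needed.
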