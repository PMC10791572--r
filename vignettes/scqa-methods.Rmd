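---
title: "Dual-perspective cell type identification: models and methods"
author: "scQA package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-perspective cell type identification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scQA)
```

# The problem

Droplet and plate-based single-cell RNA-seq measures thousands of genes in
thousands of cells, but most entries are zero. Some zeros are biological
(the gene is off in that cell type); many are *dropouts* — the transcript
was present but not captured, and capture failure is more likely the lower
the gene's expression. Most clustering pipelines either impute the zeros
or treat them as noise. scQA instead treats the zero pattern itself as a
weak qualitative signal and combines it with the quantitative expression
profile, clustering cells without a preset number of clusters and
reporting, for every cell cluster, the genes that define it
(bidirectional clustering).

The package identifies cell types in three stages:

1. **Qualitative landmarks (LC1).** Genes are clustered by shared binary
   (detected / not detected) patterns; each cluster's consensus pattern
   over cells is a *landmark*, a column of the binary cells-by-landmarks
   matrix Q1.
2. **Quantitative landmarks (LC2).** Genes are binned, grouped by how
   many bins they use, and clustered within groups when their expression
   trends agree (quasi-trend-preserved genes); cluster mean profiles form
   the columns of Q2, with entries in $[0,1]$.
3. **Cluster constructor (CC).** Cells become nodes of a directed
   k-nearest-neighbour graph weighted by Pearson similarity of Q2 rows.
   Q1 guides the choice of seed cells; labels propagate along short
   paths; clusters are pruned, merged and expanded until every cell is
   labelled and the partition is stable.

# Pre-processing

Genes expressed in fewer than $x\%$ or more than $(100-x)\%$ of cells are
removed ($x = 2.5$ by default; both boundaries inclusive — a gene
expressed in exactly $x\%$ of cells is kept). Cells are never filtered.
Among the remaining genes, the 2000 most variable are retained; the
selection ranks the variance-to-mean dispersion's z-score inside 20
equal-count mean bins (natural-log scale, ties broken by gene index).
This binned-dispersion variant is one of several in circulation; it was
chosen because it is the common default in the field's toolkits, and it
is recorded here because the choice is not forced by the method itself.

Entries are mapped to $[0,1]$ by $d_{ij} \leftarrow \log(1+d_{ij}) /
\max_j \log(1+d_{ij})$ **per gene** rather than by a global min–max.
Per-gene scaling is required downstream: both landmark constructors
average scaled values of different genes at the same cell, which is only
meaningful when every gene occupies the same $[0,1]$ range. Zeros stay
exactly zero and within-gene ranks are unchanged.

# Qualitative landmark construction

Each gene becomes a binary vector ($1$ where expression is positive).
Genes are sorted by decreasing number of zeros (ties by index), and each
gene is scored against the $0.05\,m$ genes on either side of it in the
sorted sequence with $S(G_i, G_j) = 1 - h(G_i,G_j)/n$, where $h$ counts
disagreeing cells. The top $m(m-1)/2000$ pairs (1999 edges when
$m = 2000$) form a gene graph whose connected components with more than
two vertices seed the gene clusters.

Each cluster carries a *template* $T$ (the members' mean binary pattern,
re-binarized at $0.5$) and a *subsidiary vector*
$A = \max(0.5 - \bar d, 0)$, where $\bar d$ is the members' mean scaled
expression per cell. A remaining gene's similarity to a cluster averages
per-cell increments: $1$ where the gene matches the template, $0$ where
the gene is detected but the template is off, and $a_k$ where the gene is
silent but the template is on — the subsidiary value is the plausibility
that this zero is a dropout, shrinking as the cluster's expression at
that cell grows. Genes join the best cluster when the similarity strictly
exceeds $\rho = 0.7$, otherwise they found singleton clusters that may
attract later genes; a single pass is made in sorted order, and clusters
with fewer than 3 genes are dropped. Columns of Q1 are the retained
binary templates.

# Quantitative landmark construction

Scaled values are discretized into $k = 6$ bins — bin 1 holds exactly
the zeros, the rest split $(0,1]$ evenly — and genes are grouped by the
number of distinct bins they use, so that genes with similar dynamic
range are compared with each other. Windowed pairs are scored inside
each group with Spearman rank correlation of the discretized rows
(average ranks for ties; constant rows score 0), and the top thousandth
of *all* gene pairs — the same global edge budget as LC1 — is kept,
pooled across groups; connected components (within groups, size > 2)
seed the clusters. Pooling the budget rather than giving each group its
own thousandth quota is a package decision: a 300-gene group's own quota
is a few dozen edges, too few for every coherent gene family in it to
form a component, and families without an initial component tend to be
absorbed into whatever cluster has the loosest bounds. A cluster's
template is the mean
scaled profile of its members; per-cell lower/upper bounds are the
members' 25th/75th-percentile order statistics. A candidate gene's
similarity to a cluster is the fraction of cells where its value lies
inside the (inclusive) bounds, with the same strict-$\rho$ join rule and
size-3 pruning. Q2 concatenates all retained clusters' templates, groups
in ascending bin-usage order.

Two points were genuinely open and are package decisions:

* **Bound freezing.** A cluster's acceptance bounds are *frozen* when
  the cluster is created and only recomputed after the assignment pass.
  Re-estimating the bounds after every join lets the acceptance box widen
  monotonically: each sparse gene that squeezes in drags the lower bound
  to zero at more cells, which admits more sparse genes, and marker
  clusters snowball into catch-alls for unrelated low-expression genes.
  With frozen bounds the acceptance region stays the one defined by the
  genes that seeded the cluster.
* **Minimum pair retention.** At least one pair is always kept overall,
  so a tiny matrix can still form a component.

# Cluster construction

Cells are correlated through their Q2 rows (Pearson; constant rows
defined as similarity 0 to everything). Each cell points to its
$\lfloor 0.1\,n\rfloor$ most similar cells ($\lfloor 0.05\,n\rfloor$ from
10,000 cells), ties broken by index. A node's *density* is its mean
similarity to its out-neighbours; out-neighbours are used because every
node has exactly $k_{out}$ of them, giving the mean uniform support.

**Seeds.** Cells sharing an identical Q1 row form a group; the smallest
of the per-group maximum densities is the threshold $\beta$, and all
nodes with density $\ge \beta$ are seed candidates. Mutually neighbouring
candidates whose Q1 rows differ in at most one landmark are unioned
transitively into seeds. The one-landmark allowance is a package
decision: requiring exact equality leaves a cell type split in two seeds
whenever one landmark is only partially penetrant in that type, while
unconditional union lets candidates with weak, flat Q2 profiles chain two
unrelated groups into one seed that no later step can split.

**Propagation.** Unlabelled nodes are visited in decreasing density
order. The similarity between node $n_i$ and cluster $C_j$ mixes two
directions with weight $\alpha = 0.5$: along out-edges, the sum of edge
weights over all directed paths of length $\le 2$ from $n_i$ into $C_j$
(two-hop paths route through unlabelled intermediates and contribute the
far edge's weight), divided by the number of such paths; and the mirror
image along in-edges. A term with no paths contributes 0. The node joins
the best cluster only if this similarity strictly exceeds its similarity
to the unlabelled set (the $\alpha$-mixed mean weight to unlabelled
neighbours) — otherwise the evidence is deemed insufficient and the node
waits.

**Pruning and merging.** Clusters below the minimum size
($\max(3, 0.01\,n)$ by default) dissolve back into the unlabelled pool.
Remaining clusters are visited smallest-first; a cluster whose directed
edges into some strictly larger cluster outnumber its internal
connections is absorbed by it. Internal connections are counted as
*unordered* adjacent pairs — the cross count only sees the one direction
from the small cluster outward, so a both-directions internal count would
bias the test against ever merging two equal halves of one over-split
type. A cluster that has absorbed another is never itself absorbed.

**Expansion.** Every still-unlabelled node, in decreasing density order,
compares its out-neighbour count inside each retained cluster with the
cluster's average internal out-degree $A(C_j)$; it joins the cluster it
exceeds the most, or founds a new singleton cluster when it exceeds
none. Counts and degrees are evaluated against the retained clusters as
they stood when expansion began — the comparison is defined for the
clusters that survived pruning and merging, and freezing it there keeps
early ambiguous assignments from distorting later counts and keeps fresh
singletons (whose internal degree of zero would beat any real cluster's)
from capturing their neighbours. Singletons that remain after the
process stabilises are folded back in the final cleanup below.

**Convergence.** The propagation–prune/merge–expansion cycle repeats
until the labels are unchanged between cycles (or `maxIter` = 50 cycles,
with a warning). Repeating the whole trio, rather than propagation
alone, is a package decision: propagation only acts on unlabelled nodes,
so by itself it can never revisit the small provisional clusters that
expansion creates, whereas another prune/merge pass dissolves or absorbs
them. Finally, any cluster still below the minimum size — a size the
method itself defines as too small to report — is dissolved and its
members attached to the cluster holding most of their out-neighbours.

Ablation modes mirror the pipeline's design probes: `lc1_only` builds the
graph, seeds and propagation from Q1 alone; `lc2_only` propagates on Q2
and groups cells by its binarized (positive-entry) form, the same
at-zero threshold used to binarize expression.

# Validation metrics

`ari`, `nmi`, `fmi` and `ji` compare a predicted partition with a
reference through the classification of all cell pairs (a: together in
both; b: together only in the reference; c: together only in the
prediction; d: apart in both):

$$\mathrm{ARI} = \frac{\mathrm{RI} - E[\mathrm{RI}]}{\max \mathrm{RI} - E[\mathrm{RI}]},\qquad
\mathrm{NMI} = \frac{2\,\mathrm{MI}}{H(I)+H(A)},\qquad
\mathrm{FMI} = \frac{a}{\sqrt{(a+b)(a+c)}},\qquad
\mathrm{JI} = \frac{a}{a+b+c}.$$

ARI uses the standard contingency-table (Hubert–Arabie) expectation;
entropies use natural logs (the NMI ratio is base-invariant). Degenerate
conventions: when the ARI correction denominator is zero the index is 1
for identical partitions and 0 otherwise; NMI is 1 when both partitions
are a single cluster; JI is 1 when $a+b+c=0$; FMI is 0 when $a=0$. All
four are invariant to relabelling, and $\mathrm{FMI} \ge \mathrm{JI}$
always.

# The synthetic generator

`simulateCells()` emulates the features the method exploits, and only
those: per planted type, a block of marker genes with lognormal
expression in-type (meanlog 2, sdlog 0.5) and a 1% leak elsewhere;
housekeeping genes positive in every cell (meanlog 2.5, 30% multiplicative
noise); unstructured noise genes positive in a random 30% of cells; and
per-entry dropout with probability
$\text{shape} \cdot \sigma\!\left(-(\log(1+\mu_g) - m_0)\right)$, a
logistic curve in the gene's log mean $\mu_g$ centred on the median gene
$m_0$, so dropout rises as expression falls; `shape` defaults to 0.5
(moderate sparsity) and 0 disables excess zeros. The default bench is 5
types × 100 cells with 30 markers per type, 100 housekeeping and 250
noise genes — sizes at which the whole pipeline runs in seconds, stated
here as the package's test-bench choice.

What the generator does **not** emulate — batch effects, trajectories,
doublets, library-size variation, UMI saturation — bounds what passing
tests show: recovery of well-separated discrete types from dropout-ridden
counts, not robustness to every artefact of real data.

`quasiTrendBlock()` produces families of genes that are monotone
transforms (random power $\gamma \in [0.5,2]$ and amplitude) of one base
profile plus Gaussian noise — the quasi-trend-preserved structure LC2 is
designed to group.

```{r example, eval = FALSE}
sim <- simulateCells(syntheticSpec(seed = 1L))
res <- runScqa(sim$expr)
res
clusterMetrics(cellLabels(res), sim$labels)
```

# Numerical and degenerate-input conventions

* All tie-breaks are by ascending index (genes, cells, clusters,
  enumeration order of pairs), making every stage deterministic: no RNG
  is consumed outside the synthetic module.
* Discretization guards bin boundaries with a $10^{-9}$ tolerance so a
  value sitting on a boundary after floating-point scaling lands in the
  lower bin, matching the closed-upper-interval definition.
* Pearson/Spearman of a constant vector is defined as 0; a term of the
  propagation score with an empty path set contributes 0.
* A gene cluster of size one has template and both bounds equal to its
  single row; all-zero rows are rejected before scaling (the prevalence
  filter makes them impossible in the normal path).
* The strict inequalities of the join rules ($S > \rho$, propagation
  $S(n_i,C_j) > S(n_i,U)$, merge cross $>$ internal) mean boundary cases
  always take the conservative branch (stay out, stay unlabelled, stay
  separate).

# Parameters at a glance

| Parameter | Default | Meaning |
|---|---|---|
| `filterPct` | 2.5 | prevalence window (percent) for gene filtering |
| `nHVG` | 2000 | highly variable genes retained |
| `rho` | 0.7 | strict join threshold for gene clustering (both constructors) |
| `nBins` | 6 | expression bins in LC2 |
| `alpha` | 0.5 | weight of the out-edge direction in propagation |
| `windowFrac` | 0.05 | half-width of the sorted-gene scoring window |
| `pairKeepFrac` | 1/1000 | fraction of gene pairs kept as graph edges |
| `quartilePct` | 25 | order-statistic percentile for LC2 bounds |
| `minGeneCluster` | 3 | minimum genes per landmark |
| `minClusterSize` | auto | minimum cells per cluster, $\max(3, 0.01\,n)$ |
| `maxIter` | 50 | cap on propagation cycles |

Reported sensitivity for the method's three main knobs is modest around
the defaults: mid-range $\rho$ balances cluster purity against
fragmentation, $k = 6$ bins keeps gene pre-grouping neither trivial nor
shattered, and intermediate $\alpha$ uses both edge directions — extreme
$\alpha$ discards one direction of evidence entirely.

# Known limitations

* Landmark templates are diluted when many sparse unstructured genes
  pass the containment test into a marker cluster; frozen bounds slow
  this but do not eliminate it. Heavily contaminated landmarks weaken
  the cell graph.
* Types distinguished only by genes that never form a landmark are
  invisible to the cell graph; the method's resolution is bounded by
  landmark quality, not by the propagation.
* The one-landmark seed-union allowance trades a small risk of joining
  two genuinely distinct but qualitatively adjacent types against the
  common case of one type split by a partially penetrant landmark.
* A genuinely novel cell group smaller than the minimum cluster size
  never forms its own cluster: expansion fragments it into singletons
  and the final cleanup attaches its members to existing clusters.
* Runtime is dominated by the windowed pair scoring and the per-gene
  assignment scans, both $O(m \cdot n)$ per window offset or candidate
  cluster; dense matrices are used throughout, sized for up to a few
  thousand genes and cells per run on one CPU.
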