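# scQA

Dual-perspective cell type identification for single-cell RNA-seq.

Single-cell expression matrices are dominated by zeros, and a zero is
ambiguous: the gene may be off in that cell type, or the transcript was
simply not captured (a dropout, increasingly likely the lower the gene's
expression). scQA treats the zero pattern as a weak *qualitative* signal
in its own right instead of imputing it away, and combines it with the
*quantitative* expression profile. It clusters cells without a preset
number of clusters and simultaneously reports the genes behind each
cluster — a bidirectional (gene x cell) clustering. The package is aimed
at anyone clustering scRNA-seq count matrices who wants dropout-aware
features and cluster-associated gene sets rather than a black-box
embedding.

## Method

Three stages, all deterministic (no RNG outside the simulator):

1. **Qualitative landmarks (LC1).** Each gene becomes a binary vector
   (`1` where detected). Genes sorted by zero count are scored against
   their window neighbours with `S(G_i,G_j) = 1 − h(G_i,G_j)/n` (`h` =
   Hamming distance); the top thousandth of all pairs (1999 edges at
   m = 2000) form a graph whose components seed gene clusters. Each
   cluster keeps a binarized mean template `T` and a subsidiary vector
   `A = max(0.5 − mean expression, 0)` crediting a candidate's zeros
   with their dropout plausibility. Genes join a cluster when the
   template/subsidiary similarity strictly exceeds `ρ = 0.7`. The
   retained templates are the columns of the binary cells x landmarks
   matrix **Q1**.
2. **Quantitative landmarks (LC2).** Scaled expression is discretized
   into `k = 6` bins (bin 1 = exactly the zeros); genes grouped by the
   number of bins they use are clustered within groups, scoring
   windowed pairs by Spearman correlation of the discretized rows. A
   gene joins a cluster when its values fall between the cluster's
   per-cell quartile bounds in more than `ρ` of cells. Cluster mean
   profiles are the columns of **Q2**.
3. **Cluster constructor (CC).** Cells form a directed kNN graph
   (Pearson similarity of Q2 rows; `0.1 n` out-neighbours, `0.05 n`
   from 10,000 cells). Q1 groups guide seed selection via a density
   threshold; labels propagate along directed paths of length ≤ 2,
   mixing both edge directions with weight `α = 0.5`; small clusters
   are dissolved, outward-leaning clusters merged, and the remaining
   cells assigned by comparing their in-cluster neighbour counts with
   each cluster's average internal degree — iterated to a stable
   partition.

External validation ships as ARI, NMI, FMI and JI computed from pair
counts and contingency entropies. A planted-partition simulator
(`simulateCells`) and a quasi-trend gene-family generator
(`quasiTrendBlock`) provide fully reproducible test data. The methods
vignette (`vignettes/scqa-methods.Rmd`) documents the model, every
tunable parameter, and the design decisions taken where the procedure
was genuinely open.

## Worked example

```r
library(scQA)

sim <- simulateCells(syntheticSpec(seed = 1L))   # 5 planted types
sim$expr
#> ExpressionMatrix: 500 genes x 500 cells (unscaled)

res <- runScqa(sim$expr)
res
#> ScqaResult (mode=full): 500 cells in 5 clusters
#> cluster sizes: 102, 100, 100, 100, 98

round(clusterMetrics(cellLabels(res), sim$labels), 3)
#>   ari   nmi   fmi    ji
#> 0.990 0.988 0.992 0.984

qualitativeMatrix(res)
#> LandmarkMatrix (qualitative): 500 cells x 9 landmarks; 495 member genes
quantitativeMatrix(res)
#> LandmarkMatrix (quantitative): 500 cells x 7 landmarks; 366 member genes

head(clusterLandmarkTable(res)[, 1:3])
#>    cluster landmark_id mean_value
#> L1       0          L1   0.199338
#> L4       1          L4   0.254086
#> L2       2          L2   0.383483
#> L7       3          L7   0.546630
#> L5       4          L5   0.297537
```

The five planted types are recovered as five clusters (ARI 0.99 against
the planted labels), and each cluster is paired with the landmark whose
mean value is highest across its cells; the landmark's member genes (the
`genes` column of `clusterLandmarkTable`) are the cluster's key genes.

## Command line

A thin wrapper over the same functions:

```sh
Rscript inst/scripts/scqa.R simulate --types 5 --cells-per-type 100 --seed 1 --out sim/
Rscript inst/scripts/scqa.R run --input sim/matrix.mtx --rho 0.7 --bins 6 --alpha 0.5 --out out/
Rscript inst/scripts/scqa.R eval --pred out/labels.csv --truth sim/truth.csv
```

`run` accepts dense CSV/TSV (gene ids in the first column, cell ids in
the header) or Matrix Market input with `genes.tsv`/`barcodes.tsv`
companions, writes `labels.csv`, `Q1.csv`/`Q2.csv`, landmark membership
tables and the cluster-landmark association, and can read defaults from
a YAML config file (CLI flags win). `--mode lc1_only` / `lc2_only` run
the single-constructor ablations.

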