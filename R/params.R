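#' Create a parameter set for the scQA pipeline
#'
#' The defaults are the method's published operating point: genes expressed
#' in fewer than 2.5\% or more than 97.5\% of cells are removed, 2000 highly
#' variable genes are kept, gene clusters are grown with similarity
#' threshold `rho = 0.7`, expression is discretized into 6 bins, and the two
#' directions of the cell graph are mixed with `alpha = 0.5`.
#'
#' @param filterPct percent `x`; a gene is kept iff the fraction of cells
#'   expressing it lies in `[x\%, (100-x)\%]` (boundaries inclusive).
#' @param nHVG number of highly variable genes to retain.
#' @param rho similarity threshold in `(0,1]` a gene must strictly exceed to
#'   join an existing gene cluster.
#' @param nBins number of bins `k >= 2` for expression discretization.
#' @param alpha weight in `[0,1]` of the outgoing-edge term of the
#'   node-cluster similarity; `1 - alpha` weighs the incoming-edge term.
#' @param windowFrac fraction of genes taken before and after a gene in the
#'   zero-count-sorted sequence as its scoring neighbourhood.
#' @param pairKeepFrac fraction of all gene pairs kept as edges of the gene
#'   similarity graph (one thousandth by default, so 1999 edges at
#'   m = 2000).
#' @param quartilePct percentile for the lower/upper bound vectors of
#'   quantitative gene clusters (25 = quartiles).
#' @param minGeneCluster minimum member count for a gene cluster to become a
#'   landmark.
#' @param minClusterSize minimum cell-cluster size before the merge step;
#'   `"auto"` (the default) resolves to `max(3, round(0.01 n))` at run time.
#' @param maxIter cap on label-propagation convergence sweeps.
#'
#' @return A [ScqaParams-class] object.
#' @examples
#' p <- scqaParams(rho = 0.8)
#' p
#' @export
scqaParams <- function(filterPct = 2.5, nHVG = 2000L, rho = 0.7,
                       nBins = 6L, alpha = 0.5, windowFrac = 0.05,
                       pairKeepFrac = 1 / 1000, quartilePct = 25,
                       minGeneCluster = 3L, minClusterSize = "auto",
                       maxIter = 50L) {
    mcs <- if (identical(minClusterSize, "auto") || is.na(minClusterSize))
        NA_integer_ else as.integer(minClusterSize)
    new("ScqaParams",
        filterPct = as.numeric(filterPct),
        nHVG = as.integer(nHVG),
        rho = as.numeric(rho),
        nBins = as.integer(nBins),
        alpha = as.numeric(alpha),
        windowFrac = as.numeric(windowFrac),
        pairKeepFrac = as.numeric(pairKeepFrac),
        quartilePct = as.numeric(quartilePct),
        minGeneCluster = as.integer(minGeneCluster),
        minClusterSize = mcs,
        maxIter = as.integer(maxIter)
    )
}

# resolve the automatic minimum cell-cluster size for n cells
.resolveMinClusterSize <- function(params, n) {
    if (is.na(params@minClusterSize)) max(3L, as.integer(round(0.01 * n)))
    else params@minClusterSize
}
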