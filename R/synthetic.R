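# Planted-partition synthetic scRNA-seq generator. Emulates the features
# the pipeline exploits: type-specific marker blocks (positive in one type,
# near-zero elsewhere), shared housekeeping genes, unstructured noise
# genes, lognormal positive expression and per-entry dropout whose
# probability rises as a gene's mean expression falls. It does not emulate
# batch effects, trajectories, doublets or UMI-depth variation.

#' Describe a synthetic planted-partition dataset
#'
#' Defaults are the test-bench conditions used throughout the package:
#' 5 cell types of 100 cells each, 30 marker genes per type, 100
#' housekeeping genes, 250 unstructured noise genes, and a moderate
#' mean-dependent dropout (`dropoutShape = 0.5`).
#'
#' @param nTypes number of planted cell types.
#' @param cellsPerType cells per type; a scalar is recycled.
#' @param nMarkersPerType marker genes per type, expressed (lognormal) in
#'   that type and zero elsewhere except a 1\% leak.
#' @param nHousekeeping genes positive in every cell.
#' @param nNoiseGenes genes with unstructured sparse expression.
#' @param dropoutShape amplitude in `[0,1]` of the logistic mean-dependent
#'   dropout curve; 0 disables excess zeros.
#' @param expressionScale lognormal `c(meanlog, sdlog)` for marker
#'   expression.
#' @param seed RNG seed; generation is fully reproducible.
#' @return A [SyntheticSpec-class].
#' @export
syntheticSpec <- function(nTypes = 5L, cellsPerType = 100L,
                          nMarkersPerType = 30L, nHousekeeping = 100L,
                          nNoiseGenes = 250L, dropoutShape = 0.5,
                          expressionScale = c(2, 0.5), seed = 1L) {
    cpt <- as.integer(rep(cellsPerType, length.out = nTypes))
    new("SyntheticSpec",
        nTypes = as.integer(nTypes),
        cellsPerType = cpt,
        nMarkersPerType = as.integer(nMarkersPerType),
        nHousekeeping = as.integer(nHousekeeping),
        nNoiseGenes = as.integer(nNoiseGenes),
        dropoutShape = as.numeric(dropoutShape),
        expressionScale = as.numeric(expressionScale),
        seed = as.integer(seed)
    )
}

# excess-zero probability per gene: logistic in the gene's log1p mean,
# centred on the median gene, scaled by the overall amplitude `shape`
.dropoutProb <- function(geneMeans, shape) {
    if (shape == 0) return(rep(0, length(geneMeans)))
    lm <- log1p(geneMeans)
    m0 <- stats::median(lm)
    shape * stats::plogis(-(lm - m0))
}

#' Generate a synthetic expression matrix with planted cell types
#'
#' @param spec a [SyntheticSpec-class]; see [syntheticSpec()].
#' @return A list with `expr` (an unscaled [ExpressionMatrix-class]),
#'   `labels` (0-based integer type per cell) and `geneType` (character:
#'   `"marker"`, `"housekeeping"` or `"noise"` per gene).
#' @examples
#' sim <- simulateCells(syntheticSpec(nTypes = 3L, cellsPerType = 40L,
#'     seed = 7L))
#' dim(sim$expr)
#' table(sim$labels)
#' @export
simulateCells <- function(spec = syntheticSpec()) {
    stopifnot(is(spec, "SyntheticSpec"))
    set.seed(spec@seed)
    K <- spec@nTypes
    n <- sum(spec@cellsPerType)
    labels <- rep(seq_len(K) - 1L, times = spec@cellsPerType)
    ml <- spec@expressionScale[1]
    sl <- spec@expressionScale[2]
    blocks <- list()
    gtypes <- character(0)
    gnames <- character(0)
    # marker blocks: one per type, lognormal within-type, 1% leak outside
    for (t in seq_len(K)) {
        ng <- spec@nMarkersPerType
        blk <- matrix(0, ng, n)
        inType <- labels == (t - 1L)
        blk[, inType] <- stats::rlnorm(ng * sum(inType), ml, sl)
        leak <- matrix(stats::runif(ng * n) < 0.01, ng, n) & !rep(inType,
            each = ng)
        blk[leak] <- stats::rlnorm(sum(leak), ml - 1.5, sl)
        blocks[[length(blocks) + 1L]] <- blk
        gtypes <- c(gtypes, rep("marker", ng))
        gnames <- c(gnames, sprintf("MK%d_%d", t, seq_len(ng)))
    }
    # housekeeping: positive everywhere, gene-level mean times noise
    if (spec@nHousekeeping > 0L) {
        ng <- spec@nHousekeeping
        gm <- stats::rlnorm(ng, ml + 0.5, sl)
        blk <- gm * matrix(stats::rlnorm(ng * n, 0, 0.3), ng, n)
        blocks[[length(blocks) + 1L]] <- blk
        gtypes <- c(gtypes, rep("housekeeping", ng))
        gnames <- c(gnames, sprintf("HK_%d", seq_len(ng)))
    }
    # noise genes: sparse unstructured expression
    if (spec@nNoiseGenes > 0L) {
        ng <- spec@nNoiseGenes
        blk <- matrix(0, ng, n)
        on <- matrix(stats::runif(ng * n) < 0.3, ng, n)
        blk[on] <- stats::rlnorm(sum(on), ml - 1, sl)
        blocks[[length(blocks) + 1L]] <- blk
        gtypes <- c(gtypes, rep("noise", ng))
        gnames <- c(gnames, sprintf("NS_%d", seq_len(ng)))
    }
    mat <- do.call(rbind, blocks)
    # mean-dependent dropout on positive entries
    p <- .dropoutProb(rowMeans(mat), spec@dropoutShape)
    if (any(p > 0)) {
        drop <- matrix(stats::runif(length(mat)), nrow(mat)) <
            p[row(mat)] & mat > 0
        mat[drop] <- 0
    }
    rownames(mat) <- gnames
    colnames(mat) <- sprintf("cell_%d", seq_len(n))
    list(
        expr = expressionMatrix(mat),
        labels = labels,
        geneType = gtypes
    )
}

#' Generate a block of quasi-trend-preserved gene rows
#'
#' Each generated gene is a monotone increasing transform (random power and
#' amplitude) of a shared base profile plus Gaussian noise, so the rank
#' order of cells is approximately preserved across the block - the kind
#' of gene family the quantitative landmark constructor is meant to
#' cluster.
#'
#' @param nGenes number of rows to generate.
#' @param baseProfile non-negative numeric vector; the shared profile over
#'   cells.
#' @param noiseSd standard deviation of the additive Gaussian noise.
#' @param seed RNG seed.
#' @return A `nGenes` x `length(baseProfile)` non-negative matrix.
#' @examples
#' base <- seq(0, 1, length.out = 50)
#' blk <- quasiTrendBlock(10, base, noiseSd = 0.02, seed = 3L)
#' stats::cor(blk[1, ], base, method = "spearman")
#' @export
quasiTrendBlock <- function(nGenes, baseProfile, noiseSd = 0.05,
                            seed = 1L) {
    set.seed(seed)
    n <- length(baseProfile)
    rng <- max(baseProfile) - min(baseProfile)
    b01 <- if (rng > 0) (baseProfile - min(baseProfile)) / rng
        else baseProfile
    out <- matrix(0, nGenes, n)
    for (g in seq_len(nGenes)) {
        gamma <- stats::runif(1, 0.5, 2)
        amp <- stats::runif(1, 0.5, 1.5)
        row <- amp * b01^gamma +
            stats::rnorm(n, 0, noiseSd)
        out[g, ] <- pmax(row, 0)
    }
    rownames(out) <- sprintf("QT_%d", seq_len(nGenes))
    out
}
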