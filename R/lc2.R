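#' Discretize a scaled expression matrix into bins
#'
#' Bins are `[0,0]`, `(0, 1/(k-1)]`, `(1/(k-1), 2/(k-1)]`, ...,
#' `((k-2)/(k-1), 1]`, so bin 1 holds exactly the zeros and the remaining
#' `k-1` bins split the positive range evenly. Entries are 1-based bin
#' indices.
#'
#' @param E a scaled [ExpressionMatrix-class].
#' @param nBins the number of bins `k >= 2`.
#' @return A genes x cells integer matrix of bin indices in `1..k`.
#' @export
discretizeMatrix <- function(E, nBins = 6L) {
    stopifnot(is(E, "ExpressionMatrix"))
    if (!isScaled(E)) stop("discretizeMatrix expects a scaled matrix")
    v <- exprValues(E)
    k <- as.integer(nBins)
    if (any(v < 0 | v > 1)) stop("entries outside [0,1]")
    # positive values: ceiling over the (k-1) even bins, guarded against
    # floating-point values sitting infinitesimally above a boundary
    b <- ceiling(v * (k - 1) - 1e-9)
    b[b < 1] <- 1
    b <- b + 1
    b[b > k] <- k
    b[v == 0] <- 1
    storage.mode(b) <- "integer"
    dimnames(b) <- dimnames(v)
    b
}

# number of distinct bins used by each gene
.binUsage <- function(Dp, k) {
    usage <- integer(nrow(Dp))
    for (b in seq_len(k)) usage <- usage + (rowSums(Dp == b) > 0L)
    usage
}

# Spearman rank correlation of discretized rows for windowed pairs of the
# (already sorted) rank matrix; constant rows correlate 0 by convention
.windowedPairScoresSpearman <- function(DpSorted, w) {
    m <- nrow(DpSorted)
    pos <- .windowedPairPositions(m, w)
    if (nrow(pos) == 0L)
        return(data.frame(p = integer(0), q = integer(0),
            score = numeric(0)))
    rk <- t(apply(DpSorted, 1L, rank))          # average ranks for ties
    rk <- rk - rowMeans(rk)
    den <- sqrt(rowSums(rk^2))
    score <- numeric(nrow(pos))
    off <- pos[, "q"] - pos[, "p"]
    for (o in unique(off)) {
        sel <- which(off == o)
        i <- pos[sel, "p"]
        num <- rowSums(rk[i, , drop = FALSE] * rk[i + o, , drop = FALSE])
        d <- den[i] * den[i + o]
        score[sel] <- ifelse(d > 0, num / d, 0)
    }
    data.frame(p = pos[, "p"], q = pos[, "q"], score = score)
}

# mean template plus lower/upper bound vectors of a quantitative cluster:
# per cell, the members' scaled values are sorted and the elements at the
# lower/upper quartile positions become the bounds
.lc2ClusterStats <- function(members, D, quartilePct) {
    cl <- length(members)
    if (cl == 1L) {
        tv <- D[members, ]
        return(list(T = tv, TL = tv, TU = tv))
    }
    sub <- D[members, , drop = FALSE]
    tv <- colMeans(sub)
    lo <- max(1L, floor(quartilePct / 100 * cl))
    hi <- min(cl, ceiling((100 - quartilePct) / 100 * cl))
    srt <- apply(sub, 2L, sort)
    list(T = tv, TL = srt[lo, ], TU = srt[hi, ])
}

# fraction of cells where the gene's value falls inside [TL, TU]
.quantSimilarity <- function(g, TL, TU) {
    mean(TL <= g & g <= TU)
}

# quantitative analogue of the qualitative assignment sweep, restricted
# to one bin-usage group. The acceptance bounds of a cluster are frozen
# at its creation (initial clustering or singleton founding): letting the
# bounds widen with every join would monotonically grow the acceptance
# box and absorb unrelated sparse genes. Templates and bounds are
# recomputed from the final membership once the pass is over.
.lc2Assign <- function(clusters, unassignedSorted, D, rho, minSize,
                       quartilePct) {
    n <- ncol(D)
    lmax <- length(clusters) + length(unassignedSorted)
    TLmat <- matrix(0, lmax, n)
    TUmat <- matrix(0, lmax, n)
    members <- vector("list", lmax)
    L <- length(clusters)
    for (j in seq_len(L)) {
        members[[j]] <- clusters[[j]]
        st <- .lc2ClusterStats(members[[j]], D, quartilePct)
        TLmat[j, ] <- st$TL; TUmat[j, ] <- st$TU
    }
    for (gi in unassignedSorted) {
        g <- D[gi, ]
        if (L > 0L) {
            G <- matrix(g, L, n, byrow = TRUE)
            S <- rowSums(TLmat[seq_len(L), , drop = FALSE] <= G &
                G <= TUmat[seq_len(L), , drop = FALSE]) / n
            J <- which.max(S)
        } else {
            S <- -Inf; J <- 0L
        }
        if (L > 0L && S[J] > rho) {
            members[[J]] <- c(members[[J]], gi)
        } else {
            L <- L + 1L
            members[[L]] <- gi
            TLmat[L, ] <- g; TUmat[L, ] <- g
        }
    }
    keep <- which(lengths(members[seq_len(L)]) >= minSize)
    tmpl <- matrix(0, length(keep), n)
    for (idx in seq_along(keep))
        tmpl[idx, ] <- .lc2ClusterStats(members[[keep[idx]]], D,
            quartilePct)$T
    list(members = members[keep], templates = tmpl)
}

#' Construct quantitative landmarks (Q2)
#'
#' Scaled expression is discretized into `nBins` bins; genes are grouped by
#' the number of distinct bins they use; within each group, windowed pairs
#' of zero-sorted genes are scored by Spearman rank correlation of their
#' discretized rows, the top thousandth of pairs form a graph whose
#' components (size > 2) seed clusters, and remaining genes join a cluster
#' when the fraction of cells where their value falls between the cluster's
#' lower/upper quartile bound vectors strictly exceeds `rho`. Retained
#' clusters of all groups are joined; each cluster's mean expression
#' profile becomes one column of Q2.
#'
#' @param E a scaled [ExpressionMatrix-class] (see [preprocess()]).
#' @param params a [ScqaParams-class].
#' @return A [LandmarkMatrix-class] of type `"quantitative"` (cells x
#'   landmarks, entries in `[0,1]`), with `landmarkGroups()` recording the
#'   bin-usage group of each landmark.
#' @examples
#' sim <- simulateCells(syntheticSpec(seed = 1L))
#' D <- preprocess(sim$expr, scqaParams())
#' Q2 <- quantitativeLandmarks(D, scqaParams())
#' Q2
#' @export
quantitativeLandmarks <- function(E, params = scqaParams()) {
    stopifnot(is(E, "ExpressionMatrix"))
    D <- exprValues(E)
    k <- params@nBins
    Dp <- discretizeMatrix(E, k)
    usage <- .binUsage(Dp, k)
    m <- nrow(D)
    # score windowed pairs inside every bin-usage group, then keep the
    # top thousandth of ALL gene pairs globally (the same edge budget as
    # the qualitative constructor); per-group quotas starve small groups
    # of edges and leave whole gene families without initial clusters
    pool <- list()
    sortedGenes <- list()
    for (u in sort(unique(usage))) {
        genes <- which(usage == u)
        mg <- length(genes)
        if (mg < 3L) next
        zeros <- rowSums(Dp[genes, , drop = FALSE] == 1L)
        genesSorted <- genes[order(-zeros, seq_len(mg))]
        w <- max(1L, round(params@windowFrac * mg))
        pairs <- .windowedPairScoresSpearman(
            Dp[genesSorted, , drop = FALSE], w)
        if (nrow(pairs)) {
            pairs$gi <- genesSorted[pairs$p]
            pairs$gj <- genesSorted[pairs$q]
            pairs$u <- u
            pool[[length(pool) + 1L]] <- pairs
        }
        sortedGenes[[as.character(u)]] <- genesSorted
    }
    if (!length(pool))
        stop("no scorable gene pairs in any bin-usage group")
    allPairs <- do.call(rbind, pool)
    eKeep <- max(1L, floor(params@pairKeepFrac * m * (m - 1) / 2))
    eKeep <- min(eKeep, nrow(allPairs))
    ordP <- order(-allPairs$score, seq_len(nrow(allPairs)))
    kept <- allPairs[ordP[seq_len(eKeep)], , drop = FALSE]
    allMembers <- list()
    allTemplates <- list()
    allGroups <- integer(0)
    for (u in sort(unique(usage))) {
        genesSorted <- sortedGenes[[as.character(u)]]
        if (is.null(genesSorted)) next
        mg <- length(genesSorted)
        ke <- kept[kept$u == u, , drop = FALSE]
        init <- list()
        unassigned <- genesSorted
        if (nrow(ke)) {
            lut <- integer(m)
            lut[genesSorted] <- seq_len(mg)
            comps <- .pairComponents(cbind(lut[ke$gi], lut[ke$gj]), mg)
            comps <- lapply(comps, function(i) sort(genesSorted[i]))
            comps <- comps[order(vapply(comps, min, 1L))]
            init <- comps[lengths(comps) >= 3L]
            inInit <- unlist(init, use.names = FALSE)
            unassigned <- genesSorted[!(genesSorted %in% inInit)]
        }
        res <- .lc2Assign(init, unassigned, D, params@rho,
            params@minGeneCluster, params@quartilePct)
        if (length(res$members)) {
            allMembers <- c(allMembers, res$members)
            allTemplates <- c(allTemplates,
                lapply(seq_along(res$members),
                    function(j) res$templates[j, ]))
            allGroups <- c(allGroups, rep(u, length(res$members)))
        }
    }
    if (!length(allMembers))
        stop("no quantitative gene cluster survives pruning in any group")
    vals <- do.call(cbind, allTemplates)
    rownames(vals) <- colnames(D)
    colnames(vals) <- paste0("L", seq_len(ncol(vals)))
    new("LandmarkMatrix",
        values = vals,
        type = "quantitative",
        memberships = lapply(allMembers, function(i) rownames(D)[i]),
        groups = allGroups
    )
}
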