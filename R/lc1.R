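#' Binarize an expression matrix
#'
#' Entry `g_ij = 1` iff the expression `d_ij` is positive. Zeros in
#' scRNA-seq are treated as weak qualitative signal (potential dropouts),
#' so the binary pattern of a gene is itself informative.
#'
#' @param E an [ExpressionMatrix-class] (scaled or not).
#' @return A genes x cells 0/1 numeric matrix with the same dimnames.
#' @export
binarizeMatrix <- function(E) {
    v <- exprValues(E)
    b <- (v > 0) + 0
    dimnames(b) <- dimnames(v)
    b
}

# genes ordered by decreasing number of zeros, ties by ascending index
.orderByZeros <- function(B) {
    order(-rowSums(B == 0), seq_len(nrow(B)))
}

# windowed pair enumeration over positions in a sorted sequence:
# position p is paired with p+1 .. p+w; enumeration order (p asc, offset
# asc) defines the pair index used for tie-breaking
.windowedPairPositions <- function(m, w) {
    if (m < 2L || w < 1L) return(cbind(p = integer(0), q = integer(0)))
    ps <- integer(0); qs <- integer(0)
    for (o in seq_len(min(w, m - 1L))) {
        idx <- seq_len(m - o)
        ps <- c(ps, idx)
        qs <- c(qs, idx + o)
    }
    ord <- order(ps, qs)
    cbind(p = ps[ord], q = qs[ord])
}

# similarity of binary genes i,j: 1 - hamming/n, computed for all windowed
# pairs of the sorted matrix Bs via per-offset vectorized row products
.windowedPairScoresBinary <- function(Bs, w) {
    m <- nrow(Bs); n <- ncol(Bs)
    pos <- .windowedPairPositions(m, w)
    if (nrow(pos) == 0L)
        return(data.frame(p = integer(0), q = integer(0),
            score = numeric(0)))
    rs <- rowSums(Bs)
    score <- numeric(nrow(pos))
    # group by offset for vectorized dot products
    off <- pos[, "q"] - pos[, "p"]
    for (o in unique(off)) {
        sel <- which(off == o)
        i <- pos[sel, "p"]
        dot <- rowSums(Bs[i, , drop = FALSE] *
            Bs[i + o, , drop = FALSE])
        h <- rs[i] + rs[i + o] - 2 * dot
        score[sel] <- 1 - h / n
    }
    data.frame(p = pos[, "p"], q = pos[, "q"], score = score)
}

# keep the top floor(pairKeepFrac * m(m-1)/2) pairs by score (at least
# minKeep), ties broken by enumeration order; returns the kept rows
.topPairs <- function(pairs, m, pairKeepFrac, minKeep = 0L) {
    eKeep <- floor(pairKeepFrac * m * (m - 1) / 2)
    eKeep <- max(eKeep, minKeep)
    if (eKeep < 1L) stop("pair retention rule keeps zero gene pairs")
    eKeep <- min(eKeep, nrow(pairs))
    ord <- order(-pairs$score, seq_len(nrow(pairs)))
    pairs[ord[seq_len(eKeep)], , drop = FALSE]
}

# connected components (on original gene indices) of the kept-pair graph;
# components ordered by smallest member index, members ascending
.pairComponents <- function(edges, m) {
    g <- igraph::make_empty_graph(n = m, directed = FALSE)
    if (nrow(edges))
        g <- igraph::add_edges(g, rbind(edges[, 1L], edges[, 2L]))
    memb <- igraph::components(g)$membership
    comps <- split(seq_len(m), memb)
    comps <- lapply(comps, sort)
    comps[order(vapply(comps, min, 1L))]
}

# template mean, binarized template and subsidiary vector of a qualitative
# gene cluster; D holds scaled expression, B the binary matrix
.lc1ClusterStats <- function(members, B, D) {
    if (length(members) == 1L) {
        tmean <- B[members, ]
        dmean <- D[members, ]
    } else {
        tmean <- colMeans(B[members, , drop = FALSE])
        dmean <- colMeans(D[members, , drop = FALSE])
    }
    Tb <- (tmean >= 0.5) + 0
    A <- pmax(0.5 - dmean, 0)
    list(tmean = tmean, Tb = Tb, A = A)
}

# similarity between a binary gene vector and a qualitative cluster:
# per-cell increment 1 where the gene matches the template, 0 where the
# gene is expressed but the template is not, and the subsidiary value
# (dropout plausibility) where the gene is silent but the template is on
.geneClusterSimilarity <- function(g, Tb, A) {
    mu <- as.numeric(g == Tb)
    sel <- g == 0 & Tb == 1
    mu[sel] <- A[sel]
    mean(mu)
}

# mutable assignment engine shared intent with the quantitative variant:
# sweep unassigned genes in sorted order, join the best cluster if its
# similarity strictly exceeds rho, else open a singleton that can attract
# later genes; prune clusters below minSize afterwards
.lc1Assign <- function(clusters, unassignedSorted, B, D, rho, minSize) {
    n <- ncol(B)
    lmax <- length(clusters) + length(unassignedSorted)
    Tmat <- matrix(0, lmax, n)
    Vmat <- matrix(0, lmax, n)   # Tb * A, for the dropout-credit term
    rT <- numeric(lmax)
    members <- vector("list", lmax)
    L <- length(clusters)
    for (j in seq_len(L)) {
        members[[j]] <- clusters[[j]]
        st <- .lc1ClusterStats(members[[j]], B, D)
        Tmat[j, ] <- st$Tb
        Vmat[j, ] <- st$Tb * st$A
        rT[j] <- sum(st$Tb)
    }
    for (gi in unassignedSorted) {
        g <- B[gi, ]
        rg <- sum(g)
        if (L > 0L) {
            dots <- Tmat[seq_len(L), , drop = FALSE] %*% g
            extra <- Vmat[seq_len(L), , drop = FALSE] %*% (1 - g)
            S <- (n - rT[seq_len(L)] - rg + 2 * dots + extra) / n
            J <- which.max(S)
        } else {
            S <- -Inf; J <- 0L
        }
        if (L > 0L && S[J] > rho) {
            members[[J]] <- c(members[[J]], gi)
            st <- .lc1ClusterStats(members[[J]], B, D)
            Tmat[J, ] <- st$Tb
            Vmat[J, ] <- st$Tb * st$A
            rT[J] <- sum(st$Tb)
        } else {
            L <- L + 1L
            members[[L]] <- gi
            st <- .lc1ClusterStats(gi, B, D)
            Tmat[L, ] <- st$Tb
            Vmat[L, ] <- st$Tb * st$A
            rT[L] <- sum(st$Tb)
        }
    }
    keep <- which(lengths(members[seq_len(L)]) >= minSize)
    if (!length(keep)) stop("no qualitative gene cluster survives pruning")
    list(members = members[keep],
        templates = Tmat[keep, , drop = FALSE])
}

#' Edges of the qualitative gene similarity graph
#'
#' Sorts genes by decreasing zero count, scores windowed pairs by
#' Hamming similarity of their binary patterns, and keeps the top
#' `pairKeepFrac` fraction of all gene pairs (`floor(pairKeepFrac *
#' m(m-1)/2)`; 1999 edges for the default one-thousandth at m = 2000).
#'
#' @param E an [ExpressionMatrix-class].
#' @param params a [ScqaParams-class].
#' @return A data.frame with columns `gene_i`, `gene_j` (original gene
#'   indices) and `score`, one row per retained edge.
#' @export
genePairEdges <- function(E, params = scqaParams()) {
    B <- binarizeMatrix(E)
    m <- nrow(B)
    if (m < 2L) stop("at least two genes are required")
    ord <- .orderByZeros(B)
    w <- round(params@windowFrac * m)
    pairs <- .windowedPairScoresBinary(B[ord, , drop = FALSE], w)
    kept <- .topPairs(pairs, m, params@pairKeepFrac, minKeep = 1L)
    data.frame(gene_i = ord[kept$p], gene_j = ord[kept$q],
        score = kept$score)
}

#' Construct qualitative landmarks (Q1)
#'
#' Clusters genes by shared binary dropout patterns. Genes are sorted by
#' decreasing zero count; windowed pairs are scored by Hamming similarity;
#' the top thousandth of all pairs become edges of a gene graph whose
#' connected components (size > 2) seed the clusters. Remaining genes join
#' the most similar cluster when the template/subsidiary similarity
#' strictly exceeds `rho`, or open new singleton clusters; clusters with
#' fewer than `minGeneCluster` genes are dropped. Each retained cluster's
#' binarized template becomes one column of the qualitative cell-landmark
#' matrix Q1.
#'
#' @param E a scaled [ExpressionMatrix-class] (see [preprocess()]).
#' @param params a [ScqaParams-class].
#' @return A [LandmarkMatrix-class] of type `"qualitative"` (cells x
#'   landmarks, 0/1 entries).
#' @examples
#' sim <- simulateCells(syntheticSpec(seed = 1L))
#' D <- preprocess(sim$expr, scqaParams())
#' Q1 <- qualitativeLandmarks(D, scqaParams())
#' Q1
#' @export
qualitativeLandmarks <- function(E, params = scqaParams()) {
    stopifnot(is(E, "ExpressionMatrix"))
    D <- exprValues(E)
    B <- binarizeMatrix(E)
    m <- nrow(B)
    if (m < 2L) stop("at least two genes are required")
    kept <- genePairEdges(E, params)
    ord <- .orderByZeros(B)
    edges <- cbind(kept$gene_i, kept$gene_j)
    comps <- .pairComponents(edges, m)
    init <- comps[lengths(comps) >= 3L]
    inInit <- unlist(init, use.names = FALSE)
    unassigned <- ord[!(ord %in% inInit)]
    res <- .lc1Assign(init, unassigned, B, D, params@rho,
        params@minGeneCluster)
    vals <- t(res$templates)
    rownames(vals) <- colnames(B)
    colnames(vals) <- paste0("L", seq_len(ncol(vals)))
    new("LandmarkMatrix",
        values = vals,
        type = "qualitative",
        memberships = lapply(res$members, function(i) rownames(B)[i]),
        groups = rep(NA_integer_, ncol(vals))
    )
}
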