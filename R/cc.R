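# Cluster constructor: directed kNN cell graph from the quantitative
# landmark matrix, seed generation guided by the qualitative grouping,
# bidirectional two-hop label propagation, pruning/merging, expansion,
# iterated to a stable partition.
#
# Internal state:
#   graph  - list(n, S, ON, IN, kOut, density)
#   labels - integer(n), 0 = unlabeled, >0 = cluster id
#   clusters - list of member index vectors, indexed by label

# Pearson similarity between cell rows of a landmark matrix; a constant
# row is defined to have similarity 0 to everything
.cellSimilarity <- function(Q) {
    sds <- apply(Q, 1L, stats::sd)
    S <- suppressWarnings(stats::cor(t(Q)))
    S[is.na(S)] <- 0
    const <- sds == 0
    S[const, ] <- 0
    S[, const] <- 0
    S
}

# out-degree rule: 0.1 n out-neighbours below 10,000 cells, 0.05 n at or
# above, floored and clamped to [1, n-1]
.kOutRule <- function(n) {
    kOut <- if (n < 10000L) floor(0.1 * n) else floor(0.05 * n)
    min(max(1L, as.integer(kOut)), n - 1L)
}

# directed kNN graph; neighbours ranked by similarity with ties broken by
# cell index
.buildCellGraph <- function(Q) {
    n <- nrow(Q)
    if (n < 3L) stop("at least 3 cells are required")
    if (ncol(Q) < 2L)
        stop("at least 2 landmarks are required to correlate cells")
    S <- .cellSimilarity(Q)
    kOut <- .kOutRule(n)
    ON <- vector("list", n)
    for (i in seq_len(n)) {
        ord <- order(-S[i, ], seq_len(n))
        ord <- ord[ord != i]
        ON[[i]] <- ord[seq_len(kOut)]
    }
    IN <- vector("list", n)
    src <- rep(seq_len(n), each = kOut)
    dst <- unlist(ON, use.names = FALSE)
    for (i in seq_len(n)) IN[[i]] <- integer(0)
    sp <- split(src, dst)
    IN[as.integer(names(sp))] <- lapply(sp, as.integer)
    dens <- vapply(seq_len(n), function(i) mean(S[i, ON[[i]]]), 0)
    list(n = n, S = S, ON = ON, IN = IN, kOut = kOut, density = dens)
}

# partition cells by exact equality of their (binary) grouping rows;
# groups ordered by smallest member index
.groupCells <- function(Qbin) {
    key <- apply(Qbin, 1L, paste, collapse = ",")
    sp <- split(seq_len(nrow(Qbin)), key)
    sp <- lapply(sp, as.integer)
    unname(sp[order(vapply(sp, min, 1L))])
}

# seed threshold beta = min over qualitative groups of the within-group
# maximum density; candidates are the nodes at or above beta. Candidates
# that are mutually neighbouring in the graph AND whose qualitative
# patterns differ in at most one landmark are unioned transitively into
# one seed; each seed becomes an initial labelled cluster.
.generateSeeds <- function(graph, Qbin) {
    groups <- .groupCells(Qbin)
    dens <- graph$density
    beta <- min(vapply(groups, function(g) max(dens[g]), 0))
    cand <- which(dens >= beta)
    nc <- length(cand)
    adj <- matrix(FALSE, nc, nc)
    for (a in seq_len(nc)) {
        for (b in seq_len(nc)) {
            if (a < b) {
                i <- cand[a]; j <- cand[b]
                ok <- sum(Qbin[i, ] != Qbin[j, ]) <= 1 &&
                    j %in% graph$ON[[i]] && i %in% graph$ON[[j]]
                adj[a, b] <- adj[b, a] <- ok
            }
        }
    }
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    memb <- igraph::components(g)$membership
    comps <- split(cand, memb)
    comps <- lapply(comps, sort)
    comps <- comps[order(vapply(comps, min, 1L))]
    labels <- integer(graph$n)
    for (j in seq_along(comps)) labels[comps[[j]]] <- j
    list(labels = labels, clusters = unname(comps), beta = beta)
}

# accumulate, per cluster, the sum of weights w and the count of the
# labelled targets idx (cluster ids); returns list(num, den)
.accumulateByLabel <- function(w, idx, nClusters) {
    num <- numeric(nClusters)
    if (length(idx)) {
        rs <- rowsum(w, idx)
        num[as.integer(rownames(rs))] <- rs
    }
    list(num = num, den = tabulate(idx, nClusters))
}

# one direction of the node-cluster similarity: direct edges into the
# cluster plus two-hop paths through unlabelled neighbours, the sum of
# far-edge weights divided by the number of paths
.directionTerm <- function(i, nbrs, nbrLists, S, fromNode, labels,
                           nClusters) {
    labs <- labels[nbrs]
    labelled <- nbrs[labs > 0L]
    w1 <- if (fromNode) S[i, labelled] else S[labelled, i]
    acc <- .accumulateByLabel(w1, labels[labelled], nClusters)
    num <- acc$num; den <- acc$den
    hop <- nbrs[labs == 0L]
    if (length(hop)) {
        allP <- unlist(nbrLists[hop], use.names = FALSE)
        allR <- rep(hop, lengths(nbrLists[hop]))
        labP <- labels[allP]
        sel <- labP > 0L
        if (any(sel)) {
            w2 <- if (fromNode) S[cbind(allR[sel], allP[sel])]
                else S[cbind(allP[sel], allR[sel])]
            acc2 <- .accumulateByLabel(w2, labP[sel], nClusters)
            num <- num + acc2$num
            den <- den + acc2$den
        }
    }
    ifelse(den > 0, num / den, 0)
}

# bidirectional node-cluster similarity (two-hop label propagation score):
# alpha weighs paths from the node into the cluster (out-edges), 1-alpha
# paths from the cluster into the node (in-edges)
.nodeClusterSimilarity <- function(i, graph, labels, nClusters, alpha) {
    outT <- .directionTerm(i, graph$ON[[i]], graph$ON, graph$S,
        TRUE, labels, nClusters)
    inT <- .directionTerm(i, graph$IN[[i]], graph$IN, graph$S,
        FALSE, labels, nClusters)
    alpha * outT + (1 - alpha) * inT
}

# similarity of an unlabelled node to the unlabelled set (excluding
# itself): mean weight to unlabelled out-neighbours and from unlabelled
# in-neighbours, mixed by alpha; empty sets contribute 0
.nodeUnlabeledSimilarity <- function(i, graph, labels, alpha) {
    onU <- graph$ON[[i]][labels[graph$ON[[i]]] == 0L]
    inU <- graph$IN[[i]][labels[graph$IN[[i]]] == 0L]
    outT <- if (length(onU)) mean(graph$S[i, onU]) else 0
    inT <- if (length(inU)) mean(graph$S[inU, i]) else 0
    alpha * outT + (1 - alpha) * inT
}

# one full propagation sweep over unlabelled nodes in decreasing-density
# order: a node joins its best cluster only if the similarity strictly
# exceeds its similarity to the unlabelled set
.propagateSweep <- function(labels, clusters, graph, alpha) {
    unl <- which(labels == 0L)
    unl <- unl[order(-graph$density[unl], unl)]
    changed <- 0L
    for (i in unl) {
        if (labels[i] != 0L) next
        nClusters <- length(clusters)
        if (nClusters == 0L) break
        sims <- .nodeClusterSimilarity(i, graph, labels, nClusters, alpha)
        J <- which.max(sims)
        su <- .nodeUnlabeledSimilarity(i, graph, labels, alpha)
        if (sims[J] > su) {
            labels[i] <- J
            clusters[[J]] <- c(clusters[[J]], i)
            changed <- changed + 1L
        }
    }
    list(labels = labels, clusters = clusters, changed = changed)
}

# drop empty clusters and renumber labels compactly, preserving order
.compactClusters <- function(labels, clusters) {
    keep <- which(lengths(clusters) > 0L)
    newLab <- integer(length(clusters))
    newLab[keep] <- seq_along(keep)
    pos <- labels > 0L
    labels[pos] <- newLab[labels[pos]]
    list(labels = labels, clusters = clusters[keep])
}

# number of directed edges from members of `from` into each cluster
.edgeCountsInto <- function(members, graph, labels, nClusters) {
    allN <- unlist(graph$ON[members], use.names = FALSE)
    labN <- labels[allN]
    tabulate(labN[labN > 0L], nClusters)
}

# number of unordered adjacent pairs within a member set (a pair counts
# once whether one or both directed edges are present)
.internalPairCount <- function(members, graph) {
    memb <- logical(graph$n)
    memb[members] <- TRUE
    a <- rep(members, each = graph$kOut)
    b <- unlist(graph$ON[members], use.names = FALSE)
    sel <- memb[b]
    if (!any(sel)) return(0L)
    a <- a[sel]; b <- b[sel]
    length(unique(pmin(a, b) * (graph$n + 1) + pmax(a, b)))
}

# dissolve clusters below minSize (members return to the unlabelled set),
# then merge: visiting clusters from smallest, a cluster whose directed
# edges into some strictly larger cluster outnumber its internal
# (unordered) adjacencies is absorbed; clusters that have absorbed others
# are never themselves absorbed
.pruneAndMerge <- function(labels, clusters, graph, minSize) {
    for (j in seq_along(clusters)) {
        if (length(clusters[[j]]) < minSize) {
            labels[clusters[[j]]] <- 0L
            clusters[[j]] <- integer(0)
        }
    }
    st <- .compactClusters(labels, clusters)
    labels <- st$labels; clusters <- st$clusters
    if (!length(clusters)) stop("all cell clusters were pruned away")
    nClusters <- length(clusters)
    assimilated <- logical(nClusters)
    alive <- rep(TRUE, nClusters)
    visit <- order(lengths(clusters), seq_len(nClusters))
    for (j in visit) {
        if (!alive[j] || assimilated[j]) next
        sizes <- ifelse(alive, lengths(clusters), 0L)
        larger <- which(alive & sizes > sizes[j])
        larger <- larger[larger != j]
        if (!length(larger)) next
        cnts <- .edgeCountsInto(clusters[[j]], graph, labels, nClusters)
        internal <- .internalPairCount(clusters[[j]], graph)
        outc <- cnts[larger]
        if (max(outc) > internal) {
            J <- larger[which.max(outc)]
            labels[clusters[[j]]] <- J
            clusters[[J]] <- sort(c(clusters[[J]], clusters[[j]]))
            clusters[[j]] <- integer(0)
            alive[j] <- FALSE
            assimilated[J] <- TRUE
        }
    }
    .compactClusters(labels, clusters)
}

# per-cluster average internal out-degree A(Cj)
.clusterInternalDegree <- function(clusters, graph, labels) {
    nClusters <- length(clusters)
    if (!nClusters) return(numeric(0))
    allN <- unlist(graph$ON, use.names = FALSE)
    labR <- rep(labels, each = graph$kOut)
    labN <- labels[allN]
    sel <- labR > 0L & labR == labN
    internal <- tabulate(labR[sel], nClusters)
    internal / pmax(lengths(clusters), 1L)
}

# expansion: every remaining unlabelled node (decreasing density) either
# joins the retained cluster where its out-neighbour count most exceeds
# the cluster's average internal degree, or founds a new singleton
# cluster when every difference is negative. Counts and degrees are
# evaluated against the retained clusters as they stood at entry: the
# comparison is defined for the clusters that survived pruning and
# merging, so mid-pass assignments neither distort later counts nor act
# as attractors (a fresh singleton's internal degree of 0 would
# otherwise out-compete every real cluster)
.expandClusters <- function(labels, clusters, graph) {
    unl <- which(labels == 0L)
    unl <- unl[order(-graph$density[unl], unl)]
    labels0 <- labels
    nClusters0 <- length(clusters)
    A0 <- .clusterInternalDegree(clusters, graph, labels)
    for (i in unl) {
        cnts <- tabulate(labels0[graph$ON[[i]]], nClusters0)
        diffs <- cnts - A0
        if (nClusters0 == 0L || all(diffs < 0)) {
            clusters[[length(clusters) + 1L]] <- i
            labels[i] <- length(clusters)
        } else {
            J <- which.max(diffs)
            labels[i] <- J
            clusters[[J]] <- c(clusters[[J]], i)
        }
    }
    list(labels = labels, clusters = clusters)
}

# final cleanup: clusters still below the minimum size (which the method
# itself deems too small) are dissolved and each orphan attached to the
# cluster holding most of its out-neighbours
.absorbResidual <- function(labels, clusters, graph, minSize) {
    small <- which(lengths(clusters) < minSize)
    if (length(small) && length(small) < length(clusters)) {
        orphans <- unlist(clusters[small], use.names = FALSE)
        for (j in small) {
            labels[clusters[[j]]] <- 0L
            clusters[[j]] <- integer(0)
        }
        st <- .compactClusters(labels, clusters)
        labels <- st$labels; clusters <- st$clusters
        orphans <- orphans[order(-graph$density[orphans], orphans)]
        for (i in orphans) {
            cnts <- tabulate(labels[graph$ON[[i]]], length(clusters))
            J <- which.max(cnts)
            labels[i] <- J
            clusters[[J]] <- c(clusters[[J]], i)
        }
    }
    list(labels = labels, clusters = clusters)
}

# relabel clusters 0-based, numbered by first occurrence in cell order
.finalizeLabels <- function(labels, n) {
    first <- unique(labels)
    map <- stats::setNames(seq_along(first) - 1L, first)
    as.integer(map[as.character(labels)])
}

#' Cluster cells from landmark matrices
#'
#' Builds a directed k-nearest-neighbour graph over cells (Pearson
#' similarity of rows of the propagation matrix), generates seed clusters
#' from high-density cells guided by the groups of identical rows in the
#' binary grouping matrix, then repeats a three-step cycle until the
#' partition is stable: bidirectional two-hop label propagation over
#' unlabelled cells, dissolution of small clusters and merging of
#' clusters better connected to a larger cluster than internally, and
#' expansion assigning every remaining cell to the cluster whose average
#' internal connectivity it matches (or to a new cluster when it matches
#' none). The number of clusters is never preset.
#'
#' @param propagation a [LandmarkMatrix-class] (or cells x landmarks
#'   matrix) whose rows define cell-cell similarity; normally Q2.
#' @param grouping a [LandmarkMatrix-class] (or binary cells x landmarks
#'   matrix) whose identical rows define the seed groups; normally Q1.
#' @param params a [ScqaParams-class].
#' @return Integer vector of 0-based contiguous cluster labels, one per
#'   cell, named by cell id when available.
#' @export
clusterCells <- function(propagation, grouping, params = scqaParams()) {
    Q <- if (is(propagation, "LandmarkMatrix"))
        landmarkValues(propagation) else as.matrix(propagation)
    Gb <- if (is(grouping, "LandmarkMatrix"))
        landmarkValues(grouping) else as.matrix(grouping)
    if (nrow(Q) != nrow(Gb))
        stop("propagation and grouping matrices disagree on cell count")
    graph <- .buildCellGraph(Q)
    mcs <- .resolveMinClusterSize(params, graph$n)
    sd <- .generateSeeds(graph, Gb)
    labels <- sd$labels
    clusters <- sd$clusters
    converged <- FALSE
    for (outer in seq_len(params@maxIter)) {
        prev <- labels
        repeat {
            st <- .propagateSweep(labels, clusters, graph, params@alpha)
            labels <- st$labels; clusters <- st$clusters
            if (st$changed == 0L) break
        }
        st <- .pruneAndMerge(labels, clusters, graph, mcs)
        st <- .expandClusters(st$labels, st$clusters, graph)
        labels <- st$labels; clusters <- st$clusters
        if (identical(labels, prev)) { converged <- TRUE; break }
    }
    if (!converged)
        warning("label propagation did not converge within maxIter cycles")
    st <- .absorbResidual(labels, clusters, graph, mcs)
    st <- .compactClusters(st$labels, st$clusters)
    out <- .finalizeLabels(st$labels, graph$n)
    names(out) <- rownames(Q)
    out
}

#' Run the full scQA pipeline
#'
#' Pre-processes the matrix (unless already scaled), constructs the
#' qualitative (Q1) and quantitative (Q2) landmark matrices, and clusters
#' cells with the seeded label-propagation cluster constructor. The number
#' of clusters is not preset. Ablation modes use a single landmark
#' constructor: `lc1_only` builds the cell graph and seeds from Q1;
#' `lc2_only` propagates on Q2 and groups cells by the binarized
#' (positive-entry) form of Q2.
#'
#' @param E an [ExpressionMatrix-class]; raw values are pre-processed,
#'   already-scaled matrices are used as-is.
#' @param params a [ScqaParams-class].
#' @param mode `"full"`, `"lc1_only"` or `"lc2_only"`.
#' @return A [ScqaResult-class] with 0-based per-cell labels, the landmark
#'   matrices, and the parameters used.
#' @examples
#' sim <- simulateCells(syntheticSpec(seed = 1L))
#' res <- runScqa(sim$expr)
#' res
#' table(cellLabels(res), sim$labels)
#' @export
runScqa <- function(E, params = scqaParams(),
                    mode = c("full", "lc1_only", "lc2_only")) {
    mode <- match.arg(mode)
    stopifnot(is(E, "ExpressionMatrix"))
    if (!isScaled(E)) E <- preprocess(E, params)
    Q1 <- NULL; Q2 <- NULL
    if (mode %in% c("full", "lc1_only"))
        Q1 <- qualitativeLandmarks(E, params)
    if (mode %in% c("full", "lc2_only"))
        Q2 <- quantitativeLandmarks(E, params)
    labels <- switch(mode,
        full = clusterCells(Q2, Q1, params),
        lc1_only = clusterCells(Q1, Q1, params),
        lc2_only = clusterCells(Q2,
            (landmarkValues(Q2) > 0) + 0, params)
    )
    new("ScqaResult",
        labels = unname(labels),
        cellIDs = cellIDs(E),
        Q1 = Q1, Q2 = Q2,
        params = params,
        mode = mode
    )
}
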