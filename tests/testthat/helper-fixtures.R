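# Shared fixtures, all generated in code.

# tiny expression matrix with named dims
toyMatrix <- function(vals, nr, nc) {
    m <- matrix(vals, nr, nc)
    dimnames(m) <- list(sprintf("g%d", seq_len(nr)),
        sprintf("c%d", seq_len(nc)))
    m
}

# small planted-type simulation used by several unit tests (3 types,
# fast); distinct from the default 5-type bench used in acceptance
smallSim <- function(seed = 11L) {
    simulateCells(syntheticSpec(nTypes = 3L, cellsPerType = 50L,
        nMarkersPerType = 20L, nHousekeeping = 40L, nNoiseGenes = 80L,
        seed = seed))
}

# quasi-trend fixture: blocks of genes that are monotone transforms of a
# shared profile plus noise, against a sparse unstructured background
quasiTrendFixture <- function(nBlocks = 4L, genesPerBlock = 50L,
                              nCells = 200L, noiseSd = 0.05) {
    blocks <- lapply(seq_len(nBlocks), function(b) {
        set.seed(100L + b)
        base <- stats::runif(nCells)
        quasiTrendBlock(genesPerBlock, base, noiseSd = noiseSd,
            seed = 200L + b)
    })
    mat <- do.call(rbind, blocks)
    rownames(mat) <- sprintf("QT%d_%d", rep(seq_len(nBlocks),
        each = genesPerBlock), rep(seq_len(genesPerBlock), nBlocks))
    set.seed(7L)
    bg <- matrix(0, 100L, nCells)
    on <- matrix(stats::runif(100L * nCells) < 0.4, 100L, nCells)
    bg[on] <- stats::rlnorm(sum(on), 0, 0.5)
    rownames(bg) <- sprintf("BG_%d", seq_len(100L))
    expressionMatrix(rbind(mat, bg),
        cellIDs = sprintf("cell%d", seq_len(nCells)))
}

# cache expensive full-pipeline runs within one test session
.runCache <- new.env(parent = emptyenv())
cachedFullRun <- function(seed) {
    key <- paste0("s", seed)
    if (is.null(.runCache[[key]])) {
        sim <- simulateCells(syntheticSpec(seed = seed))
        res <- suppressWarnings(runScqa(sim$expr))
        .runCache[[key]] <- list(sim = sim, res = res)
    }
    .runCache[[key]]
}

# literal O(n^2) pair-classification oracle for the external metrics
pairCountsLoop <- function(I, A) {
    n <- length(I)
    a <- b <- cc <- d <- 0L
    for (i in seq_len(n - 1L)) {
        for (j in (i + 1L):n) {
            sameI <- I[i] == I[j]
            sameA <- A[i] == A[j]
            if (sameI && sameA) a <- a + 1L
            else if (!sameI && sameA) b <- b + 1L
            else if (sameI && !sameA) cc <- cc + 1L
            else d <- d + 1L
        }
    }
    list(a = a, b = b, c = cc, d = d)
}

# brute-force enumeration of all directed paths of length <= 2 from/to a
# node for the label-propagation similarity (independent of the package's
# accumulation shortcut)
nodeClusterSimBrute <- function(i, graph, labels, j, alpha) {
    ONi <- graph$ON[[i]]; INi <- graph$IN[[i]]
    Cj <- which(labels == j)
    U <- which(labels == 0L)
    numO <- 0; denO <- 0
    for (r in ONi) {
        if (r %in% Cj) { numO <- numO + graph$S[i, r]; denO <- denO + 1 }
        if (r %in% U) {
            for (p in graph$ON[[r]]) {
                if (p %in% Cj) {
                    numO <- numO + graph$S[r, p]; denO <- denO + 1
                }
            }
        }
    }
    numI <- 0; denI <- 0
    for (r in INi) {
        if (r %in% Cj) { numI <- numI + graph$S[r, i]; denI <- denI + 1 }
        if (r %in% U) {
            for (p in graph$IN[[r]]) {
                if (p %in% Cj) {
                    numI <- numI + graph$S[p, r]; denI <- denI + 1
                }
            }
        }
    }
    outT <- if (denO > 0) numO / denO else 0
    inT <- if (denI > 0) numI / denI else 0
    alpha * outT + (1 - alpha) * inT
}

# random small directed graph in the internal representation
randomCellGraph <- function(n, kOut, seed) {
    set.seed(seed)
    S <- matrix(stats::runif(n * n, -0.2, 1), n, n)
    S <- (S + t(S)) / 2
    diag(S) <- 1
    ON <- lapply(seq_len(n), function(i) {
        ord <- order(-S[i, ], seq_len(n))
        ord <- ord[ord != i]
        ord[seq_len(kOut)]
    })
    IN <- vector("list", n)
    for (i in seq_len(n)) IN[[i]] <- integer(0)
    for (i in seq_len(n)) for (r in ON[[i]])
        IN[[r]] <- c(IN[[r]], i)
    dens <- vapply(seq_len(n), function(i) mean(S[i, ON[[i]]]), 0)
    list(n = n, S = S, ON = ON, IN = IN, kOut = kOut, density = dens)
}
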