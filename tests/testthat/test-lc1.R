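test_that("binarization thresholds at zero", {
    m <- rbind(a = c(0, 0.3, 0.8), b = c(0, 0, 0), c = c(1, 2, 3))
    colnames(m) <- c("c1", "c2", "c3")
    B <- binarizeMatrix(expressionMatrix(m))
    expect_equal(unname(B["a", ]), c(0, 1, 1))
    expect_equal(unname(B["b", ]), c(0, 0, 0))
    expect_equal(unname(B["c", ]), c(1, 1, 1))
})

test_that("genes sort by decreasing zero count with index tie-break", {
    B <- rbind(c(1, 0, 0, 0), c(0, 0, 0, 0), c(1, 1, 1, 0))
    expect_equal(scQA:::.orderByZeros(B), c(2L, 1L, 3L))
    # all-equal zero counts -> identity order
    Bt <- rbind(c(1, 0), c(0, 1), c(1, 0))
    expect_equal(scQA:::.orderByZeros(Bt), 1:3)
    # zero-count sequence along the order is non-increasing on random input
    set.seed(3)
    for (rep in 1:5) {
        Br <- matrix(rbinom(300, 1, 0.5), 30, 10)
        z <- rowSums(Br == 0)
        expect_true(all(diff(z[scQA:::.orderByZeros(Br)]) <= 0))
    }
})

test_that("windowed pair scores equal one minus normalized Hamming distance", {
    # hand-counted example
    B <- rbind(c(1, 0, 1, 1), c(1, 1, 1, 0))
    sc <- scQA:::.windowedPairScoresBinary(B, 1L)
    expect_equal(sc$score, 0.5)
    # identical and complementary vectors
    B2 <- rbind(c(1, 0, 1), c(1, 0, 1), c(0, 1, 0))
    sc2 <- scQA:::.windowedPairScoresBinary(B2, 2L)
    expect_equal(sc2$score[sc2$p == 1 & sc2$q == 2], 1)
    expect_equal(sc2$score[sc2$p == 1 & sc2$q == 3], 0)
    # oracle: literal per-pair Hamming count on random matrices
    set.seed(8)
    for (rep in 1:3) {
        Br <- matrix(rbinom(20 * 7, 1, 0.4), 20, 7)
        w <- 3L
        sc <- scQA:::.windowedPairScoresBinary(Br, w)
        for (k in seq_len(nrow(sc))) {
            h <- sum(Br[sc$p[k], ] != Br[sc$q[k], ])
            expect_equal(sc$score[k], 1 - h / ncol(Br))
        }
        # window truncates at the ends: every pair within w positions
        expect_true(all(sc$q - sc$p <= w))
    }
})

test_that("gene graph keeps the top thousandth of pairs, ties by index", {
    # m = 200 -> floor(19900/1000) = 19 edges
    set.seed(10)
    m200 <- matrix(rbinom(200 * 30, 1, 0.5), 200, 30,
        dimnames = list(sprintf("g%d", 1:200), sprintf("c%d", 1:30)))
    e <- genePairEdges(expressionMatrix(m200))
    expect_equal(nrow(e), 19L)
    # all-equal scores: first pairs in enumeration order are kept
    pairs <- data.frame(p = c(1L, 1L, 2L), q = c(2L, 3L, 3L),
        score = c(0.5, 0.5, 0.5))
    kept <- scQA:::.topPairs(pairs, 3L, 2 / 3)
    expect_equal(nrow(kept), 2L)
    expect_equal(kept$p, c(1L, 1L))
    expect_equal(kept$q, c(2L, 3L))
})

test_that("initial clusters keep components above two genes and compute templates", {
    # components of sizes {3, 2, 1} over 6 genes
    edges <- cbind(c(1L, 1L, 4L), c(2L, 3L, 5L))
    comps <- scQA:::.pairComponents(edges, 6L)
    sizes <- sort(unname(lengths(comps)), decreasing = TRUE)
    expect_equal(sizes, c(3L, 2L, 1L))
    # template: members' binary rows [1,0,1], [1,1,1]
    B <- rbind(c(1, 0, 1), c(1, 1, 1))
    D <- rbind(c(0.6, 0, 0.9), c(0.2, 0.8, 1))
    st <- scQA:::.lc1ClusterStats(1:2, B, D)
    expect_equal(st$tmean, c(1, 0.5, 1))
    expect_equal(st$Tb, c(1, 1, 1))
    # subsidiary vector: max(0.5 - mean expression, 0)
    expect_equal(st$A, c(max(0.5 - 0.4, 0), max(0.5 - 0.4, 0), 0))
})

test_that("gene-cluster similarity follows the three-case increment rule", {
    # worked example: Gi=[1,0,0], T=[1,1,0], A2=0.2 -> (1+0.2+1)/3
    g <- c(1, 0, 0)
    Tb <- c(1, 1, 0)
    A <- c(0, 0.2, 0)
    expect_equal(scQA:::.geneClusterSimilarity(g, Tb, A), 2.2 / 3)
    expect_equal(scQA:::.geneClusterSimilarity(Tb, Tb, A), 1)
    expect_equal(scQA:::.geneClusterSimilarity(1 - Tb, Tb, c(0, 0, 0)), 0)
    # oracle equivalence on random instances
    set.seed(12)
    for (rep in 1:20) {
        n <- 15L
        g <- rbinom(n, 1, 0.5)
        Tb <- rbinom(n, 1, 0.5)
        A <- runif(n, 0, 0.5)
        mu <- numeric(n)
        for (k in 1:n) {
            mu[k] <- if (g[k] == Tb[k]) 1
                else if (g[k] == 1 && Tb[k] == 0) 0
                else A[k]
        }
        expect_equal(scQA:::.geneClusterSimilarity(g, Tb, A), mean(mu))
        expect_gte(scQA:::.geneClusterSimilarity(g, Tb, A), 0)
        expect_lte(scQA:::.geneClusterSimilarity(g, Tb, A), 1)
    }
})

test_that("assignment joins only above rho, singletons attract, small clusters pruned", {
    n <- 10L
    # cluster of 3 identical genes; candidate matching at 8/10 cells
    base <- c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0)
    near <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 1)   # differs at 2 -> S = 0.8
    B <- rbind(base, base, base, near)
    D <- B * 0.9
    res <- scQA:::.lc1Assign(list(1:3), 4L, B, D, rho = 0.7, minSize = 3L)
    expect_equal(res$members[[1]], 1:4)
    # S exactly rho does not join (strict inequality): S = 0.7 via 3 diffs
    bound <- c(1, 1, 1, 1, 0, 0, 0, 1, 1, 1)  # differs at 3 -> S = 0.7
    B2 <- rbind(base, base, base, bound)
    res2 <- scQA:::.lc1Assign(list(1:3), 4L, B2, B2 * 0.9, rho = 0.7,
        minSize = 1L)
    expect_equal(lengths(res2$members), c(3L, 1L))
    # pruning: sizes {3, 1} with minSize 3 -> one cluster retained
    res3 <- scQA:::.lc1Assign(list(1:3), 4L, B2, B2 * 0.9, rho = 0.7,
        minSize = 3L)
    expect_equal(length(res3$members), 1L)
    # a singleton created mid-pass attracts an identical later gene
    other <- 1 - base
    B3 <- rbind(base, base, base, other, other, other)
    res4 <- scQA:::.lc1Assign(list(1:3), 4:6, B3, B3 * 0.9, rho = 0.7,
        minSize = 3L)
    expect_equal(length(res4$members), 2L)
    expect_equal(sort(res4$members[[2]]), 4:6)
})

test_that("Q1 columns are the recomputed binary templates of their members", {
    sim <- smallSim()
    D <- suppressWarnings(preprocess(sim$expr, scqaParams()))
    Q1 <- qualitativeLandmarks(D, scqaParams())
    v <- landmarkValues(Q1)
    expect_true(all(v %in% c(0, 1)))
    expect_equal(nrow(v), ncol(exprValues(D)))
    B <- binarizeMatrix(D)
    mem <- memberships(Q1)
    for (j in seq_along(mem)) {
        rows <- B[mem[[j]], , drop = FALSE]
        expect_equal(unname(v[, j]),
            unname((colMeans(rows) >= 0.5) + 0))
    }
    # genes belong to at most one landmark
    allg <- unlist(mem)
    expect_equal(anyDuplicated(allg), 0L)
})

test_that("qualitative landmarks are deterministic and recover planted patterns", {
    # three planted binary patterns, 30 genes each with 5% bit flips,
    # plus unstructured genes
    set.seed(21)
    n <- 90L
    patterns <- list(
        rep(c(1, 0, 0), each = 30),
        rep(c(0, 1, 0), each = 30),
        rep(c(0, 0, 1), each = 30)
    )
    rows <- list()
    for (t in 1:3) {
        for (g in 1:30) {
            r <- patterns[[t]]
            flip <- runif(n) < 0.05
            r[flip] <- 1 - r[flip]
            rows[[sprintf("P%d_%d", t, g)]] <- r
        }
    }
    for (g in 1:20)
        rows[[sprintf("R_%d", g)]] <- rbinom(n, 1, 0.4)
    m <- do.call(rbind, rows)
    colnames(m) <- sprintf("c%d", seq_len(n))
    E <- expressionMatrix(m, isScaled = TRUE)
    Q1a <- qualitativeLandmarks(E, scqaParams())
    Q1b <- qualitativeLandmarks(E, scqaParams())
    expect_identical(landmarkValues(Q1a), landmarkValues(Q1b))
    v <- landmarkValues(Q1a)
    for (t in 1:3) {
        hits <- apply(v, 2L, function(col)
            identical(unname(col), patterns[[t]]))
        expect_true(any(hits))
    }
})
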