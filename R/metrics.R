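# External clustering validation. All four indices derive from the
# classification of the n(n-1)/2 cell pairs into:
#   a - same cluster in both partitions
#   b - same in the reference, split in the prediction
#   c - split in the reference, same in the prediction
#   d - split in both
# computed via the contingency-table shortcut (tested against the literal
# O(n^2) pair loop).

.checkPartitions <- function(I, A) {
    if (length(I) != length(A))
        stop("partitions must label the same cells")
    if (length(I) < 2L) stop("at least two cells are required")
}

#' Pair-confusion counts between two partitions
#'
#' @param I predicted cluster labels (any atomic type).
#' @param A reference labels of the same length.
#' @return A list with integer fields `a`, `b`, `c`, `d` (see source) and
#'   `ri`, the Rand index `(a+d)/C(n,2)`.
#' @export
pairCounts <- function(I, A) {
    .checkPartitions(I, A)
    n <- length(I)
    tab <- table(I, A)
    total <- choose(n, 2)
    sumSq <- sum(choose(tab, 2))                      # a
    rowS <- sum(choose(rowSums(tab), 2))              # a + c (same in I)
    colS <- sum(choose(colSums(tab), 2))              # a + b (same in A)
    a <- sumSq
    b <- colS - sumSq
    c <- rowS - sumSq
    d <- total - a - b - c
    list(a = a, b = b, c = c, d = d, ri = (a + d) / total)
}

#' Adjusted Rand index
#'
#' Rand index corrected for chance agreement under the permutation model
#' (Hubert-Arabie form). When the correction denominator is zero the index
#' is defined as 1 for identical partitions and 0 otherwise.
#'
#' @inheritParams pairCounts
#' @return A number `<= 1`; 1 for identical partitions, about 0 for random
#'   agreement.
#' @export
ari <- function(I, A) {
    .checkPartitions(I, A)
    n <- length(I)
    tab <- table(I, A)
    sumSq <- sum(choose(tab, 2))
    rowS <- sum(choose(rowSums(tab), 2))
    colS <- sum(choose(colSums(tab), 2))
    total <- choose(n, 2)
    expected <- rowS * colS / total
    maxIdx <- (rowS + colS) / 2
    if (maxIdx == expected) {
        pc <- pairCounts(I, A)
        return(if (pc$b == 0 && pc$c == 0) 1 else 0)
    }
    (sumSq - expected) / (maxIdx - expected)
}

# plug-in entropy of a partition, natural log
.entropy <- function(x) {
    p <- table(x) / length(x)
    p <- p[p > 0]
    -sum(p * log(p))
}

#' Normalized mutual information
#'
#' `2 MI / (H(I) + H(A))` with plug-in entropies (natural log). Defined as
#' 1 when both partitions are a single cluster.
#'
#' @inheritParams pairCounts
#' @return A number in `[0,1]`.
#' @export
nmi <- function(I, A) {
    .checkPartitions(I, A)
    n <- length(I)
    hI <- .entropy(I)
    hA <- .entropy(A)
    if (hI + hA == 0) return(1)
    tab <- table(I, A) / n
    pI <- rowSums(tab)
    pA <- colSums(tab)
    outer <- pI %o% pA
    pos <- tab > 0
    mi <- sum(tab[pos] * log(tab[pos] / outer[pos]))
    2 * mi / (hI + hA)
}

#' Fowlkes-Mallows index
#'
#' `a / sqrt((a+b)(a+c))`; 0 when no pair is jointly clustered (`a = 0`).
#'
#' @inheritParams pairCounts
#' @return A number in `[0,1]`.
#' @export
fmi <- function(I, A) {
    pc <- pairCounts(I, A)
    if (pc$a == 0) return(0)
    pc$a / sqrt((pc$a + pc$b) * (pc$a + pc$c))
}

#' Jaccard index between partitions
#'
#' `a / (a+b+c)`; defined as 1 when all three counts are zero (both
#' partitions all-singleton).
#'
#' @inheritParams pairCounts
#' @return A number in `[0,1]`.
#' @export
ji <- function(I, A) {
    pc <- pairCounts(I, A)
    denom <- pc$a + pc$b + pc$c
    if (denom == 0) return(1)
    pc$a / denom
}

#' All external validation metrics at once
#'
#' @inheritParams pairCounts
#' @return Named numeric vector with elements `ari`, `nmi`, `fmi`, `ji`.
#' @examples
#' truth <- rep(1:3, each = 10)
#' pred <- truth
#' pred[1] <- 2
#' clusterMetrics(pred, truth)
#' @export
clusterMetrics <- function(I, A) {
    c(ari = ari(I, A), nmi = nmi(I, A), fmi = fmi(I, A), ji = ji(I, A))
}
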