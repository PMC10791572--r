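#' Construct an ExpressionMatrix
#'
#' Wraps a genes x cells matrix of non-negative values. Accepts a base
#' matrix, a sparse `Matrix`, or a `SummarizedExperiment` (first assay).
#'
#' @param values genes x cells matrix-like object with non-negative entries.
#' @param geneIDs optional character vector of gene identifiers; taken from
#'   rownames when missing.
#' @param cellIDs optional character vector of cell identifiers; taken from
#'   colnames when missing.
#' @param isScaled logical; whether entries are already log-scaled to
#'   `[0,1]`.
#' @return An [ExpressionMatrix-class].
#' @examples
#' m <- matrix(rpois(12, 3), 4, 3,
#'     dimnames = list(paste0("g", 1:4), paste0("c", 1:3)))
#' expressionMatrix(m)
#' @export
expressionMatrix <- function(values, geneIDs = NULL, cellIDs = NULL,
                             isScaled = FALSE) {
    if (inherits(values, "SummarizedExperiment")) {
        if (!requireNamespace("SummarizedExperiment", quietly = TRUE))
            stop("the SummarizedExperiment package is required for this input")
        values <- SummarizedExperiment::assay(values)
    }
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    if (!is.null(geneIDs)) rownames(values) <- geneIDs
    if (!is.null(cellIDs)) colnames(values) <- cellIDs
    if (is.null(rownames(values)))
        rownames(values) <- paste0("gene", seq_len(nrow(values)))
    if (is.null(colnames(values)))
        colnames(values) <- paste0("cell", seq_len(ncol(values)))
    new("ExpressionMatrix", values = values, isScaled = isScaled)
}

#' Load an expression matrix from disk
#'
#' Dense CSV/TSV files carry gene identifiers in the first column and cell
#' identifiers in the header row. Matrix Market (`mtx`) input is the
#' standard sparse triple: the matrix file (genes as rows) plus companion
#' `genes.tsv` and `barcodes.tsv` whose first columns hold the identifiers.
#'
#' @param path path to the matrix file.
#' @param format one of `"csv"`, `"tsv"`, `"mtx"`; guessed from the file
#'   extension when missing.
#' @param genesFile,cellsFile companion identifier files for `mtx` input;
#'   default to `genes.tsv` / `barcodes.tsv` next to the matrix file.
#' @return An [ExpressionMatrix-class] (unscaled).
#' @export
loadExpression <- function(path, format = c("auto", "csv", "tsv", "mtx"),
                           genesFile = NULL, cellsFile = NULL) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("input file not found: ", path)
    if (format == "auto") {
        ext <- tolower(tools::file_ext(path))
        format <- switch(ext, csv = "csv", tsv = "tsv", txt = "tsv",
            mtx = "mtx",
            stop("cannot guess format from extension '", ext, "'"))
    }
    if (format %in% c("csv", "tsv")) {
        sep <- if (format == "csv") "," else "\t"
        df <- utils::read.table(path, header = TRUE, sep = sep,
            check.names = FALSE, stringsAsFactors = FALSE)
        gids <- as.character(df[[1L]])
        vals <- as.matrix(df[, -1L, drop = FALSE])
        storage.mode(vals) <- "double"
        if (anyDuplicated(gids))
            stop("duplicate gene identifiers in ", path)
        rownames(vals) <- gids
    } else {
        dirn <- dirname(path)
        if (is.null(genesFile)) genesFile <- file.path(dirn, "genes.tsv")
        if (is.null(cellsFile)) cellsFile <- file.path(dirn, "barcodes.tsv")
        if (!file.exists(genesFile))
            stop("companion gene file not found: ", genesFile)
        if (!file.exists(cellsFile))
            stop("companion barcode file not found: ", cellsFile)
        sp <- Matrix::readMM(path)
        gids <- utils::read.table(genesFile, sep = "\t",
            stringsAsFactors = FALSE)[[1L]]
        cids <- utils::read.table(cellsFile, sep = "\t",
            stringsAsFactors = FALSE)[[1L]]
        if (length(gids) != nrow(sp) || length(cids) != ncol(sp))
            stop("matrix dimensions do not match identifier lists")
        if (anyDuplicated(gids))
            stop("duplicate gene identifiers in ", genesFile)
        vals <- as.matrix(sp)
        storage.mode(vals) <- "double"
        dimnames(vals) <- list(as.character(gids), as.character(cids))
    }
    if (anyNA(vals)) stop("missing values in expression matrix")
    if (any(vals < 0)) stop("negative expression values in ", path)
    expressionMatrix(vals)
}

#' Filter genes by expression prevalence
#'
#' Keeps gene i iff the percentage of cells with a positive value lies in
#' `[x\%, (100-x)\%]`, boundaries inclusive. Cells are never filtered.
#'
#' @param E an [ExpressionMatrix-class] (unscaled).
#' @param filterPct the percent `x`.
#' @return An [ExpressionMatrix-class] with the retained genes, order
#'   preserved.
#' @export
filterGenes <- function(E, filterPct = 2.5) {
    stopifnot(is(E, "ExpressionMatrix"))
    if (isScaled(E)) stop("filterGenes expects an unscaled matrix")
    v <- exprValues(E)
    n <- ncol(v)
    frac <- 100 * rowSums(v > 0) / n
    keep <- frac >= filterPct & frac <= (100 - filterPct)
    if (!any(keep)) stop("all genes removed by the prevalence filter")
    expressionMatrix(v[keep, , drop = FALSE])
}

# per-gene mean and variance-to-mean dispersion, z-scored within
# equal-count mean bins; the dispersion rank drives HVG selection
.dispersionScores <- function(v, nbins = 20L) {
    mu <- rowMeans(v)
    va <- apply(v, 1L, stats::var)
    disp <- ifelse(mu > 0, va / mu, 0)
    lmu <- log1p(mu)
    ldisp <- log1p(disp)
    m <- length(mu)
    nbins <- min(nbins, m)
    # equal-count bins over the mean: order genes by mean, chunk evenly
    ord <- order(lmu, seq_len(m))
    binOf <- integer(m)
    binOf[ord] <- as.integer(cut(seq_len(m), breaks = nbins, labels = FALSE))
    z <- numeric(m)
    for (b in unique(binOf)) {
        idx <- which(binOf == b)
        s <- stats::sd(ldisp[idx])
        if (is.na(s) || s == 0) z[idx] <- 0
        else z[idx] <- (ldisp[idx] - mean(ldisp[idx])) / s
    }
    z
}

#' Select highly variable genes
#'
#' Ranks genes by the z-score of their variance-to-mean dispersion within 20
#' equal-count mean-expression bins (natural-log scale) and keeps the top
#' `nHVG`. When fewer than `nHVG` genes are present all are kept with a
#' warning.
#'
#' @param E an [ExpressionMatrix-class] after [filterGenes()].
#' @param nHVG number of genes to retain.
#' @return An [ExpressionMatrix-class]; gene order of the input preserved.
#' @export
selectHVGs <- function(E, nHVG = 2000L) {
    stopifnot(is(E, "ExpressionMatrix"))
    v <- exprValues(E)
    m <- nrow(v)
    if (m < 10L) stop("fewer than 10 genes remain; cannot select HVGs")
    if (m <= nHVG) {
        if (m < nHVG)
            warning(sprintf("only %d genes available; keeping all", m))
        return(E)
    }
    z <- .dispersionScores(v)
    sel <- order(-z, seq_len(m))[seq_len(nHVG)]
    expressionMatrix(v[sort(sel), , drop = FALSE])
}

#' Log-transform and scale expression into [0,1]
#'
#' Applies `log(1 + d)` and divides each gene's row by its own maximum, so
#' zeros stay exactly zero, every gene's maximum is exactly 1, and the
#' within-gene rank order of cells is preserved.
#'
#' @param E an [ExpressionMatrix-class] with a positive maximum per gene.
#' @return A scaled [ExpressionMatrix-class].
#' @export
logAndScale <- function(E) {
    stopifnot(is(E, "ExpressionMatrix"))
    v <- log1p(exprValues(E))
    mx <- apply(v, 1L, max)
    if (any(mx == 0))
        stop("gene(s) with all-zero expression; run filterGenes first")
    v <- v / mx
    expressionMatrix(v, isScaled = TRUE)
}

#' Full pre-processing pipeline
#'
#' Prevalence filter, highly-variable-gene selection, then log-transform
#' and per-gene scaling into `[0,1]`.
#'
#' @param E an [ExpressionMatrix-class] (raw counts or normalized values).
#' @param params a [ScqaParams-class]; see [scqaParams()].
#' @return A scaled [ExpressionMatrix-class] ready for landmark
#'   construction.
#' @examples
#' sim <- simulateCells(syntheticSpec(seed = 1L))
#' D <- preprocess(sim$expr, scqaParams())
#' D
#' @export
preprocess <- function(E, params = scqaParams()) {
    E <- filterGenes(E, params@filterPct)
    E <- selectHVGs(E, params@nHVG)
    logAndScale(E)
}
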