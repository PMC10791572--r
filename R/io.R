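# Result serialization. Floats are written with 6 significant digits and
# rows follow the input cell order, so re-running an identical
# configuration reproduces byte-identical files.

.fmtNum <- function(x) {
    ifelse(x == round(x), format(x, scientific = FALSE, trim = TRUE),
        format(signif(x, 6), scientific = FALSE, trim = TRUE))
}

.writeMatrixCSV <- function(mat, path, idCol) {
    df <- data.frame(id = rownames(mat), check.names = FALSE,
        stringsAsFactors = FALSE)
    names(df) <- idCol
    for (j in seq_len(ncol(mat))) df[[colnames(mat)[j]]] <-
        .fmtNum(mat[, j])
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Write scQA results to a directory
#'
#' Writes `labels.csv` (cell_id, cluster), the landmark matrices
#' `Q1.csv` / `Q2.csv` (cells x landmarks), the landmark membership tables
#' `landmarks_q1.tsv` / `landmarks_q2.tsv` (landmark_id, gene_id, and the
#' bin-usage group for Q2), and `cluster_landmarks.tsv` associating each
#' cell cluster with its most active landmark and that landmark's member
#' genes (the bidirectional clustering report).
#'
#' @param result a [ScqaResult-class].
#' @param dir output directory, created if missing.
#' @return Invisibly, the paths written.
#' @export
writeScqaResults <- function(result, dir) {
    stopifnot(is(result, "ScqaResult"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- character(0)
    labs <- data.frame(cell_id = cellIDs(result),
        cluster = unname(cellLabels(result)))
    p <- file.path(dir, "labels.csv")
    utils::write.csv(labs, p, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
    writeLm <- function(lm, stem) {
        mp <- file.path(dir, paste0(stem, ".csv"))
        .writeMatrixCSV(landmarkValues(lm), mp, "cell_id")
        mem <- memberships(lm)
        grp <- landmarkGroups(lm)
        tb <- data.frame(
            landmark_id = rep(names(mem), lengths(mem)),
            gene_id = unlist(mem, use.names = FALSE)
        )
        if (!all(is.na(grp)))
            tb$group <- rep(grp, lengths(mem))
        tp <- file.path(dir, paste0("landmarks_", tolower(stem), ".tsv"))
        utils::write.table(tb, tp, sep = "\t", row.names = FALSE,
            quote = FALSE)
        c(mp, tp)
    }
    if (!is.null(qualitativeMatrix(result)))
        paths <- c(paths, writeLm(qualitativeMatrix(result), "Q1"))
    if (!is.null(quantitativeMatrix(result)))
        paths <- c(paths, writeLm(quantitativeMatrix(result), "Q2"))
    assoc <- clusterLandmarkTable(result)
    if (!is.null(assoc)) {
        ap <- file.path(dir, "cluster_landmarks.tsv")
        utils::write.table(assoc, ap, sep = "\t", row.names = FALSE,
            quote = FALSE)
        paths <- c(paths, ap)
    }
    invisible(paths)
}

#' Associate each cell cluster with its key landmark genes
#'
#' For every cell cluster, reports the landmark (quantitative when
#' available, else qualitative) with the highest mean value across the
#' cluster's cells, together with that landmark's member genes - the gene
#' side of the bidirectional clustering.
#'
#' @param result a [ScqaResult-class].
#' @return A data.frame with columns `cluster`, `landmark_id`,
#'   `mean_value`, `genes` (comma-separated), or NULL when the result
#'   carries no landmark matrix.
#' @export
clusterLandmarkTable <- function(result) {
    lm <- quantitativeMatrix(result)
    if (is.null(lm)) lm <- qualitativeMatrix(result)
    if (is.null(lm)) return(NULL)
    vals <- landmarkValues(lm)
    mem <- memberships(lm)
    labs <- unname(cellLabels(result))
    out <- lapply(sort(unique(labs)), function(cl) {
        mv <- colMeans(vals[labs == cl, , drop = FALSE])
        j <- which.max(mv)
        data.frame(cluster = cl, landmark_id = colnames(vals)[j],
            mean_value = signif(mv[j], 6),
            genes = paste(mem[[j]], collapse = ","))
    })
    do.call(rbind, out)
}

#' Write a synthetic dataset as Matrix Market files plus truth labels
#'
#' @param sim the list returned by [simulateCells()].
#' @param dir output directory.
#' @return Invisibly, the paths written (`matrix.mtx`, `genes.tsv`,
#'   `barcodes.tsv`, `truth.csv`).
#' @export
writeSimulation <- function(sim, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    v <- exprValues(sim$expr)
    mp <- file.path(dir, "matrix.mtx")
    Matrix::writeMM(methods::as(Matrix::Matrix(v, sparse = TRUE),
        "generalMatrix"), mp)
    gp <- file.path(dir, "genes.tsv")
    writeLines(rownames(v), gp)
    bp <- file.path(dir, "barcodes.tsv")
    writeLines(colnames(v), bp)
    tp <- file.path(dir, "truth.csv")
    utils::write.csv(data.frame(cell_id = colnames(v),
        cluster = sim$labels), tp, row.names = FALSE, quote = FALSE)
    invisible(c(mp, gp, bp, tp))
}

#' Read cluster labels from a CSV file
#'
#' Expects columns `cell_id` and `cluster` (or any two columns in that
#' order).
#'
#' @param path CSV path.
#' @return Named vector of labels.
#' @export
readLabels <- function(path) {
    if (!file.exists(path)) stop("label file not found: ", path)
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (ncol(df) < 2L) stop("label file needs cell_id and cluster columns")
    stats::setNames(df[[2L]], as.character(df[[1L]]))
}

# --- run configuration ------------------------------------------------

.configDefaults <- function() {
    list(
        filter_pct = 2.5, n_hvg = 2000L, rho = 0.7, n_bins = 6L,
        alpha = 0.5, window_frac = 0.05, pair_keep_frac = 1 / 1000,
        quartile_pct = 25, min_gene_cluster = 3L,
        min_cluster_size = "auto", max_iter = 50L,
        mode = "full", log_level = "info",
        input = "", genes = "", cells = "", out = ""
    )
}

#' Read a flat key-value run configuration
#'
#' YAML file of flat keys; unknown keys are rejected, missing keys take
#' the method's default values.
#'
#' @param path YAML file path.
#' @return Named list with all configuration fields.
#' @seealso [writeRunConfig()]
#' @export
readRunConfig <- function(path) {
    if (!file.exists(path)) stop("config file not found: ", path)
    raw <- yaml::read_yaml(path)
    defs <- .configDefaults()
    unknown <- setdiff(names(raw), names(defs))
    if (length(unknown))
        stop("unknown config keys: ", paste(unknown, collapse = ", "))
    defs[names(raw)] <- raw
    defs
}

#' Write a run configuration to a YAML file
#'
#' @param config named list as returned by [readRunConfig()].
#' @param path destination file.
#' @return Invisibly, `path`.
#' @export
writeRunConfig <- function(config, path) {
    defs <- .configDefaults()
    unknown <- setdiff(names(config), names(defs))
    if (length(unknown))
        stop("unknown config keys: ", paste(unknown, collapse = ", "))
    full <- defs
    full[names(config)] <- config
    yaml::write_yaml(full, path)
    invisible(path)
}

# translate a config list into ScqaParams
.paramsFromConfig <- function(cfg) {
    scqaParams(
        filterPct = cfg$filter_pct, nHVG = cfg$n_hvg, rho = cfg$rho,
        nBins = cfg$n_bins, alpha = cfg$alpha,
        windowFrac = cfg$window_frac, pairKeepFrac = cfg$pair_keep_frac,
        quartilePct = cfg$quartile_pct,
        minGeneCluster = cfg$min_gene_cluster,
        minClusterSize = cfg$min_cluster_size, maxIter = cfg$max_iter
    )
}
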