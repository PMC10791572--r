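# Generics and accessors. Slots are never touched directly outside the
# package; these accessors are the supported surface.

#' @rdname ExpressionMatrix-class
#' @param object an object of the documented class.
#' @export
setGeneric("geneIDs", function(object) standardGeneric("geneIDs"))

#' @rdname ExpressionMatrix-class
#' @export
setGeneric("cellIDs", function(object) standardGeneric("cellIDs"))

#' @rdname ExpressionMatrix-class
#' @export
setGeneric("exprValues", function(object) standardGeneric("exprValues"))

#' @rdname ExpressionMatrix-class
#' @export
setGeneric("isScaled", function(object) standardGeneric("isScaled"))

#' @rdname LandmarkMatrix-class
#' @param object an object of the documented class.
#' @export
setGeneric("landmarkValues", function(object) standardGeneric("landmarkValues"))

#' @rdname LandmarkMatrix-class
#' @export
setGeneric("memberships", function(object) standardGeneric("memberships"))

#' @rdname LandmarkMatrix-class
#' @export
setGeneric("nLandmarks", function(object) standardGeneric("nLandmarks"))

#' @rdname LandmarkMatrix-class
#' @export
setGeneric("landmarkGroups", function(object) standardGeneric("landmarkGroups"))

#' @rdname ScqaResult-class
#' @param object an object of the documented class.
#' @export
setGeneric("cellLabels", function(object) standardGeneric("cellLabels"))

#' @rdname ScqaResult-class
#' @export
setGeneric("qualitativeMatrix", function(object)
    standardGeneric("qualitativeMatrix"))

#' @rdname ScqaResult-class
#' @export
setGeneric("quantitativeMatrix", function(object)
    standardGeneric("quantitativeMatrix"))

#' @rdname ExpressionMatrix-class
#' @export
setMethod("geneIDs", "ExpressionMatrix", function(object)
    rownames(object@values))

#' @rdname ExpressionMatrix-class
#' @export
setMethod("cellIDs", "ExpressionMatrix", function(object)
    colnames(object@values))

#' @rdname ExpressionMatrix-class
#' @export
setMethod("exprValues", "ExpressionMatrix", function(object) object@values)

#' @rdname ExpressionMatrix-class
#' @export
setMethod("isScaled", "ExpressionMatrix", function(object) object@isScaled)

#' @rdname ExpressionMatrix-class
#' @param x an `ExpressionMatrix`.
#' @export
setMethod("dim", "ExpressionMatrix", function(x) dim(x@values))

setMethod("show", "ExpressionMatrix", function(object) {
    cat(sprintf(
        "ExpressionMatrix: %d genes x %d cells (%s)\n",
        nrow(object@values), ncol(object@values),
        if (object@isScaled) "log-scaled to [0,1]" else "unscaled"
    ))
    invisible(NULL)
})

#' @rdname LandmarkMatrix-class
#' @export
setMethod("landmarkValues", "LandmarkMatrix", function(object) object@values)

#' @rdname LandmarkMatrix-class
#' @export
setMethod("memberships", "LandmarkMatrix", function(object) {
    stats::setNames(object@memberships, colnames(object@values))
})

#' @rdname LandmarkMatrix-class
#' @export
setMethod("nLandmarks", "LandmarkMatrix", function(object)
    ncol(object@values))

#' @rdname LandmarkMatrix-class
#' @export
setMethod("landmarkGroups", "LandmarkMatrix", function(object)
    object@groups)

#' @rdname LandmarkMatrix-class
#' @export
setMethod("cellIDs", "LandmarkMatrix", function(object)
    rownames(object@values))

setMethod("show", "LandmarkMatrix", function(object) {
    cat(sprintf(
        "LandmarkMatrix (%s): %d cells x %d landmarks; %d member genes\n",
        object@type, nrow(object@values), ncol(object@values),
        sum(lengths(object@memberships))
    ))
    invisible(NULL)
})

#' @rdname ScqaResult-class
#' @export
setMethod("cellLabels", "ScqaResult", function(object)
    stats::setNames(object@labels, object@cellIDs))

#' @rdname ScqaResult-class
#' @export
setMethod("cellIDs", "ScqaResult", function(object) object@cellIDs)

#' @rdname ScqaResult-class
#' @export
setMethod("qualitativeMatrix", "ScqaResult", function(object) object@Q1)

#' @rdname ScqaResult-class
#' @export
setMethod("quantitativeMatrix", "ScqaResult", function(object) object@Q2)

setMethod("show", "ScqaResult", function(object) {
    k <- length(unique(object@labels))
    cat(sprintf(
        "ScqaResult (mode=%s): %d cells in %d clusters\n",
        object@mode, length(object@labels), k
    ))
    sizes <- sort(table(object@labels), decreasing = TRUE)
    cat("cluster sizes:", paste(as.integer(sizes), collapse = ", "), "\n")
    invisible(NULL)
})

setMethod("show", "ScqaParams", function(object) {
    cat("ScqaParams:\n")
    cat(sprintf("  filterPct=%g nHVG=%d rho=%g nBins=%d alpha=%g\n",
        object@filterPct, object@nHVG, object@rho, object@nBins,
        object@alpha))
    cat(sprintf(
        "  windowFrac=%g pairKeepFrac=%g quartilePct=%g minGeneCluster=%d\n",
        object@windowFrac, object@pairKeepFrac, object@quartilePct,
        object@minGeneCluster))
    cat(sprintf("  minClusterSize=%s maxIter=%d\n",
        if (is.na(object@minClusterSize)) "auto"
        else as.character(object@minClusterSize),
        object@maxIter))
    invisible(NULL)
})

setMethod("show", "SyntheticSpec", function(object) {
    cat(sprintf(
        "SyntheticSpec: %d types, %d cells, %d markers/type, %d housekeeping, %d noise genes, dropoutShape=%g, seed=%d\n",
        object@nTypes, sum(object@cellsPerType), object@nMarkersPerType,
        object@nHousekeeping, object@nNoiseGenes, object@dropoutShape,
        object@seed
    ))
    invisible(NULL)
})
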