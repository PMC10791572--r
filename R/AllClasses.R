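#' @import methods
NULL

#' Parameters controlling the scQA pipeline
#'
#' Container for the tunable parameters of the landmark constructors and the
#' cluster constructor. All defaults are the method's published operating
#' point; see [scqaParams()] for the meaning of each slot.
#'
#' @slot filterPct numeric(1); genes expressed in fewer than `filterPct`\%
#'   or more than `100 - filterPct`\% of cells are removed.
#' @slot nHVG integer(1); number of highly variable genes retained.
#' @slot rho numeric(1); similarity threshold a gene must exceed to join an
#'   existing gene cluster.
#' @slot nBins integer(1); number of expression bins used by the quantitative
#'   landmark constructor.
#' @slot alpha numeric(1) in `[0,1]`; weight of the outgoing-edge term when
#'   mixing the two directions of the cell graph.
#' @slot windowFrac numeric(1); half-width of the sorted-gene neighbourhood,
#'   as a fraction of the number of genes.
#' @slot pairKeepFrac numeric(1); fraction of all gene pairs retained as
#'   edges of the gene similarity graph.
#' @slot quartilePct numeric(1); percentile used for the lower/upper bound
#'   vectors of quantitative gene clusters.
#' @slot minGeneCluster integer(1); gene clusters smaller than this are
#'   discarded.
#' @slot minClusterSize integer(1) or NA; cell clusters smaller than this are
#'   dissolved before merging. NA means automatic: `max(3, round(0.01 n))`.
#' @slot maxIter integer(1); cap on label-propagation convergence sweeps.
#'
#' @seealso [scqaParams()]
#' @exportClass ScqaParams
setClass("ScqaParams",
    representation(
        filterPct = "numeric",
        nHVG = "integer",
        rho = "numeric",
        nBins = "integer",
        alpha = "numeric",
        windowFrac = "numeric",
        pairKeepFrac = "numeric",
        quartilePct = "numeric",
        minGeneCluster = "integer",
        minClusterSize = "integer",
        maxIter = "integer"
    )
)

setValidity("ScqaParams", function(object) {
    msgs <- character()
    if (!(object@filterPct > 0 && object@filterPct < 50))
        msgs <- c(msgs, "filterPct must lie in (0, 50)")
    if (!(object@rho > 0 && object@rho <= 1))
        msgs <- c(msgs, "rho must lie in (0, 1]")
    if (object@nBins < 2L)
        msgs <- c(msgs, "nBins must be >= 2")
    if (!(object@alpha >= 0 && object@alpha <= 1))
        msgs <- c(msgs, "alpha must lie in [0, 1]")
    if (object@nHVG < 1L)
        msgs <- c(msgs, "nHVG must be >= 1")
    if (!(object@windowFrac > 0 && object@windowFrac <= 1))
        msgs <- c(msgs, "windowFrac must lie in (0, 1]")
    if (!(object@pairKeepFrac > 0 && object@pairKeepFrac <= 1))
        msgs <- c(msgs, "pairKeepFrac must lie in (0, 1]")
    if (!(object@quartilePct > 0 && object@quartilePct < 50))
        msgs <- c(msgs, "quartilePct must lie in (0, 50)")
    if (object@minGeneCluster < 1L)
        msgs <- c(msgs, "minGeneCluster must be >= 1")
    if (object@maxIter < 1L)
        msgs <- c(msgs, "maxIter must be >= 1")
    if (length(msgs)) msgs else TRUE
})

#' Genes-by-cells expression matrix
#'
#' A dense genes x cells matrix of non-negative expression values with
#' unique gene and cell identifiers stored as dimnames, plus a flag
#' recording whether entries have been log-transformed and scaled into
#' `[0,1]`.
#'
#' @slot values numeric matrix, genes as rows, cells as columns.
#' @slot isScaled logical(1); TRUE once [logAndScale()] has been applied.
#'
#' @seealso [expressionMatrix()], [loadExpression()]
#' @exportClass ExpressionMatrix
setClass("ExpressionMatrix",
    representation(values = "matrix", isScaled = "logical")
)

setValidity("ExpressionMatrix", function(object) {
    v <- object@values
    msgs <- character()
    if (is.null(rownames(v)) || is.null(colnames(v)))
        msgs <- c(msgs, "gene and cell identifiers (dimnames) are required")
    else {
        if (anyDuplicated(rownames(v)))
            msgs <- c(msgs, "duplicate gene identifiers")
        if (anyDuplicated(colnames(v)))
            msgs <- c(msgs, "duplicate cell identifiers")
    }
    if (!is.numeric(v))
        msgs <- c(msgs, "values must be numeric")
    else if (any(v < 0))
        msgs <- c(msgs, "negative expression values are not allowed")
    if (isTRUE(object@isScaled) && length(v) && max(v) > 1 + 1e-12)
        msgs <- c(msgs, "scaled matrix has entries outside [0,1]")
    if (length(msgs)) msgs else TRUE
})

#' Cells-by-landmarks consensus matrix
#'
#' A landmark is the consensus expression pattern (over cells) of a cluster
#' of genes sharing a common pattern. The qualitative matrix Q1 holds binary
#' consensus templates; the quantitative matrix Q2 holds mean consensus
#' profiles in `[0,1]`. One column per landmark; the genes backing each
#' column are kept in `memberships`.
#'
#' @slot values numeric matrix, cells as rows, landmarks as columns.
#' @slot type `"qualitative"` (entries in \{0,1\}) or `"quantitative"`
#'   (entries in `[0,1]`).
#' @slot memberships list of character vectors; member gene ids per landmark.
#' @slot groups integer vector; bin-usage group of each landmark
#'   (quantitative only, `NA` otherwise).
#'
#' @seealso [qualitativeLandmarks()], [quantitativeLandmarks()]
#' @exportClass LandmarkMatrix
setClass("LandmarkMatrix",
    representation(
        values = "matrix",
        type = "character",
        memberships = "list",
        groups = "integer"
    )
)

setValidity("LandmarkMatrix", function(object) {
    v <- object@values
    msgs <- character()
    if (ncol(v) < 1L)
        msgs <- c(msgs, "at least one landmark is required")
    if (!object@type %in% c("qualitative", "quantitative"))
        msgs <- c(msgs, "type must be 'qualitative' or 'quantitative'")
    if (length(object@memberships) != ncol(v))
        msgs <- c(msgs, "one membership vector per landmark is required")
    if (length(object@groups) != ncol(v))
        msgs <- c(msgs, "one group per landmark is required")
    if (object@type == "qualitative" && length(v) && !all(v %in% c(0, 1)))
        msgs <- c(msgs, "qualitative landmark entries must be 0/1")
    if (object@type == "quantitative" && length(v) &&
        (min(v) < -1e-12 || max(v) > 1 + 1e-12))
        msgs <- c(msgs, "quantitative landmark entries must lie in [0,1]")
    if (length(msgs)) msgs else TRUE
})

#' Result of a scQA run
#'
#' Holds the final per-cell cluster labels (0-based, contiguous), the two
#' cell-landmark matrices that produced them, and the parameters used.
#'
#' @slot labels integer vector of 0-based cluster labels, one per cell.
#' @slot cellIDs character vector of cell identifiers.
#' @slot Q1 [LandmarkMatrix-class] or NULL; qualitative landmarks.
#' @slot Q2 [LandmarkMatrix-class] or NULL; quantitative landmarks.
#' @slot params [ScqaParams-class] used for the run.
#' @slot mode `"full"`, `"lc1_only"` or `"lc2_only"`.
#'
#' @seealso [runScqa()]
#' @exportClass ScqaResult
setClass("ScqaResult",
    representation(
        labels = "integer",
        cellIDs = "character",
        Q1 = "ANY",
        Q2 = "ANY",
        params = "ScqaParams",
        mode = "character"
    )
)

setValidity("ScqaResult", function(object) {
    msgs <- character()
    if (length(object@labels) != length(object@cellIDs))
        msgs <- c(msgs, "one label per cell is required")
    if (length(object@labels) && min(object@labels) < 0L)
        msgs <- c(msgs, "labels must be >= 0")
    if (!object@mode %in% c("full", "lc1_only", "lc2_only"))
        msgs <- c(msgs, "mode must be full, lc1_only or lc2_only")
    if (length(msgs)) msgs else TRUE
})

#' Specification of a planted-partition synthetic dataset
#'
#' Describes a synthetic scRNA-seq-like matrix with planted cell types:
#' type-specific marker-gene blocks, shared housekeeping genes, unstructured
#' noise genes, lognormal positive expression and mean-dependent dropout.
#'
#' @slot nTypes integer(1); number of planted cell types.
#' @slot cellsPerType integer vector; cells per type (recycled to nTypes).
#' @slot nMarkersPerType integer(1); marker genes per type.
#' @slot nHousekeeping integer(1); genes positive in every cell.
#' @slot nNoiseGenes integer(1); unstructured genes.
#' @slot dropoutShape numeric(1) in `[0,1]`; amplitude of the mean-dependent
#'   dropout curve (0 = no excess zeros).
#' @slot expressionScale numeric(2); lognormal `meanlog` and `sdlog` for
#'   marker expression.
#' @slot seed integer(1); RNG seed.
#'
#' @seealso [syntheticSpec()], [simulateCells()]
#' @exportClass SyntheticSpec
setClass("SyntheticSpec",
    representation(
        nTypes = "integer",
        cellsPerType = "integer",
        nMarkersPerType = "integer",
        nHousekeeping = "integer",
        nNoiseGenes = "integer",
        dropoutShape = "numeric",
        expressionScale = "numeric",
        seed = "integer"
    )
)

setValidity("SyntheticSpec", function(object) {
    msgs <- character()
    if (object@nTypes < 1L)
        msgs <- c(msgs, "at least one cell type is required")
    if (any(object@cellsPerType < 1L))
        msgs <- c(msgs, "cellsPerType must be positive")
    if (length(object@cellsPerType) != object@nTypes)
        msgs <- c(msgs, "cellsPerType must have one entry per type")
    if (!(object@dropoutShape >= 0 && object@dropoutShape <= 1))
        msgs <- c(msgs, "dropoutShape must lie in [0, 1]")
    if (length(object@expressionScale) != 2L || object@expressionScale[2] < 0)
        msgs <- c(msgs, "expressionScale must be c(meanlog, sdlog >= 0)")
    if (length(msgs)) msgs else TRUE
})
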