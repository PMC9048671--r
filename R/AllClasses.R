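#' @import methods
#' @importFrom Matrix Matrix readMM writeMM t colSums rowSums
NULL

## ---------------------------------------------------------------------------
## Core data containers
## ---------------------------------------------------------------------------

#' FeatureMatrix: a cell-by-feature expression/intensity matrix
#'
#' Canonical in-memory container for single-cell feature data. Rows are
#' cells, columns are features; values are non-negative (UMI counts for
#' RNA, tag counts for ADT, per-gene accessibility scores for ATAC-derived
#' activity matrices). Stored sparse (\linkS4class{dgCMatrix}); cell and
#' feature identifiers live in the dimnames and must be unique.
#'
#' @slot values sparse numeric matrix, cells x features, all entries
#'   finite and >= 0, with unique rownames (cell ids) and colnames
#'   (feature ids).
#' @slot modality free-form tag describing the data type; conventional
#'   values are \code{"rna"}, \code{"adt"} and \code{"atac-activity"}.
#'   The \code{"adt"} tag switches off highly-variable-feature selection
#'   during embedding (antibody panels are small and fully informative).
#'
#' @seealso [FeatureMatrix()], [readMtxDir()], [readDenseMatrix()]
#' @exportClass FeatureMatrix
setClass("FeatureMatrix",
    representation(values = "dgCMatrix", modality = "character"))

setValidity("FeatureMatrix", function(object) {
    v <- object@values
    msg <- character()
    if ((nrow(v) > 0L && is.null(rownames(v))) ||
        (ncol(v) > 0L && is.null(colnames(v))))
        msg <- c(msg, "values must carry cell ids (rownames) and feature ids (colnames)")
    else {
        if (anyDuplicated(rownames(v))) msg <- c(msg, "duplicated cell ids")
        if (anyDuplicated(colnames(v))) msg <- c(msg, "duplicated feature ids")
        if (any(!nzchar(rownames(v))) || anyNA(rownames(v)))
            msg <- c(msg, "empty or NA cell ids")
        if (any(!nzchar(colnames(v))) || anyNA(colnames(v)))
            msg <- c(msg, "empty or NA feature ids")
    }
    if (length(v@x) && (any(!is.finite(v@x)) || any(v@x < 0)))
        msg <- c(msg, "values must be finite and non-negative")
    if (length(object@modality) != 1L || is.na(object@modality))
        msg <- c(msg, "modality must be a single string")
    if (length(msg)) msg else TRUE
})

#' CellLabels: per-cell categorical annotations
#'
#' Ground-truth (or predicted) population labels keyed by cell id, used by
#' the evaluation module.
#'
#' @slot cellIds unique cell identifiers.
#' @slot labels one label per cell id.
#' @exportClass CellLabels
setClass("CellLabels",
    representation(cellIds = "character", labels = "character"))

setValidity("CellLabels", function(object) {
    msg <- character()
    if (length(object@cellIds) != length(object@labels))
        msg <- c(msg, "one label per cell id required")
    if (anyDuplicated(object@cellIds)) msg <- c(msg, "duplicated cell ids")
    if (anyNA(object@labels)) msg <- c(msg, "NA labels not allowed")
    if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Gating models
## ---------------------------------------------------------------------------

#' Signature: a named set of signed marker genes
#'
#' A marker signature is an ordered set of gene symbols, each carrying a
#' sign: +1 for genes whose expression supports the identity the
#' signature describes, -1 for genes whose expression argues against it
#' (written with a trailing \code{"-"} in text form, e.g. \code{"CD3D-"}).
#' At least one positive gene is required; a signature made only of
#' negated genes has no identity to detect and is rejected.
#'
#' @slot name signature name, unique within a gating model.
#' @slot genes gene symbols, trailing \code{"-"} already stripped.
#' @slot signs integer +1/-1 per gene.
#' @exportClass Signature
setClass("Signature",
    representation(name = "character", genes = "character", signs = "integer"))

setValidity("Signature", function(object) {
    msg <- character()
    if (length(object@name) != 1L || !nzchar(object@name))
        msg <- c(msg, "signature name must be a single non-empty string")
    if (length(object@genes) < 1L)
        msg <- c(msg, "signature needs at least one gene")
    if (length(object@genes) != length(object@signs))
        msg <- c(msg, "genes and signs lengths differ")
    if (any(!object@signs %in% c(1L, -1L)))
        msg <- c(msg, "signs must be +1 or -1")
    if (any(!nzchar(object@genes)) || any(grepl("-$", object@genes)))
        msg <- c(msg, "gene symbols must be non-empty with no trailing '-'")
    if (length(object@signs) && !any(object@signs == 1L))
        msg <- c(msg, sprintf("signature '%s' has no positive gene", object@name))
    if (anyDuplicated(object@genes))
        msg <- c(msg, sprintf("signature '%s' lists a gene twice", object@name))
    if (length(msg)) msg else TRUE
})

#' GatingLevel: one filtering step of a hierarchical gating model
#'
#' A level holds the signatures evaluated at one step of the gate
#' hierarchy. A cell passes the level if at least one \emph{positive}
#' signature scores at or above the positive threshold and no
#' \emph{negative} signature reaches the negative threshold (veto).
#'
#' @slot positive list of \linkS4class{Signature} (at least one).
#' @slot negative list of \linkS4class{Signature} (possibly empty).
#' @exportClass GatingLevel
setClass("GatingLevel",
    representation(positive = "list", negative = "list"))

setValidity("GatingLevel", function(object) {
    msg <- character()
    ok <- function(l) all(vapply(l, is, logical(1), class2 = "Signature"))
    if (!length(object@positive))
        msg <- c(msg, "each gating level needs at least one positive signature")
    if (!ok(object@positive) || !ok(object@negative))
        msg <- c(msg, "level entries must be Signature objects")
    if (length(msg)) msg else TRUE
})

#' GatingModel: an ordered hierarchy of gating levels
#'
#' Cells are filtered sequentially: level 1 is evaluated on all cells,
#' level k only on cells that passed level k-1. A cell is "Pure" iff it
#' passes every level.
#'
#' @slot name model name (for a single-level model built with
#'   [gatingModel()] this is also the signature name).
#' @slot levels list of \linkS4class{GatingLevel}, positionally numbered
#'   from 1.
#' @exportClass GatingModel
setClass("GatingModel",
    representation(name = "character", levels = "list"))

setValidity("GatingModel", function(object) {
    msg <- character()
    if (length(object@name) != 1L || !nzchar(object@name))
        msg <- c(msg, "model name must be a single non-empty string")
    if (!length(object@levels))
        msg <- c(msg, "model needs at least one level")
    if (!all(vapply(object@levels, is, logical(1), class2 = "GatingLevel")))
        msg <- c(msg, "levels must be GatingLevel objects")
    else {
        nms <- unlist(lapply(object@levels, function(l)
            vapply(c(l@positive, l@negative), function(s) s@name, character(1))))
        if (anyDuplicated(nms))
            msg <- c(msg, "signature names must be unique within a model")
    }
    if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Scores, graphs, calls
## ---------------------------------------------------------------------------

#' ScoreMatrix: per-cell signature scores
#'
#' Cells x signatures matrix of scores in [0, 1], either raw (one score
#' per cell computed from that cell's feature ranks alone) or smoothed
#' (each score replaced by the mean over the cell's kNN neighbourhood).
#'
#' @slot values numeric matrix, cells x signatures, all in [0, 1];
#'   rownames are cell ids, colnames signature names.
#' @slot smoothed logical flag distinguishing raw from kNN-smoothed scores.
#' @exportClass ScoreMatrix
setClass("ScoreMatrix",
    representation(values = "matrix", smoothed = "logical"))

setValidity("ScoreMatrix", function(object) {
    v <- object@values
    msg <- character()
    if (!is.numeric(v)) msg <- c(msg, "score values must be numeric")
    if (is.null(rownames(v)) || is.null(colnames(v)))
        msg <- c(msg, "scores must carry cell ids (rownames) and signature names (colnames)")
    if (length(v) && (anyNA(v) || min(v) < 0 || max(v) > 1))
        msg <- c(msg, "scores must lie in [0, 1]")
    if (length(object@smoothed) != 1L || is.na(object@smoothed))
        msg <- c(msg, "smoothed must be TRUE or FALSE")
    if (length(msg)) msg else TRUE
})

#' NeighborGraph: exact k-nearest-neighbour structure over cells
#'
#' Row i of \code{indices} lists cell i itself (always first) followed by
#' its nearest other cells by Euclidean distance in the embedding, ties
#' broken by lower cell index. With k = 1 the graph is the identity and
#' smoothing leaves scores unchanged.
#'
#' @slot indices integer matrix, cells x min(k, nCells).
#' @slot k requested neighbourhood size (self included).
#' @slot embeddingDims dimensionality of the embedding the graph was
#'   built in.
#' @exportClass NeighborGraph
setClass("NeighborGraph",
    representation(indices = "matrix", k = "integer", embeddingDims = "integer"))

setValidity("NeighborGraph", function(object) {
    idx <- object@indices
    n <- nrow(idx)
    msg <- character()
    if (!is.integer(idx)) msg <- c(msg, "indices must be integer")
    else {
        if (ncol(idx) < 1L || ncol(idx) > n)
            msg <- c(msg, "neighbor list length must be in 1..nCells")
        if (!identical(idx[, 1L], seq_len(n)))
            msg <- c(msg, "first neighbor of each cell must be the cell itself")
        if (length(idx) && (min(idx) < 1L || max(idx) > n))
            msg <- c(msg, "neighbor indices out of range")
    }
    if (object@k < 1L) msg <- c(msg, "k must be >= 1")
    if (length(msg)) msg else TRUE
})

#' PurityCall: per-cell gating verdicts
#'
#' For each cell, one pass/fail flag per gating level plus the final
#' label: \code{"Pure"} iff the cell passed every level. Failure is
#' absorbing -- a cell failing level k is failed at all deeper levels.
#'
#' @slot cellIds cell identifiers, in input order.
#' @slot perLevel logical matrix, cells x levels (colnames
#'   \code{"level1"}, \code{"level2"}, ...).
#' @slot final \code{"Pure"} or \code{"Impure"} per cell.
#' @exportClass PurityCall
setClass("PurityCall",
    representation(cellIds = "character", perLevel = "matrix",
                   final = "character"))

setValidity("PurityCall", function(object) {
    msg <- character()
    pl <- object@perLevel
    n <- length(object@cellIds)
    if (!is.logical(pl)) msg <- c(msg, "perLevel must be logical")
    if (nrow(pl) != n || length(object@final) != n)
        msg <- c(msg, "cellIds, perLevel and final disagree on cell count")
    if (any(!object@final %in% c("Pure", "Impure")))
        msg <- c(msg, "final labels must be 'Pure' or 'Impure'")
    if (is.logical(pl) && nrow(pl) == n && ncol(pl) >= 1L) {
        allPass <- rowSums(pl) == ncol(pl)
        if (!identical(unname(allPass), unname(object@final == "Pure")))
            msg <- c(msg, "final must be 'Pure' iff all levels passed")
        if (ncol(pl) > 1L)
            for (j in 2:ncol(pl))
                if (any(pl[, j] & !pl[, j - 1L])) {
                    msg <- c(msg, "a cell failing a level may not pass a deeper level")
                    break
                }
    }
    if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Parameter bundles
## ---------------------------------------------------------------------------

#' @exportClass ScoringParams
setClass("ScoringParams",
    representation(maxRank = "integer", wNeg = "numeric"))

setValidity("ScoringParams", function(object) {
    msg <- character()
    if (!is.na(object@maxRank) && object@maxRank < 1L)
        msg <- c(msg, "maxRank must be >= 1 (or NA for automatic choice)")
    if (length(object@wNeg) != 1L || is.na(object@wNeg) || object@wNeg < 0)
        msg <- c(msg, "wNeg must be a single non-negative number")
    if (length(msg)) msg else TRUE
})

#' @exportClass GateParams
setClass("GateParams",
    representation(posThreshold = "numeric", negThreshold = "numeric",
                   recomputeGraphPerLevel = "logical",
                   signatureThresholds = "numeric"))

setValidity("GateParams", function(object) {
    msg <- character()
    thr <- c(object@posThreshold, object@negThreshold, object@signatureThresholds)
    if (anyNA(thr) || any(thr < 0) || any(thr > 1))
        msg <- c(msg, "thresholds must lie in [0, 1]")
    if (length(object@signatureThresholds) &&
        (is.null(names(object@signatureThresholds)) ||
         any(!nzchar(names(object@signatureThresholds)))))
        msg <- c(msg, "signatureThresholds must be named by signature")
    if (length(object@recomputeGraphPerLevel) != 1L ||
        is.na(object@recomputeGraphPerLevel))
        msg <- c(msg, "recomputeGraphPerLevel must be TRUE or FALSE")
    if (length(msg)) msg else TRUE
})

#' @exportClass SmoothParams
setClass("SmoothParams",
    representation(k = "integer", nHVG = "integer", nPCs = "integer",
                   targetSum = "numeric"))

setValidity("SmoothParams", function(object) {
    msg <- character()
    if (object@k < 1L) msg <- c(msg, "k must be >= 1")
    if (object@nHVG < 2L) msg <- c(msg, "nHVG must be >= 2")
    if (object@nPCs < 1L) msg <- c(msg, "nPCs must be >= 1")
    if (object@targetSum <= 0) msg <- c(msg, "targetSum must be > 0")
    if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Synthetic data and evaluation
## ---------------------------------------------------------------------------

#' PopulationSpec: generative description of one synthetic cell population
#'
#' Counts are drawn per gene from a negative binomial with mean
#' \code{baselineMean} (times \code{markerFold} for this population's
#' marker genes) and size parameter \code{dispersion}, then zeroed with
#' probability \code{dropoutExtra} (extra zero inflation emulating
#' dropout).
#'
#' @exportClass PopulationSpec
setClass("PopulationSpec",
    representation(name = "character", nCells = "integer",
                   markerGenes = "character", markerFold = "numeric",
                   baselineMean = "numeric", dispersion = "numeric",
                   dropoutExtra = "numeric"))

setValidity("PopulationSpec", function(object) {
    msg <- character()
    if (length(object@name) != 1L || !nzchar(object@name))
        msg <- c(msg, "population name must be a single non-empty string")
    if (object@nCells < 1L) msg <- c(msg, "nCells must be >= 1")
    if (anyDuplicated(object@markerGenes))
        msg <- c(msg, "duplicated marker genes")
    if (object@markerFold < 1) msg <- c(msg, "markerFold must be >= 1")
    if (object@baselineMean <= 0) msg <- c(msg, "baselineMean must be > 0")
    if (object@dispersion <= 0) msg <- c(msg, "dispersion must be > 0")
    if (object@dropoutExtra < 0 || object@dropoutExtra >= 1)
        msg <- c(msg, "dropoutExtra must be in [0, 1)")
    if (length(msg)) msg else TRUE
})

#' @exportClass SyntheticDataset
setClass("SyntheticDataset",
    representation(matrix = "FeatureMatrix", truth = "CellLabels",
                   specEcho = "list"))

setValidity("SyntheticDataset", function(object) {
    if (!identical(rownames(object@matrix@values), object@truth@cellIds))
        "truth labels must cover exactly the matrix cells, in order"
    else TRUE
})

#' ConfusionCounts: 2x2 confusion tallies for one target population
#' @exportClass ConfusionCounts
setClass("ConfusionCounts",
    representation(tp = "integer", fp = "integer", fn = "integer",
                   tn = "integer"))

setValidity("ConfusionCounts", function(object) {
    cnt <- c(object@tp, object@fp, object@fn, object@tn)
    if (length(cnt) != 4L || anyNA(cnt) || any(cnt < 0))
        "tp, fp, fn, tn must be single non-negative integers"
    else TRUE
})

#' EvalReport: per-(model, dataset) metrics plus unweighted means
#' @exportClass EvalReport
setClass("EvalReport",
    representation(results = "data.frame", meanPrecision = "numeric",
                   meanMCC = "numeric"))
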