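## coerce any numeric matrix-like to a general sparse column matrix
.asDgc <- function(m) {
    if (is(m, "dgCMatrix")) return(m)
    m <- as(as(as(Matrix(m, sparse = TRUE), "dMatrix"), "generalMatrix"),
            "CsparseMatrix")
    m
}

#' Construct a FeatureMatrix
#'
#' @param values numeric matrix-like, cells in rows, features in columns.
#'   Dense matrices are converted to sparse storage.
#' @param cellIds,featureIds identifiers; default to the dimnames of
#'   `values`.
#' @param modality free-form modality tag; `"adt"` marks small antibody
#'   panels (skips highly-variable-feature selection in [embedCells()]).
#' @return a \linkS4class{FeatureMatrix}.
#' @examples
#' m <- matrix(rpois(12, 2), nrow = 3,
#'             dimnames = list(paste0("c", 1:3), paste0("g", 1:4)))
#' fm <- FeatureMatrix(m)
#' nCells(fm)
#' @export
FeatureMatrix <- function(values, cellIds = rownames(values),
                          featureIds = colnames(values), modality = "rna") {
    v <- .asDgc(values)
    if (!is.null(cellIds)) rownames(v) <- as.character(cellIds)
    if (!is.null(featureIds)) colnames(v) <- as.character(featureIds)
    new("FeatureMatrix", values = v, modality = as.character(modality))
}

#' @rdname FeatureMatrix-class
#' @aliases cellIds,FeatureMatrix-method
setMethod("cellIds", "FeatureMatrix", function(x) rownames(x@values))

#' @rdname FeatureMatrix-class
setMethod("featureIds", "FeatureMatrix", function(x) colnames(x@values))

#' @rdname FeatureMatrix-class
setMethod("modality", "FeatureMatrix", function(x) x@modality)

#' @rdname FeatureMatrix-class
setMethod("counts", "FeatureMatrix", function(x) x@values)

#' @rdname FeatureMatrix-class
setMethod("nCells", "FeatureMatrix", function(x) nrow(x@values))

#' @rdname FeatureMatrix-class
setMethod("nFeatures", "FeatureMatrix", function(x) ncol(x@values))

#' @rdname FeatureMatrix-class
setMethod("dim", "FeatureMatrix", function(x) dim(x@values))

#' @rdname FeatureMatrix-class
#' @param i,j cell / feature indices (integer, logical or character)
#' @param drop ignored; subsetting always returns a FeatureMatrix
#' @param ... ignored
setMethod("[", "FeatureMatrix", function(x, i, j, ..., drop = FALSE) {
    v <- x@values
    if (!missing(i)) v <- v[i, , drop = FALSE]
    if (!missing(j)) v <- v[, j, drop = FALSE]
    new("FeatureMatrix", values = v, modality = x@modality)
})

setMethod("show", "FeatureMatrix", function(object) {
    v <- object@values
    dens <- if (length(v)) length(v@x) / length(v) else 0
    cat(sprintf("FeatureMatrix: %d cells x %d features [%s], %.1f%% nonzero\n",
                nrow(v), ncol(v), object@modality, 100 * dens))
})

#' @rdname CellLabels-class
#' @param cellIds cell identifiers
#' @param labels one label per cell
#' @export
CellLabels <- function(cellIds, labels) {
    new("CellLabels", cellIds = as.character(cellIds),
        labels = as.character(labels))
}

#' @rdname CellLabels-class
setMethod("cellIds", "CellLabels", function(x) x@cellIds)

#' @rdname CellLabels-class
setMethod("cellLabels", "CellLabels", function(x)
    stats::setNames(x@labels, x@cellIds))

setMethod("show", "CellLabels", function(object) {
    tab <- table(object@labels)
    cat(sprintf("CellLabels: %d cells, %d classes (%s)\n",
                length(object@cellIds), length(tab),
                paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
})

#' @rdname ScoreMatrix-class
setMethod("scoreValues", "ScoreMatrix", function(x) x@values)

#' @rdname ScoreMatrix-class
setMethod("isSmoothed", "ScoreMatrix", function(x) x@smoothed)

#' @rdname ScoreMatrix-class
setMethod("signatureNames", "ScoreMatrix", function(x) colnames(x@values))

#' @rdname ScoreMatrix-class
setMethod("cellIds", "ScoreMatrix", function(x) rownames(x@values))

setMethod("show", "ScoreMatrix", function(object) {
    cat(sprintf("ScoreMatrix: %d cells x %d signatures (%s)\n",
                nrow(object@values), ncol(object@values),
                if (object@smoothed) "kNN-smoothed" else "raw"))
})

#' @rdname PurityCall-class
setMethod("cellIds", "PurityCall", function(x) x@cellIds)

#' @rdname PurityCall-class
setMethod("finalLabels", "PurityCall", function(x)
    stats::setNames(x@final, x@cellIds))

#' @rdname PurityCall-class
setMethod("levelFlags", "PurityCall", function(x) x@perLevel)

setMethod("show", "PurityCall", function(object) {
    cat(sprintf("PurityCall: %d cells, %d level(s), %d Pure / %d Impure\n",
                length(object@cellIds), ncol(object@perLevel),
                sum(object@final == "Pure"), sum(object@final == "Impure")))
})
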