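#' @rdname FeatureMatrix-class
#' @param object,x a MarkerGate object
#' @export
setGeneric("cellIds", function(x) standardGeneric("cellIds"))

#' @rdname FeatureMatrix-class
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))

#' @rdname FeatureMatrix-class
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))

#' @rdname FeatureMatrix-class
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))

#' @rdname FeatureMatrix-class
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' @rdname FeatureMatrix-class
#' @export
setGeneric("nFeatures", function(x) standardGeneric("nFeatures"))

#' @rdname CellLabels-class
#' @export
setGeneric("cellLabels", function(x) standardGeneric("cellLabels"))

#' @rdname ScoreMatrix-class
#' @export
setGeneric("scoreValues", function(x) standardGeneric("scoreValues"))

#' @rdname ScoreMatrix-class
#' @export
setGeneric("isSmoothed", function(x) standardGeneric("isSmoothed"))

#' @rdname ScoreMatrix-class
#' @export
setGeneric("signatureNames", function(x) standardGeneric("signatureNames"))

#' @rdname PurityCall-class
#' @export
setGeneric("finalLabels", function(x) standardGeneric("finalLabels"))

#' @rdname PurityCall-class
#' @export
setGeneric("levelFlags", function(x) standardGeneric("levelFlags"))

#' @rdname GatingModel-class
#' @export
setGeneric("modelName", function(x) standardGeneric("modelName"))

#' @rdname GatingModel-class
#' @export
setGeneric("modelLevels", function(x) standardGeneric("modelLevels"))

#' @rdname GatingModel-class
#' @export
setGeneric("modelSignatures", function(x) standardGeneric("modelSignatures"))
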