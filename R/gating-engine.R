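## ---------------------------------------------------------------------------
## Hierarchical gating: fixed thresholds over kNN-smoothed scores,
## applied level by level. Level 1 sees all cells; level k only the
## survivors of level k-1, whose neighbour graph is (by default)
## recomputed on the surviving subset so that smoothing at deeper levels
## happens among the relevant cells only.
## ---------------------------------------------------------------------------

#' Gating parameters
#'
#' @param posThreshold smoothed-score threshold a positive signature
#'   must reach (inclusive, `>=`) for a cell to pass a level. Default 0.2.
#' @param negThreshold smoothed-score threshold at which a negative
#'   (veto) signature rejects a cell (a cell passes only while every
#'   negative signature stays strictly below it). Default 0.2.
#' @param recomputeGraphPerLevel recompute embedding + kNN graph on the
#'   surviving subset before each deeper level (default TRUE).
#' @param signatureThresholds optional named numeric vector overriding
#'   the default threshold for individual signatures.
#' @return a \linkS4class{GateParams}.
#' @export
gateParams <- function(posThreshold = 0.2, negThreshold = 0.2,
                       recomputeGraphPerLevel = TRUE,
                       signatureThresholds = numeric()) {
    p <- new("GateParams", posThreshold = as.numeric(posThreshold),
             negThreshold = as.numeric(negThreshold),
             recomputeGraphPerLevel = as.logical(recomputeGraphPerLevel),
             signatureThresholds = signatureThresholds)
    validObject(p)
    p
}

.sigThreshold <- function(params, sigName, default) {
    ov <- params@signatureThresholds
    if (length(ov) && sigName %in% names(ov)) ov[[sigName]] else default
}

#' Apply one gating level to smoothed scores
#'
#' A cell passes iff the maximum over the level's positive signatures
#' reaches the positive threshold (inclusive) AND every negative
#' signature stays strictly below the negative threshold. Cells outside
#' `active` remain failed.
#'
#' @param smoothed a smoothed \linkS4class{ScoreMatrix} holding a column
#'   for every signature of the level.
#' @param level a \linkS4class{GatingLevel}.
#' @param params a \linkS4class{GateParams}.
#' @param active logical mask of cells still in play (default: all).
#' @return logical vector over the cells of `smoothed`.
#' @export
gateLevel <- function(smoothed, level, params = gateParams(), active = NULL) {
    stopifnot(is(smoothed, "ScoreMatrix"), is(level, "GatingLevel"),
              is(params, "GateParams"))
    if (!isSmoothed(smoothed))
        .stopf("gating requires kNN-smoothed scores")
    v <- smoothed@values
    need <- vapply(c(level@positive, level@negative),
                   function(s) s@name, character(1))
    miss <- setdiff(need, colnames(v))
    if (length(miss))
        .stopf("score matrix lacks signature column(s): %s",
               paste(miss, collapse = ", "))
    if (is.null(active)) active <- rep(TRUE, nrow(v))

    pass <- rep(FALSE, nrow(v))
    for (s in level@positive)
        pass <- pass | (v[, s@name] >=
                        .sigThreshold(params, s@name, params@posThreshold))
    for (s in level@negative)
        pass <- pass & (v[, s@name] <
                        .sigThreshold(params, s@name, params@negThreshold))
    unname(pass & active)
}

#' Run a hierarchical gating model over a feature matrix
#'
#' The full pipeline: validate the model against the matrix features,
#' score every signature per cell (rank-based, see
#' [scoreSignatures()]), then for each level embed the active cells,
#' build the kNN graph, smooth the raw scores over it and apply the
#' level's thresholds. The rank ceiling is resolved once on the full
#' matrix so scores are comparable across levels. If fewer than 2 cells
#' survive into a deeper level, the remaining levels pass the survivors
#' through with a warning (no neighbourhood can be formed). The run is
#' deterministic given `seed`.
#'
#' @param x a \linkS4class{FeatureMatrix}.
#' @param model a \linkS4class{GatingModel}; every signature must keep
#'   at least one positive gene present in the matrix.
#' @param scoring a \linkS4class{ScoringParams}.
#' @param gate a \linkS4class{GateParams}.
#' @param smooth a \linkS4class{SmoothParams}.
#' @param seed integer seed threaded through the pipeline.
#' @return a \linkS4class{PurityCall}.
#' @examples
#' ds <- presetDataset("nk-vs-t", seed = 42, nCellsPerPop = 60,
#'                     nFeatures = 300)
#' nk <- gatingModel("NK", c("NCAM1", "KLRD1", "CD3D-"))
#' calls <- runGating(dataMatrix(ds), nk,
#'                    smooth = smoothParams(k = 10, nHVG = 200, nPCs = 10))
#' table(finalLabels(calls), cellLabels(truthLabels(ds)))
#' @export
runGating <- function(x, model, scoring = scoringParams(),
                      gate = gateParams(), smooth = smoothParams(),
                      seed = 0L) {
    stopifnot(is(x, "FeatureMatrix"), is(model, "GatingModel"),
              is(scoring, "ScoringParams"), is(gate, "GateParams"),
              is(smooth, "SmoothParams"))
    n <- nCells(x)
    if (n == 0L) .stopf("matrix has zero cells")
    rep <- validateModelFeatures(model, featureIds(x))
    if (!rep$usable)
        .stopf("model '%s' is unusable on this matrix: signature(s) %s lost all positive genes",
               modelName(model), paste(rep$unusable, collapse = ", "))
    if (nrow(rep$missing))
        warning(sprintf("model '%s': %d gene(s) absent from the matrix",
                        modelName(model), nrow(rep$missing)), call. = FALSE)

    old <- .saveSeed()
    on.exit(.restoreSeed(old))
    set.seed(as.integer(seed) %% .Machine$integer.max)

    maxRank <- if (is.na(scoring@maxRank)) autoMaxRank(x) else scoring@maxRank
    raw <- suppressWarnings(
        scoreSignatures(x, model, scoringParams(maxRank, scoring@wNeg)))

    nLvl <- length(model@levels)
    perLevel <- matrix(FALSE, nrow = n, ncol = nLvl,
                       dimnames = list(cellIds(x),
                                       paste0("level", seq_len(nLvl))))
    active <- rep(TRUE, n)

    smFull <- NULL
    if (!gate@recomputeGraphPerLevel) {
        emb <- embedCells(x, smooth, seed)
        smFull <- smoothScores(raw, knnGraph(emb, smooth@k))
    }

    for (l in seq_len(nLvl)) {
        sub <- which(active)
        if (length(sub) == 0L) break
        if (gate@recomputeGraphPerLevel) {
            if (length(sub) < 2L) {
                warning(sprintf(
                    "only %d cell(s) reached level %d; passing survivors through",
                    length(sub), l), call. = FALSE)
                perLevel[sub, l:nLvl] <- TRUE
                break
            }
            emb <- embedCells(x[sub, ], smooth, seed)
            smSub <- smoothScores(
                new("ScoreMatrix", values = raw@values[sub, , drop = FALSE],
                    smoothed = FALSE),
                knnGraph(emb, smooth@k))
            pass <- gateLevel(smSub, model@levels[[l]], gate)
            perLevel[sub[pass], l] <- TRUE
            active[sub[!pass]] <- FALSE
        } else {
            pass <- gateLevel(smFull, model@levels[[l]], gate, active)
            perLevel[pass, l] <- TRUE
            active <- pass
        }
    }

    final <- ifelse(rowSums(perLevel) == nLvl, "Pure", "Impure")
    calls <- new("PurityCall", cellIds = cellIds(x), perLevel = perLevel,
                 final = unname(final))
    validObject(calls)
    calls
}

.saveSeed <- function() {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv())
    else NULL
}

.restoreSeed <- function(old) {
    if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
}
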