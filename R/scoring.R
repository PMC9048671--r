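## ---------------------------------------------------------------------------
## Rank-based per-cell signature scoring.
##
## Within each cell, features are ranked by descending value (average
## ranks on ties); ranks beyond the rank ceiling maxRank are clamped to
## maxRank + 1, so a feature ranked past the ceiling contributes nothing.
## For a signature of n positive genes with (clamped) ranks r_1..r_n:
##
##     U = sum(r_i) - n (n + 1) / 2        (Mann-Whitney U)
##     S = 1 - U / (n * maxRank)           in [0, 1]
##
## Negated genes ("CD3D-") are scored identically as their own set and
## subtracted: score = clamp(S_pos - wNeg * S_neg, 0, 1).
## ---------------------------------------------------------------------------

#' Scoring parameters
#'
#' @param maxRank rank ceiling. `NA` (default) selects it from the data
#'   via [autoMaxRank()]: the smaller of 1500 (the conventional ceiling
#'   for whole-transcriptome data), the median per-cell number of
#'   detected features (the scale at which a cell's ranking stops being
#'   informative), and the feature count minus one. An explicit value is
#'   used as given.
#' @param wNeg weight of the negated-gene score subtraction (default 1).
#' @return a \linkS4class{ScoringParams}.
#' @export
scoringParams <- function(maxRank = NA, wNeg = 1) {
    p <- new("ScoringParams", maxRank = as.integer(maxRank),
             wNeg = as.numeric(wNeg))
    validObject(p)
    p
}

#' Automatic rank-ceiling choice
#'
#' The rank ceiling marks the boundary beyond which a feature is treated
#' as not meaningfully expressed in a cell. The conventional value 1500
#' presumes a whole-transcriptome feature space; for smaller feature
#' spaces it is lowered to the median per-cell number of detected
#' (nonzero) features, so that undetected features -- whose tie-averaged
#' rank always lies beyond that median -- contribute zero signal, and is
#' always at most `nFeatures(x) - 1` so the ceiling is attainable.
#'
#' @param x a \linkS4class{FeatureMatrix}.
#' @return integer rank ceiling (at least 2).
#' @export
autoMaxRank <- function(x) {
    stopifnot(is(x, "FeatureMatrix"))
    detected <- Matrix::rowSums(x@values > 0)
    med <- as.integer(stats::median(detected))
    max(2L, min(1500L, nFeatures(x) - 1L, med))
}

#' Rank features of one cell with a rank ceiling
#'
#' Ranks are assigned by descending value; tied values receive the mean
#' of their rank span; every rank exceeding `maxRank` is replaced by
#' `maxRank + 1`.
#'
#' @param expression finite non-negative numeric vector (one cell's
#'   values across features).
#' @param maxRank rank ceiling, >= 1.
#' @return numeric rank vector of the same length.
#' @examples
#' rankFeatures(c(9, 4, 4, 1), maxRank = 10)  # 1, 2.5, 2.5, 4
#' @export
rankFeatures <- function(expression, maxRank) {
    if (length(maxRank) != 1L || is.na(maxRank) || maxRank < 1)
        .stopf("maxRank must be a single value >= 1")
    if (any(!is.finite(expression)) || any(expression < 0))
        .stopf("expression must be finite and non-negative")
    r <- rank(-expression, ties.method = "average")
    r[r > maxRank] <- maxRank + 1
    r
}

## cells x features matrix of clamped descending ranks
.rankMatrix <- function(x, maxRank) {
    dense <- as.matrix(x@values)
    r <- t(apply(dense, 1L, function(row) rank(-row, ties.method = "average")))
    r[r > maxRank] <- maxRank + 1
    dimnames(r) <- dimnames(dense)
    r
}

## signature score from a precomputed clamped rank matrix
.scoreFromRanks <- function(ranks, sig, maxRank, wNeg, warnMissing = TRUE) {
    present <- sig@genes %in% colnames(ranks)
    if (warnMissing && any(!present))
        warning(sprintf("signature '%s': dropping %d gene(s) absent from the matrix (%s)",
                        sig@name, sum(!present),
                        paste(sig@genes[!present], collapse = ", ")),
                call. = FALSE)
    genes <- sig@genes[present]
    signs <- sig@signs[present]
    pos <- genes[signs == 1L]
    if (!length(pos))
        .stopf("signature '%s' has no usable positive genes in this matrix",
               sig@name)
    uScore <- function(set) {
        n <- length(set)
        R <- rowSums(ranks[, set, drop = FALSE])
        U <- R - n * (n + 1) / 2
        1 - U / (n * maxRank)
    }
    s <- uScore(pos)
    negGenes <- genes[signs == -1L]
    if (length(negGenes)) s <- s - wNeg * uScore(negGenes)
    pmin(1, pmax(0, s))
}

#' Score signatures across all cells
#'
#' Computes the rank-based signature score of each cell for each
#' signature (see the package vignette for the statistic). Scores depend
#' only on within-cell feature ranks, so they are invariant under any
#' strictly monotone transform of a cell's expression vector and need no
#' prior normalization. Positive genes absent from the matrix are
#' dropped with a warning; a signature whose positive genes are all
#' absent raises an error naming it.
#'
#' @param x a \linkS4class{FeatureMatrix}.
#' @param signatures a \linkS4class{Signature}, a list of them, or a
#'   \linkS4class{GatingModel} (all its signatures are scored).
#' @param params a \linkS4class{ScoringParams}.
#' @return a raw (unsmoothed) \linkS4class{ScoreMatrix}, cells x
#'   signatures, values in [0, 1].
#' @examples
#' m <- matrix(rpois(600, 1), nrow = 20,
#'             dimnames = list(sprintf("c%02d", 1:20), sprintf("g%02d", 1:30)))
#' fm <- FeatureMatrix(m)
#' sc <- scoreSignatures(fm, markerSignature("sig", c("g01", "g02")))
#' range(scoreValues(sc))
#' @export
scoreSignatures <- function(x, signatures, params = scoringParams()) {
    stopifnot(is(x, "FeatureMatrix"), is(params, "ScoringParams"))
    if (is(signatures, "GatingModel")) signatures <- modelSignatures(signatures)
    if (is(signatures, "Signature")) signatures <- list(signatures)
    stopifnot(length(signatures) >= 1L,
              all(vapply(signatures, is, logical(1), class2 = "Signature")))
    maxRank <- if (is.na(params@maxRank)) autoMaxRank(x) else params@maxRank
    ranks <- .rankMatrix(x, maxRank)
    vals <- vapply(signatures, function(sig)
        .scoreFromRanks(ranks, sig, maxRank, params@wNeg),
        numeric(nrow(ranks)))
    if (nrow(ranks) == 1L) vals <- matrix(vals, nrow = 1L)
    dimnames(vals) <- list(cellIds(x),
                           vapply(signatures, function(s) s@name, character(1)))
    new("ScoreMatrix", values = vals, smoothed = FALSE)
}

#' @rdname scoreSignatures
#' @param signature a single \linkS4class{Signature}.
#' @return `scoreSignature()` returns a named numeric vector over cells.
#' @export
scoreSignature <- function(x, signature, params = scoringParams()) {
    drop(scoreValues(scoreSignatures(x, signature, params))[, 1L])
}
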