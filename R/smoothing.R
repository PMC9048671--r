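## ---------------------------------------------------------------------------
## Neighbourhood construction and score smoothing.
##
## Raw signature scores are noisy because of dropout; replacing each
## cell's score by the mean over its k nearest transcriptional
## neighbours shrinks that noise roughly by sqrt(k) while preserving
## population-level structure, provided neighbourhoods stay within
## populations. Neighbour space: library-size scaling to a fixed target
## sum, log1p, highly-variable-feature selection, per-feature
## standardization, exact truncated PCA.
## ---------------------------------------------------------------------------

#' Smoothing parameters
#'
#' @param k neighbourhood size, the cell itself included (so `k = 1`
#'   makes smoothing the identity). Default 30: large enough to shrink
#'   per-cell score noise by about 5.5-fold, small enough that
#'   neighbourhoods of populations of a few hundred cells stay within
#'   the population (see the vignette for the choice).
#' @param nHVG number of highly variable features kept for the
#'   embedding (default 800); ADT matrices skip selection and use all
#'   features.
#' @param nPCs number of principal components (default 30).
#' @param targetSum per-cell library-size target (default 1e4).
#' @return a \linkS4class{SmoothParams}.
#' @export
smoothParams <- function(k = 30, nHVG = 800, nPCs = 30, targetSum = 1e4) {
    p <- new("SmoothParams", k = as.integer(k), nHVG = as.integer(nHVG),
             nPCs = as.integer(nPCs), targetSum = as.numeric(targetSum))
    validObject(p)
    p
}

#' Embed cells into principal-component space
#'
#' Pipeline: per-cell total-count scaling to `targetSum`, `log1p`,
#' selection of the `nHVG` most variable features (variance of the log
#' values; skipped for `"adt"` matrices), per-feature standardization,
#' exact truncated PCA to `min(nPCs, rank)` dimensions. The
#' decomposition is deterministic (component signs are fixed by making
#' each loading's largest-magnitude entry positive); `seed` is accepted
#' for interface uniformity with the stochastic stages.
#'
#' @param x a \linkS4class{FeatureMatrix} with at least 2 cells.
#' @param params a \linkS4class{SmoothParams}.
#' @param seed unused by the exact decomposition; kept so callers can
#'   thread one seed through the whole pipeline.
#' @return numeric matrix, cells x components, rownames = cell ids.
#' @export
embedCells <- function(x, params = smoothParams(), seed = 0L) {
    stopifnot(is(x, "FeatureMatrix"), is(params, "SmoothParams"))
    if (nCells(x) < 2L) .stopf("embedding needs at least 2 cells")
    m <- as.matrix(x@values)
    tot <- rowSums(m)
    sf <- ifelse(tot > 0, params@targetSum / tot, 0)
    ln <- log1p(m * sf)

    n <- nrow(ln)
    cm <- colMeans(ln)
    v <- (colMeans(ln * ln) - cm^2) * n / (n - 1)
    keep <- which(v > 0)
    if (length(keep) < 2L)
        .stopf("fewer than 2 features with nonzero variance")
    if (!identical(x@modality, "adt") && length(keep) > params@nHVG)
        keep <- keep[order(-v[keep], keep)][seq_len(params@nHVG)]
    keep <- sort(keep)
    z <- scale(ln[, keep, drop = FALSE], center = cm[keep],
               scale = sqrt(v[keep]))

    q <- min(params@nPCs, ncol(z), nrow(z) - 1L)
    sv <- svd(z, nu = q, nv = q)
    ## fix the sign indeterminacy of each component
    for (j in seq_len(q)) {
        i <- which.max(abs(sv$v[, j]))
        if (sv$v[i, j] < 0) {
            sv$u[, j] <- -sv$u[, j]
            sv$v[, j] <- -sv$v[, j]
        }
    }
    emb <- sv$u %*% diag(sv$d[seq_len(q)], q)
    rownames(emb) <- cellIds(x)
    colnames(emb) <- paste0("PC", seq_len(q))
    emb
}

#' Exact k-nearest-neighbour graph
#'
#' Euclidean kNN with the cell itself always the first neighbour;
#' distance ties among other cells are broken by lower cell index.
#'
#' @param embedding numeric matrix, cells x dimensions.
#' @param k neighbourhood size including self; lists are truncated to
#'   `min(k, nCells)`.
#' @return a \linkS4class{NeighborGraph}.
#' @export
knnGraph <- function(embedding, k) {
    embedding <- as.matrix(embedding)
    if (length(k) != 1L || is.na(k) || k < 1) .stopf("k must be >= 1")
    k <- as.integer(k)
    n <- nrow(embedding)
    kEff <- min(k, n)
    d <- as.matrix(stats::dist(embedding))
    idx <- matrix(0L, nrow = n, ncol = kEff)
    ord <- seq_len(n)
    for (i in seq_len(n)) {
        o <- order(d[i, ], ord)
        o <- o[o != i]
        idx[i, ] <- c(i, o)[seq_len(kEff)]
    }
    new("NeighborGraph", indices = idx, k = k,
        embeddingDims = ncol(embedding))
}

#' Smooth signature scores over a neighbour graph
#'
#' Replaces each cell's score by the unweighted mean of its neighbour
#' list's raw scores (self included). Smoothed values are convex
#' combinations of raw values, so per signature they stay within the raw
#' [min, max]; constant score fields are fixed points and `k = 1` is the
#' identity.
#'
#' @param scores a raw \linkS4class{ScoreMatrix}.
#' @param graph a \linkS4class{NeighborGraph} over the same cells.
#' @return a smoothed \linkS4class{ScoreMatrix}.
#' @export
smoothScores <- function(scores, graph) {
    stopifnot(is(scores, "ScoreMatrix"), is(graph, "NeighborGraph"))
    if (isSmoothed(scores)) .stopf("scores are already smoothed")
    v <- scores@values
    idx <- graph@indices
    if (nrow(idx) != nrow(v))
        .stopf("graph covers %d cells but scores cover %d",
               nrow(idx), nrow(v))
    out <- matrix(0, nrow = nrow(v), ncol = ncol(v), dimnames = dimnames(v))
    for (j in seq_len(ncol(idx)))
        out <- out + v[idx[, j], , drop = FALSE]
    out <- out / ncol(idx)
    ## guard against float drift at the [0,1] boundary
    out[out < 0] <- 0
    out[out > 1] <- 1
    new("ScoreMatrix", values = out, smoothed = TRUE)
}
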