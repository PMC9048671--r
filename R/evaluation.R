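## ---------------------------------------------------------------------------
## Evaluation of gating calls against annotated truth: confusion counts,
## precision / recall / Matthews correlation, and batch evaluation of a
## model collection over annotated datasets.
## ---------------------------------------------------------------------------

#' Confusion counts of gating calls against truth labels
#'
#' Cells are joined by id (order-independent); cells present on only one
#' side are dropped with a message. tp counts cells called Pure whose
#' truth equals `targetLabel`, fp those called Pure with another truth,
#' fn Impure cells of the target, tn the rest.
#'
#' @param calls a \linkS4class{PurityCall}.
#' @param truth a \linkS4class{CellLabels}.
#' @param targetLabel the truth label the model is meant to purify.
#' @return a \linkS4class{ConfusionCounts}.
#' @export
confusionCounts <- function(calls, truth, targetLabel) {
    stopifnot(is(calls, "PurityCall"), is(truth, "CellLabels"))
    common <- intersect(calls@cellIds, truth@cellIds)
    if (!length(common))
        .stopf("calls and truth share no cell ids")
    dropped <- (length(calls@cellIds) - length(common)) +
        (length(truth@cellIds) - length(common))
    if (dropped > 0L)
        message(sprintf("confusionCounts: dropped %d cell(s) present on one side only",
                        dropped))
    pure <- finalLabels(calls)[common] == "Pure"
    isTarget <- cellLabels(truth)[common] == targetLabel
    new("ConfusionCounts",
        tp = sum(pure & isTarget), fp = sum(pure & !isTarget),
        fn = sum(!pure & isTarget), tn = sum(!pure & !isTarget))
}

setMethod("show", "ConfusionCounts", function(object) {
    cat(sprintf("ConfusionCounts: tp=%d fp=%d fn=%d tn=%d (n=%d)\n",
                object@tp, object@fp, object@fn, object@tn,
                object@tp + object@fp + object@fn + object@tn))
})

#' Precision, recall and Matthews correlation from confusion counts
#'
#' \deqn{MCC = (tp \cdot tn - fp \cdot fn) /
#'       \sqrt{(tp+fp)(tp+fn)(tn+fp)(tn+fn)}}
#' When a metric's denominator vanishes the metric is reported as 0 and
#' flagged undefined rather than NaN, so downstream aggregation stays
#' stable.
#'
#' @param counts a \linkS4class{ConfusionCounts}.
#' @return list with `precision`, `recall`, `mcc` and logical flags
#'   `precisionDefined`, `recallDefined`, `mccDefined`.
#' @examples
#' classificationMetrics(new("ConfusionCounts", tp = 3L, fp = 1L,
#'                           fn = 1L, tn = 5L))
#' @export
classificationMetrics <- function(counts) {
    stopifnot(is(counts, "ConfusionCounts"))
    tp <- as.numeric(counts@tp); fp <- as.numeric(counts@fp)
    fn <- as.numeric(counts@fn); tn <- as.numeric(counts@tn)
    precisionDefined <- (tp + fp) > 0
    recallDefined <- (tp + fn) > 0
    factors <- c(tp + fp, tp + fn, tn + fp, tn + fn)
    mccDefined <- all(factors > 0)
    list(
        precision = if (precisionDefined) tp / (tp + fp) else 0,
        recall = if (recallDefined) tp / (tp + fn) else 0,
        mcc = if (mccDefined) (tp * tn - fp * fn) / sqrt(prod(factors)) else 0,
        precisionDefined = precisionDefined,
        recallDefined = recallDefined,
        mccDefined = mccDefined)
}

#' Evaluate gating models over annotated datasets
#'
#' Runs every model on every dataset it is paired with and tabulates
#' confusion counts and metrics against the dataset's truth labels.
#' `datasets` is a list of entries, each a list with elements `matrix`
#' (\linkS4class{FeatureMatrix}), `truth` (\linkS4class{CellLabels}),
#' `target` (truth label the model purifies) and optionally `name`.
#' When `pairs` is NULL every model is run on every dataset; otherwise
#' `pairs` is a two-column data.frame (`model`, `dataset`) naming the
#' combinations to run. Rows are ordered by model then dataset name;
#' unweighted means of precision and MCC across rows are attached.
#'
#' @param models named list of \linkS4class{GatingModel} (e.g. from
#'   [loadModelDB()]).
#' @param datasets list of annotated datasets (see Details).
#' @param pairs optional data.frame restricting (model, dataset) pairs.
#' @param scoring,gate,smooth,seed forwarded to [runGating()].
#' @return an \linkS4class{EvalReport}.
#' @export
evaluateModels <- function(models, datasets, pairs = NULL,
                           scoring = scoringParams(), gate = gateParams(),
                           smooth = smoothParams(), seed = 0L) {
    stopifnot(is.list(models), length(models) >= 1L,
              is.list(datasets), length(datasets) >= 1L)
    if (is.null(names(models)))
        names(models) <- vapply(models, modelName, character(1))
    dsNames <- vapply(seq_along(datasets), function(i) {
        nm <- datasets[[i]]$name
        if (is.null(nm)) sprintf("dataset%d", i) else nm
    }, character(1))
    names(datasets) <- dsNames
    if (is.null(pairs))
        pairs <- expand.grid(model = names(models), dataset = dsNames,
                             stringsAsFactors = FALSE)
    pairs <- pairs[order(pairs$model, pairs$dataset), , drop = FALSE]

    rows <- lapply(seq_len(nrow(pairs)), function(i) {
        mdl <- models[[pairs$model[i]]]
        ds <- datasets[[pairs$dataset[i]]]
        calls <- runGating(ds$matrix, mdl, scoring = scoring, gate = gate,
                           smooth = smooth, seed = seed)
        cnt <- confusionCounts(calls, ds$truth, ds$target)
        met <- classificationMetrics(cnt)
        data.frame(model = pairs$model[i], dataset = pairs$dataset[i],
                   target = ds$target, tp = cnt@tp, fp = cnt@fp,
                   fn = cnt@fn, tn = cnt@tn,
                   precision = met$precision, recall = met$recall,
                   mcc = met$mcc, stringsAsFactors = FALSE)
    })
    results <- do.call(rbind, rows)
    rownames(results) <- NULL
    new("EvalReport", results = results,
        meanPrecision = mean(results$precision),
        meanMCC = mean(results$mcc))
}

#' @rdname evaluateModels
#' @param x an \linkS4class{EvalReport}.
#' @export
evalResults <- function(x) {
    stopifnot(is(x, "EvalReport"))
    x@results
}

setMethod("show", "EvalReport", function(object) {
    cat(sprintf("EvalReport: %d row(s), mean precision %.3f, mean MCC %.3f\n",
                nrow(object@results), object@meanPrecision, object@meanMCC))
})

#' Write an evaluation report as TSV
#'
#' One row per (model, dataset) plus a trailing SUMMARY row carrying the
#' unweighted mean precision and MCC.
#'
#' @param report an \linkS4class{EvalReport}.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeEvalReport <- function(report, path) {
    stopifnot(is(report, "EvalReport"))
    df <- report@results
    summary <- df[0, ]
    summary[1, ] <- NA
    summary$model <- "SUMMARY"
    summary$dataset <- ""
    summary$target <- ""
    summary$precision <- report@meanPrecision
    summary$mcc <- report@meanMCC
    out <- rbind(df, summary)
    .atomicWrite(path, function(tmp)
        utils::write.table(out, tmp, sep = "\t", quote = FALSE,
                           row.names = FALSE, na = ""))
}
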