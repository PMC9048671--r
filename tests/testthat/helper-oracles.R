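# Independent oracles, kept deliberately naive: they share no code with
# the implementation paths they check.

# Mann-Whitney U of a signature within one cell by explicit pairwise
# comparison: for every (signature gene, other feature) pair, count a
# win for the pair when the other feature is expressed higher (ties
# count half). Score via the same normalization as the package.
bruteSignatureScore <- function(expression, sigIdx, maxRank) {
    other <- setdiff(seq_along(expression), sigIdx)
    U <- 0
    for (g in sigIdx)
        for (h in other) {
            if (expression[h] > expression[g]) U <- U + 1
            else if (expression[h] == expression[g]) U <- U + 0.5
        }
    1 - U / (length(sigIdx) * maxRank)
}

# per-cell tally of confusion counts and metrics from raw vectors
bruteMetrics <- function(pure, isTarget) {
    tp <- 0; fp <- 0; fn <- 0; tn <- 0
    for (i in seq_along(pure)) {
        if (pure[i] && isTarget[i]) tp <- tp + 1
        else if (pure[i] && !isTarget[i]) fp <- fp + 1
        else if (!pure[i] && isTarget[i]) fn <- fn + 1
        else tn <- tn + 1
    }
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
    mcc <- if (den > 0) (tp * tn - fp * fn) / sqrt(den) else 0
    list(tp = tp, fp = fp, fn = fn, tn = tn,
         precision = prec, recall = rec, mcc = mcc)
}
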