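smoothedScores <- function(v, sigNames) {
    dimnames(v) <- list(sprintf("c%02d", seq_len(nrow(v))), sigNames)
    new("ScoreMatrix", values = v, smoothed = TRUE)
}

test_that("gate level combines positive max with negative veto", {
    lvl <- new("GatingLevel",
               positive = list(markerSignature("a", "G1"),
                               markerSignature("b", "G2")),
               negative = list(markerSignature("v", "G3")))
    v <- rbind(c(0.9, 0.0, 0.0),   # clear pass via 'a'
               c(0.9, 0.0, 0.8),   # vetoed by 'v'
               c(0.2, 0.0, 0.0),   # exactly at threshold: pass (>=)
               c(0.0, 0.0, 0.0),   # no positive signal
               c(0.1, 0.3, 0.19))  # passes via 'b', veto just below
    pass <- gateLevel(smoothedScores(v, c("a", "b", "v")), lvl)
    expect_identical(pass, c(TRUE, FALSE, TRUE, FALSE, TRUE))

    # negative exactly at its threshold vetoes (strict <)
    vEq <- smoothedScores(rbind(c(0.9, 0, 0.2)), c("a", "b", "v"))
    expect_false(gateLevel(vEq, lvl))

    # inactive cells stay failed
    pass2 <- gateLevel(smoothedScores(v, c("a", "b", "v")), lvl,
                       active = c(TRUE, TRUE, FALSE, TRUE, FALSE))
    expect_identical(pass2, c(TRUE, FALSE, FALSE, FALSE, FALSE))
})

test_that("gating requires smoothed scores and the level's columns", {
    lvl <- new("GatingLevel", positive = list(markerSignature("a", "G1")),
               negative = list())
    raw <- new("ScoreMatrix",
               values = matrix(0.5, 1, 1, dimnames = list("c1", "a")),
               smoothed = FALSE)
    expect_error(gateLevel(raw, lvl), "smoothed")
    sm <- smoothedScores(matrix(0.5, 1, 1), "other")
    expect_error(gateLevel(sm, lvl), "lacks signature column")
})

test_that("per-signature threshold overrides take precedence", {
    lvl <- new("GatingLevel", positive = list(markerSignature("a", "G1")),
               negative = list())
    sm <- smoothedScores(matrix(c(0.25, 0.45), ncol = 1), "a")
    expect_identical(gateLevel(sm, lvl, gateParams(posThreshold = 0.2)),
                     c(TRUE, TRUE))
    expect_identical(
        gateLevel(sm, lvl, gateParams(posThreshold = 0.2,
                                      signatureThresholds = c(a = 0.4))),
        c(FALSE, TRUE))
})

test_that("hierarchical runs are monotone and final = intersection of levels", {
    specs <- list(
        populationSpec("stroma", 70, sprintf("S.PRG%02d", 1:15)),
        populationSpec("T", 70, c("PTPRC", "CD3D", sprintf("T.PRG%02d", 1:15))),
        populationSpec("mac", 70,
                       c("PTPRC", "CD68", "FCGR1A", sprintf("M.PRG%02d", 1:15))))
    ds <- generateDataset(specs, nFeatures = 500, seed = 21)
    mdl <- parseGatingTable(writeModelFile(macrophageModelLines),
                            name = "macrophage")
    calls <- runGating(dataMatrix(ds), mdl, smooth = smallSmooth(), seed = 1)
    pl <- levelFlags(calls)
    expect_false(any(pl[, 2] & !pl[, 1]))
    expect_identical(unname(finalLabels(calls) == "Pure"),
                     unname(pl[, 1] & pl[, 2]))
    # macrophages recovered, T cells (immune but not macrophage) rejected
    truth <- cellLabels(truthLabels(ds))[cellIds(calls)]
    expect_gt(mean(pl[truth == "mac", 2]), 0.8)
    expect_lt(mean(pl[truth == "T", 2]), 0.2)
    expect_gt(mean(pl[truth == "T", 1]), 0.8)
})

test_that("identical inputs and seed reproduce identical calls", {
    ds <- smallMixture()
    mdl <- gatingModel("B", "MS4A1")
    c1 <- runGating(dataMatrix(ds), mdl, smooth = smallSmooth(), seed = 5)
    c2 <- runGating(dataMatrix(ds), mdl, smooth = smallSmooth(), seed = 5)
    expect_identical(finalLabels(c1), finalLabels(c2))
    expect_identical(levelFlags(c1), levelFlags(c2))
})

test_that("raising thresholds moves the pure set monotonically", {
    ds <- smallMixture()
    fm <- dataMatrix(ds)
    raw <- scoreSignatures(fm, markerSignature("B", "MS4A1"))
    emb <- embedCells(fm, smallSmooth())
    sm <- smoothScores(raw, knnGraph(emb, smallSmooth()@k))
    lvl <- new("GatingLevel", positive = list(markerSignature("B", "MS4A1")),
               negative = list())
    prev <- NULL
    for (thr in c(0.1, 0.3, 0.5)) {
        cur <- gateLevel(sm, lvl, gateParams(posThreshold = thr))
        if (!is.null(prev)) expect_false(any(cur & !prev))
        prev <- cur
    }

    # raising the veto threshold can only grow the pure set
    lvl2 <- new("GatingLevel", positive = list(markerSignature("B", "MS4A1")),
                negative = list(markerSignature("Tveto", "CD3D")))
    raw2 <- scoreSignatures(fm, list(markerSignature("B", "MS4A1"),
                                     markerSignature("Tveto", "CD3D")))
    sm2 <- smoothScores(raw2, knnGraph(emb, smallSmooth()@k))
    prev <- NULL
    for (thr in c(0.05, 0.2, 0.6)) {
        cur <- gateLevel(sm2, lvl2, gateParams(negThreshold = thr))
        if (!is.null(prev)) expect_false(any(prev & !cur))
        prev <- cur
    }
})

test_that("a one-level gate ignores unrelated signature columns", {
    set.seed(3)
    v <- cbind(runif(20), runif(20))
    lvl <- new("GatingLevel", positive = list(markerSignature("a", "G1")),
               negative = list())
    both <- gateLevel(smoothedScores(v, c("a", "zz")), lvl)
    alone <- gateLevel(smoothedScores(v[, 1, drop = FALSE], "a"), lvl)
    expect_identical(both, alone)
})

test_that("models whose positive genes are absent fail before computing", {
    ds <- smallMixture()
    expect_error(runGating(dataMatrix(ds), gatingModel("x", "NOT_A_GENE"),
                           smooth = smallSmooth(), seed = 1),
                 "unusable")
    expect_error(runGating(dataMatrix(ds)[0, ], gatingModel("B", "MS4A1"),
                           smooth = smallSmooth(), seed = 1),
                 "zero cells")
})

test_that("a level reached by fewer than 2 cells passes survivors through", {
    # cell c01 is the only one expressing G1; k = 1 makes smoothing the
    # identity so exactly one cell survives level 1
    m <- namedMatrix(matrix(rpois(6 * 30, 1) + 1, nrow = 6))
    m[, 1] <- 0
    m[1, 1] <- 100
    m[, 2] <- rpois(6, 3) + 1
    fm <- FeatureMatrix(m)
    mdl <- parseGatingTable(writeModelFile(c(
        "levels\tuse_as\tname\tsignature",
        "level1\tpositive\tfirst\tg01",
        "level2\tpositive\tsecond\tg02")), name = "two")
    expect_warning(
        calls <- runGating(fm, mdl, scoring = scoringParams(maxRank = 10),
                           smooth = smoothParams(k = 1, nHVG = 20, nPCs = 3),
                           seed = 1),
        "passing survivors through")
    expect_identical(unname(finalLabels(calls)["c01"]), "Pure")
    expect_identical(sum(finalLabels(calls) == "Pure"), 1L)
})

test_that("a shared graph across levels is supported", {
    ds <- smallMixture()
    mdl <- gatingModel("B", "MS4A1")
    cA <- runGating(dataMatrix(ds), mdl, smooth = smallSmooth(),
                    gate = gateParams(recomputeGraphPerLevel = FALSE),
                    seed = 2)
    cB <- runGating(dataMatrix(ds), mdl, smooth = smallSmooth(), seed = 2)
    # one-level models are unaffected by the recomputation switch
    expect_identical(finalLabels(cA), finalLabels(cB))
})
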