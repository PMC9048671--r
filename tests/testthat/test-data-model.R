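test_that("FeatureMatrix enforces its invariants", {
    m <- namedMatrix(matrix(0:5, nrow = 2))
    fm <- FeatureMatrix(m, modality = "rna")
    expect_s4_class(fm, "FeatureMatrix")
    expect_identical(dim(fm), c(2L, 3L))
    expect_identical(cellIds(fm), c("c01", "c02"))

    bad <- m; rownames(bad) <- c("a", "a")
    expect_error(FeatureMatrix(bad), "duplicated cell ids")
    bad <- m; bad[1, 1] <- -1
    expect_error(FeatureMatrix(bad), "non-negative")
    expect_error(FeatureMatrix(unname(m)), "ids")
})

test_that("FeatureMatrix subsetting keeps ids and modality", {
    fm <- randomFeatureMatrix(6, 5, seed = 1)
    sub <- fm[c(2, 4), c("g01", "g03")]
    expect_identical(cellIds(sub), c("c02", "c04"))
    expect_identical(featureIds(sub), c("g01", "g03"))
    expect_equal(as.matrix(counts(sub)),
                 as.matrix(counts(fm))[c(2, 4), c(1, 3)])
})

test_that("MTX directory read transcribes and transposes the triplet", {
    dir <- withr::local_tempdir()
    writeLines(c("%%MatrixMarket matrix coordinate integer general",
                 "3 2 2", "1 1 5", "3 2 2"),
               file.path(dir, "matrix.mtx"))
    writeLines(c("gA", "gB", "gC"), file.path(dir, "features.tsv"))
    writeLines(c("cellX", "cellY"), file.path(dir, "barcodes.tsv"))
    fm <- readMtxDir(dir)
    expect_identical(dim(fm), c(2L, 3L))
    expect_equal(unname(as.matrix(counts(fm))),
                 rbind(c(5, 0, 0), c(0, 0, 2)))
    expect_identical(cellIds(fm), c("cellX", "cellY"))
    expect_identical(featureIds(fm), c("gA", "gB", "gC"))
})

test_that("MTX read is independent of triplet body line order", {
    dirs <- c(withr::local_tempdir(), withr::local_tempdir())
    bodies <- list(c("1 1 5", "3 2 2", "2 1 7"),
                   c("2 1 7", "3 2 2", "1 1 5"))
    for (i in 1:2) {
        writeLines(c("%%MatrixMarket matrix coordinate integer general",
                     "3 2 3", bodies[[i]]), file.path(dirs[i], "matrix.mtx"))
        writeLines(c("gA", "gB", "gC"), file.path(dirs[i], "features.tsv"))
        writeLines(c("cX", "cY"), file.path(dirs[i], "barcodes.tsv"))
    }
    expect_equal(as.matrix(counts(readMtxDir(dirs[1]))),
                 as.matrix(counts(readMtxDir(dirs[2]))))
})

test_that("empty MTX body yields an all-zero matrix", {
    dir <- withr::local_tempdir()
    writeLines(c("%%MatrixMarket matrix coordinate integer general",
                 "3 2 0"), file.path(dir, "matrix.mtx"))
    writeLines(c("gA", "gB", "gC"), file.path(dir, "features.tsv"))
    writeLines(c("cX", "cY"), file.path(dir, "barcodes.tsv"))
    fm <- readMtxDir(dir)
    expect_equal(unname(as.matrix(counts(fm))), matrix(0, 2, 3))
})

test_that("MTX write/read round-trip is lossless, including gzipped inputs", {
    fm <- randomFeatureMatrix(8, 12, seed = 3,
                              rfun = function(n) rpois(n, 2))
    dir <- withr::local_tempdir()
    writeMtxDir(fm, dir)
    back <- readMtxDir(dir)
    expect_identical(cellIds(back), cellIds(fm))
    expect_identical(featureIds(back), featureIds(fm))
    expect_equal(as.matrix(counts(back)), as.matrix(counts(fm)))

    # gzip each file; reading must be transparent
    for (f in c("matrix.mtx", "features.tsv", "barcodes.tsv")) {
        con <- gzfile(file.path(dir, paste0(f, ".gz")), "wt")
        writeLines(readLines(file.path(dir, f)), con)
        close(con)
        unlink(file.path(dir, f))
    }
    backGz <- readMtxDir(dir)
    expect_equal(as.matrix(counts(backGz)), as.matrix(counts(fm)))
})

test_that("MTX reader reports missing files and dimension mismatches", {
    dir <- withr::local_tempdir()
    expect_error(readMtxDir(file.path(dir, "nope")), "not found")
    writeLines(c("%%MatrixMarket matrix coordinate integer general",
                 "3 2 0"), file.path(dir, "matrix.mtx"))
    writeLines(c("cX", "cY"), file.path(dir, "barcodes.tsv"))
    expect_error(readMtxDir(dir), "features")
    writeLines(c("gA", "gB"), file.path(dir, "features.tsv"))
    expect_error(readMtxDir(dir), "3 features")
})

test_that("dense reader honours orientation and flags bad input", {
    dir <- withr::local_tempdir()
    p <- file.path(dir, "m.tsv")
    writeLines(c("feature_id\tcX\tcY", "gA\t1\t2", "gB\t3\t4"), p)
    fm <- readDenseMatrix(p, orientation = "features")
    expect_identical(cellIds(fm), c("cX", "cY"))
    expect_equal(unname(as.matrix(counts(fm))), rbind(c(1, 3), c(2, 4)))

    writeLines(c("cell_id\tgA\tgB", "cX\t1\t3", "cY\t2\t4"), p)
    fm2 <- readDenseMatrix(p, orientation = "cells")
    expect_equal(as.matrix(counts(fm2)), as.matrix(counts(fm)))

    writeLines(c("cell_id\tgA\tgB", "cX\t1\t3", "cX\t2\t4"), p)
    expect_error(readDenseMatrix(p, orientation = "cells"), "duplicated")
    writeLines(c("cell_id\tgA\tgB", "cX\t1\toops", "cY\t2\t4"), p)
    expect_error(readDenseMatrix(p, orientation = "cells"),
                 "non-numeric value at data row 1, column 2")
})

test_that("dense write/read round-trip preserves values to full precision", {
    fm <- randomFeatureMatrix(5, 7, seed = 11)
    for (orient in c("features", "cells")) {
        p <- file.path(withr::local_tempdir(), "m.tsv")
        writeDenseMatrix(fm, p, orientation = orient)
        back <- readDenseMatrix(p, orientation = orient)
        expect_identical(cellIds(back), cellIds(fm))
        expect_equal(as.matrix(counts(back)), as.matrix(counts(fm)),
                     tolerance = 1e-12)
    }
})

test_that("purity-call TSV serializes in input order and round-trips", {
    pl <- matrix(c(TRUE, TRUE, TRUE, FALSE), nrow = 2,
                 dimnames = list(c("cA", "cB"), c("level1", "level2")))
    calls <- new("PurityCall", cellIds = c("cA", "cB"), perLevel = pl,
                 final = c("Pure", "Impure"))
    p <- file.path(withr::local_tempdir(), "calls.tsv")
    writePurityCalls(calls, p)
    lines <- readLines(p)
    expect_identical(lines[1], "cell_id\tlevel1\tlevel2\tfinal")
    expect_identical(lines[2], "cA\tTRUE\tTRUE\tPure")
    expect_identical(lines[3], "cB\tTRUE\tFALSE\tImpure")

    back <- readPurityCalls(p)
    expect_identical(cellIds(back), cellIds(calls))
    expect_identical(finalLabels(back), finalLabels(calls))
    expect_identical(unname(levelFlags(back)), unname(levelFlags(calls)))
})

test_that("zero-cell purity calls write a header-only file", {
    calls <- new("PurityCall", cellIds = character(),
                 perLevel = matrix(logical(), nrow = 0, ncol = 1,
                                   dimnames = list(NULL, "level1")),
                 final = character())
    p <- file.path(withr::local_tempdir(), "empty.tsv")
    writePurityCalls(calls, p)
    expect_identical(readLines(p), "cell_id\tlevel1\tfinal")
})

test_that("cell-label TSV round-trips and unwritable paths error", {
    lab <- CellLabels(c("c1", "c2"), c("B", "T"))
    p <- file.path(withr::local_tempdir(), "lab.tsv")
    writeCellLabels(lab, p)
    back <- readCellLabels(p)
    expect_identical(cellLabels(back), cellLabels(lab))
    blocker <- file.path(withr::local_tempdir(), "afile")
    writeLines("x", blocker)
    expect_error(suppressWarnings(
        writeCellLabels(lab, file.path(blocker, "lab.tsv"))))
})
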