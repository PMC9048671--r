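## ---------------------------------------------------------------------------
## Readers/writers for the on-disk formats the tool touches:
## 10x-style MatrixMarket triplet directories, dense CSV/TSV, label TSVs.
## All writers are atomic (temp file + rename) and all round-trips are
## lossless for values representable in the format.
## ---------------------------------------------------------------------------

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

## open a (possibly gzipped, sniffed by extension) text connection
.openText <- function(path) {
    if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

## locate one of several candidate basenames (plain or .gz) in a directory
.findFile <- function(dir, candidates) {
    for (base in candidates)
        for (f in c(base, paste0(base, ".gz"))) {
            p <- file.path(dir, f)
            if (file.exists(p)) return(p)
        }
    .stopf("file not found in '%s': expected one of %s", dir,
           paste(candidates, collapse = ", "))
}

.readIdColumn <- function(path) {
    con <- .openText(path)
    on.exit(close(con))
    tab <- utils::read.table(con, sep = "\t", header = FALSE, quote = "",
                             comment.char = "", colClasses = "character")
    trimws(tab[[1L]])
}

## atomic write: run `writer(tmp)` then rename into place
.atomicWrite <- function(path, writer) {
    dir <- dirname(path)
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    tmp <- tempfile(pattern = ".mgtmp", tmpdir = dir)
    ok <- FALSE
    on.exit(if (!ok && file.exists(tmp)) unlink(tmp))
    writer(tmp)
    if (!file.rename(tmp, path))
        .stopf("cannot write to '%s'", path)
    ok <- TRUE
    invisible(path)
}

#' Read a 10x-style MatrixMarket directory
#'
#' Expects a directory holding a coordinate MatrixMarket file
#' (`matrix.mtx`), feature ids (`features.tsv` or `genes.tsv`, first
#' column used) and cell barcodes (`barcodes.tsv`), each optionally
#' gzipped. The on-disk matrix is features x cells (10x convention) and
#' is transposed to the canonical cells x features layout.
#'
#' @param path directory containing the triplet files.
#' @param modality modality tag for the returned matrix.
#' @return a \linkS4class{FeatureMatrix}.
#' @seealso [writeMtxDir()]
#' @export
readMtxDir <- function(path, modality = "rna") {
    if (!dir.exists(path)) .stopf("directory not found: '%s'", path)
    mtxPath <- .findFile(path, "matrix.mtx")
    featPath <- .findFile(path, c("features.tsv", "genes.tsv"))
    bcPath <- .findFile(path, "barcodes.tsv")
    con <- .openText(mtxPath)
    on.exit(close(con))
    m <- Matrix::readMM(con)
    feats <- .readIdColumn(featPath)
    cells <- .readIdColumn(bcPath)
    if (nrow(m) != length(feats))
        .stopf("matrix header says %d features but '%s' lists %d",
               nrow(m), basename(featPath), length(feats))
    if (ncol(m) != length(cells))
        .stopf("matrix header says %d cells but '%s' lists %d",
               ncol(m), basename(bcPath), length(cells))
    v <- .asDgc(Matrix::t(m))
    rownames(v) <- cells
    colnames(v) <- feats
    new("FeatureMatrix", values = v, modality = modality)
}

#' Write a FeatureMatrix as a 10x-style MatrixMarket directory
#'
#' Writes `matrix.mtx` (features x cells, transposed back to the 10x
#' convention), `features.tsv` and `barcodes.tsv` into `path`.
#'
#' @param x a \linkS4class{FeatureMatrix}.
#' @param path output directory (created if missing).
#' @return `path`, invisibly.
#' @export
writeMtxDir <- function(x, path) {
    stopifnot(is(x, "FeatureMatrix"))
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    .atomicWrite(file.path(path, "matrix.mtx"), function(tmp)
        Matrix::writeMM(Matrix::t(x@values), tmp))
    .atomicWrite(file.path(path, "features.tsv"), function(tmp)
        writeLines(featureIds(x), tmp))
    .atomicWrite(file.path(path, "barcodes.tsv"), function(tmp)
        writeLines(cellIds(x), tmp))
    invisible(path)
}

#' Read a dense delimited matrix
#'
#' Reads a CSV (`.csv`) or TSV (anything else) with a header row and one
#' leading id column. `orientation` declares what the file's rows are;
#' the result is always cells x features.
#'
#' @param path file path (optionally gzipped).
#' @param orientation `"features"` if file rows are features (so columns
#'   are cells), `"cells"` if file rows are cells.
#' @param modality modality tag.
#' @return a \linkS4class{FeatureMatrix}.
#' @export
readDenseMatrix <- function(path, orientation = c("features", "cells"),
                            modality = "rna") {
    orientation <- match.arg(orientation)
    if (!file.exists(path)) .stopf("file not found: '%s'", path)
    sep <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
    con <- .openText(path)
    on.exit(close(con))
    tab <- utils::read.table(con, sep = sep, header = TRUE, quote = "",
                             comment.char = "", check.names = FALSE,
                             colClasses = "character")
    ids <- trimws(tab[[1L]])
    body <- tab[, -1L, drop = FALSE]
    if (anyDuplicated(ids))
        .stopf("duplicated row ids in '%s' (e.g. '%s')", path,
               ids[anyDuplicated(ids)])
    if (anyDuplicated(colnames(body)))
        .stopf("duplicated column ids in '%s'", path)
    num <- suppressWarnings(
        vapply(body, function(col) as.numeric(col), numeric(nrow(tab))))
    if (nrow(tab) == 1L) num <- matrix(num, nrow = 1L)
    bad <- which(is.na(num) & !is.na(as.matrix(body)), arr.ind = TRUE)
    if (nrow(bad))
        .stopf("non-numeric value at data row %d, column %d of '%s'",
               bad[1L, 1L], bad[1L, 2L], path)
    dimnames(num) <- list(ids, colnames(body))
    if (orientation == "features") num <- t(num)
    FeatureMatrix(num, modality = modality)
}

#' Write a FeatureMatrix as a dense delimited table
#'
#' @param x a \linkS4class{FeatureMatrix}.
#' @param path output path; `.csv` selects comma separation, anything
#'   else tab.
#' @param orientation layout of the written file (see [readDenseMatrix()]).
#' @return `path`, invisibly.
#' @export
writeDenseMatrix <- function(x, path, orientation = c("features", "cells")) {
    orientation <- match.arg(orientation)
    stopifnot(is(x, "FeatureMatrix"))
    sep <- if (grepl("\\.csv$", path)) "," else "\t"
    m <- as.matrix(x@values)
    idName <- "cell_id"
    if (orientation == "features") {
        m <- t(m)
        idName <- "feature_id"
    }
    df <- data.frame(id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    colnames(df)[1L] <- idName
    .atomicWrite(path, function(tmp)
        utils::write.table(df, tmp, sep = sep, quote = FALSE,
                           row.names = FALSE))
}

#' Read / write per-cell ground-truth labels
#'
#' Two-column TSV with header `cell_id<TAB>label`.
#'
#' @param path file path.
#' @return [readCellLabels()] returns a \linkS4class{CellLabels}.
#' @export
readCellLabels <- function(path) {
    if (!file.exists(path)) .stopf("file not found: '%s'", path)
    con <- .openText(path)
    on.exit(close(con))
    tab <- utils::read.table(con, sep = "\t", header = TRUE, quote = "",
                             comment.char = "", colClasses = "character")
    if (ncol(tab) < 2L) .stopf("'%s' must have at least two columns", path)
    CellLabels(trimws(tab[[1L]]), trimws(tab[[2L]]))
}

#' @rdname readCellLabels
#' @param x a \linkS4class{CellLabels}.
#' @export
writeCellLabels <- function(x, path) {
    stopifnot(is(x, "CellLabels"))
    df <- data.frame(cell_id = x@cellIds, label = x@labels)
    .atomicWrite(path, function(tmp)
        utils::write.table(df, tmp, sep = "\t", quote = FALSE,
                           row.names = FALSE))
}

#' Write gating calls as TSV
#'
#' One row per cell in input order: `cell_id`, one `levelN` column of
#' TRUE/FALSE flags per gating level, and the `final` label
#' (`"Pure"`/`"Impure"`). With zero cells a header-only file is written.
#'
#' @param calls a \linkS4class{PurityCall}.
#' @param path output path.
#' @return `path`, invisibly.
#' @seealso [readPurityCalls()]
#' @export
writePurityCalls <- function(calls, path) {
    stopifnot(is(calls, "PurityCall"))
    pl <- calls@perLevel
    df <- data.frame(cell_id = calls@cellIds, pl, final = calls@final,
                     check.names = FALSE, stringsAsFactors = FALSE)
    .atomicWrite(path, function(tmp)
        utils::write.table(df, tmp, sep = "\t", quote = FALSE,
                           row.names = FALSE))
}

#' @rdname writePurityCalls
#' @export
readPurityCalls <- function(path) {
    if (!file.exists(path)) .stopf("file not found: '%s'", path)
    tab <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                             comment.char = "", colClasses = "character")
    lvlCols <- grep("^level[0-9]+$", colnames(tab), value = TRUE)
    if (!length(lvlCols)) .stopf("'%s' has no level columns", path)
    pl <- vapply(tab[lvlCols], function(col) col == "TRUE",
                 logical(nrow(tab)))
    if (nrow(tab) == 1L) pl <- matrix(pl, nrow = 1L, dimnames = list(NULL, lvlCols))
    if (nrow(tab) == 0L) pl <- matrix(logical(0), nrow = 0L, ncol = length(lvlCols),
                                      dimnames = list(NULL, lvlCols))
    rownames(pl) <- tab[["cell_id"]]
    new("PurityCall", cellIds = tab[["cell_id"]], perLevel = pl,
        final = tab[["final"]])
}
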