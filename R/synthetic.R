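## ---------------------------------------------------------------------------
## Seeded generator of marker-structured cell populations.
##
## Counts follow a zero-inflated negative binomial: gene g in population
## p has NB mean baselineMean (times markerFold if g is one of p's
## marker genes) with NB size `dispersion`, and each count is zeroed
## with probability dropoutExtra on top of the NB zeros. Populations are
## therefore discrete clusters whose marker genes are elevated over a
## sparse background -- the structure the gating pipeline presupposes --
## without any gene-gene correlation beyond population membership.
## ---------------------------------------------------------------------------

#' Describe one synthetic cell population
#'
#' @param name population (truth label) name.
#' @param nCells number of cells.
#' @param markerGenes feature ids elevated in this population. Besides
#'   the canonical marker symbols a population typically carries a
#'   private "program" of additional genes (see [presetDataset()]):
#'   real cell types differ in whole transcriptional programs, and the
#'   PCA/kNN stage needs that correlated structure to recover
#'   neighbourhoods.
#' @param markerFold NB-mean multiplier for marker genes (> 1).
#' @param baselineMean NB mean of every non-marker gene.
#' @param dispersion NB size parameter (smaller = more overdispersed).
#' @param dropoutExtra extra zero-inflation probability in [0, 1).
#' @return a \linkS4class{PopulationSpec}.
#' @export
populationSpec <- function(name, nCells, markerGenes, markerFold = 8,
                           baselineMean = 0.3, dispersion = 1.5,
                           dropoutExtra = 0.3) {
    p <- new("PopulationSpec", name = as.character(name),
             nCells = as.integer(nCells),
             markerGenes = as.character(markerGenes),
             markerFold = as.numeric(markerFold),
             baselineMean = as.numeric(baselineMean),
             dispersion = as.numeric(dispersion),
             dropoutExtra = as.numeric(dropoutExtra))
    validObject(p)
    p
}

#' @rdname SyntheticDataset-class
#' @param x a \linkS4class{SyntheticDataset}.
#' @export
dataMatrix <- function(x) {
    stopifnot(is(x, "SyntheticDataset"))
    x@matrix
}

#' @rdname SyntheticDataset-class
#' @export
truthLabels <- function(x) {
    stopifnot(is(x, "SyntheticDataset"))
    x@truth
}

#' @rdname SyntheticDataset-class
#' @export
specEcho <- function(x) {
    stopifnot(is(x, "SyntheticDataset"))
    x@specEcho
}

setMethod("show", "SyntheticDataset", function(object) {
    tab <- table(object@truth@labels)
    cat(sprintf("SyntheticDataset: %d cells x %d features, seed %s\n",
                nCells(object@matrix), nFeatures(object@matrix),
                format(object@specEcho$seed)))
    cat(sprintf("  populations: %s\n",
                paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
})

#' Generate a synthetic dataset from population specs
#'
#' Deterministic given `seed`. The feature universe consists of every
#' marker gene named by the specs followed by filler features
#' (`FT00001`, ...) up to `nFeatures`. Cells are generated population by
#' population, then shuffled; the truth labels follow the shuffle.
#'
#' @param specs non-empty list of \linkS4class{PopulationSpec}.
#' @param nFeatures size of the feature universe (must cover all
#'   markers).
#' @param seed integer seed.
#' @param modality modality tag for the generated matrix.
#' @return a \linkS4class{SyntheticDataset}.
#' @export
generateDataset <- function(specs, nFeatures, seed, modality = "rna") {
    if (is(specs, "PopulationSpec")) specs <- list(specs)
    stopifnot(length(specs) >= 1L,
              all(vapply(specs, is, logical(1), class2 = "PopulationSpec")))
    for (s in specs) validObject(s)
    markers <- unique(unlist(lapply(specs, function(s) s@markerGenes)))
    if (length(markers) > nFeatures)
        .stopf("%d marker genes exceed the feature universe of %d",
               length(markers), nFeatures)
    featIds <- c(markers,
                 sprintf("FT%05d", seq_len(nFeatures - length(markers))))
    popNames <- vapply(specs, function(s) s@name, character(1))
    if (anyDuplicated(popNames)) .stopf("duplicated population names")

    old <- .saveSeed()
    on.exit(.restoreSeed(old))
    set.seed(as.integer(seed) %% .Machine$integer.max)

    blocks <- lapply(specs, function(s) {
        mu <- rep(s@baselineMean, nFeatures)
        mu[match(s@markerGenes, featIds)] <- s@baselineMean * s@markerFold
        cnt <- matrix(stats::rnbinom(s@nCells * nFeatures,
                                     size = s@dispersion,
                                     mu = rep(mu, each = s@nCells)),
                      nrow = s@nCells)
        if (s@dropoutExtra > 0)
            cnt[stats::runif(length(cnt)) < s@dropoutExtra] <- 0L
        cnt
    })
    m <- do.call(rbind, blocks)
    labels <- rep(popNames, vapply(specs, function(s) s@nCells, integer(1)))
    perm <- sample.int(nrow(m))
    m <- m[perm, , drop = FALSE]
    labels <- labels[perm]
    rownames(m) <- sprintf("CELL%05d", seq_len(nrow(m)))
    colnames(m) <- featIds

    new("SyntheticDataset",
        matrix = FeatureMatrix(m, modality = modality),
        truth = CellLabels(rownames(m), labels),
        specEcho = list(specs = specs, nFeatures = as.integer(nFeatures),
                        seed = as.integer(seed)))
}

## a population's private transcriptional program
.programGenes <- function(pop, n = 40L) sprintf("%s.PRG%02d", pop, seq_len(n))

#' Preset synthetic datasets mirroring common purification scenarios
#'
#' Four ready-made scenarios, all 2000 features, 500 cells per
#' population by default, marker fold 8, baseline mean 0.3, dispersion
#' 1.5, extra dropout 0.3. Canonical marker genes carry their real
#' symbols so literal gating models run unchanged on the fixtures; each
#' population additionally elevates a 40-gene private program.
#'
#' \describe{
#'   \item{pbmc-like}{B (MS4A1), NK (NCAM1, KLRD1), T (CD3D), Mono
#'     (LYZ, CD14): a blood-like mixture for single-marker and
#'     negative-marker purification.}
#'   \item{tumor-like}{malignant (MLANA, PMEL; no PTPRC), T (CD3D,
#'     PTPRC), macrophage (CD68, FCGR1A, PTPRC): the two-level
#'     immune-then-macrophage hierarchy.}
#'   \item{nk-vs-t}{NK (NCAM1, KLRD1) against T cells that co-express
#'     KLRD1 (as effector/NKT-like T cells do) plus CD3D -- the case
#'     where the CD3D- veto is required for precision.}
#'   \item{airway-like}{basal (KRT5) and secretory (SCGB1A1) majorities
#'     with a rare FOXI1+/CFTR+ ionocyte population (40 cells).}
#' }
#'
#' @param name preset name.
#' @param seed integer seed.
#' @param nCellsPerPop cells per population (the airway-like ionocyte
#'   population is fixed at 40 rare cells).
#' @param nFeatures feature-universe size.
#' @return a \linkS4class{SyntheticDataset}.
#' @export
presetDataset <- function(name = c("pbmc-like", "tumor-like", "nk-vs-t",
                                   "airway-like"),
                          seed, nCellsPerPop = 500, nFeatures = 2000) {
    if (length(name) != 1L || !name %in% c("pbmc-like", "tumor-like",
                                           "nk-vs-t", "airway-like"))
        .stopf("unknown preset '%s'", paste(name, collapse = ","))
    n <- nCellsPerPop
    specs <- switch(name,
        "pbmc-like" = list(
            populationSpec("B", n, c("MS4A1", .programGenes("B"))),
            populationSpec("NK", n, c("NCAM1", "KLRD1", .programGenes("NK"))),
            populationSpec("T", n, c("CD3D", .programGenes("T"))),
            populationSpec("Mono", n, c("LYZ", "CD14", .programGenes("MONO")))),
        "tumor-like" = list(
            populationSpec("malignant", n,
                           c("MLANA", "PMEL", .programGenes("MAL"))),
            populationSpec("T", n, c("CD3D", "PTPRC", .programGenes("T"))),
            populationSpec("macrophage", n,
                           c("CD68", "FCGR1A", "PTPRC", .programGenes("MAC")))),
        "nk-vs-t" = list(
            populationSpec("NK", n, c("NCAM1", "KLRD1", .programGenes("NK"))),
            populationSpec("T", n, c("CD3D", "KLRD1", .programGenes("T")))),
        "airway-like" = list(
            populationSpec("basal", n, c("KRT5", .programGenes("BAS"))),
            populationSpec("secretory", n,
                           c("SCGB1A1", .programGenes("SEC"))),
            populationSpec("ionocyte", 40L,
                           c("FOXI1", "CFTR", .programGenes("ION")))))
    generateDataset(specs, nFeatures = nFeatures, seed = seed)
}

#' Write a synthetic dataset as an on-disk fixture
#'
#' Writes the matrix in the 10x-style MatrixMarket layout (see
#' [writeMtxDir()]) plus the truth labels as `truth.tsv`, so the CLI
#' consumes the fixture exactly like real data.
#'
#' @param x a \linkS4class{SyntheticDataset}.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
writeDataset <- function(x, dir) {
    stopifnot(is(x, "SyntheticDataset"))
    writeMtxDir(x@matrix, dir)
    writeCellLabels(x@truth, file.path(dir, "truth.tsv"))
    invisible(dir)
}
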