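# Small in-code fixtures shared across test files.

# dense cells x features matrix with ids
namedMatrix <- function(m, cellPrefix = "c", featPrefix = "g") {
    dimnames(m) <- list(sprintf("%s%02d", cellPrefix, seq_len(nrow(m))),
                        sprintf("%s%02d", featPrefix, seq_len(ncol(m))))
    m
}

randomFeatureMatrix <- function(nCells, nFeatures, seed,
                                rfun = function(n) runif(n, 0, 10)) {
    set.seed(seed)
    FeatureMatrix(namedMatrix(matrix(rfun(nCells * nFeatures),
                                     nrow = nCells)))
}

# write a gating table from raw lines, return its path
writeModelFile <- function(lines, dir = NULL) {
    path <- if (is.null(dir)) tempfile("model", fileext = ".tsv")
            else file.path(dir, "model.tsv")
    writeLines(lines, path)
    path
}

# the two-level immune -> macrophage gating table
macrophageModelLines <- c(
    "levels\tuse_as\tname\tsignature",
    "level1\tpositive\timmune\tPTPRC",
    "level2\tpositive\tmacrophage\tCD68;FCGR1A")

# small, quick synthetic mixture for engine/CLI tests
smallMixture <- function(seed = 7, nCells = 80, nFeatures = 400) {
    specs <- list(
        populationSpec("B", nCells, c("MS4A1", sprintf("B.PRG%02d", 1:15))),
        populationSpec("T", nCells, c("CD3D", sprintf("T.PRG%02d", 1:15))))
    generateDataset(specs, nFeatures = nFeatures, seed = seed)
}

# smoothing config proportionate to the small mixture
smallSmooth <- function(k = 10) smoothParams(k = k, nHVG = 200, nPCs = 10)
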