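## ---------------------------------------------------------------------------
## Gating-model construction, TSV parsing/serialization, local model DB.
##
## On-disk dialect (tab-separated, header required):
##   levels   use_as    name       signature
##   level1   positive  immune     PTPRC
##   level2   positive  macrophage CD68;FCGR1A
## Gene tokens are ';'-separated; a trailing '-' negates a gene
## (e.g. "CD3D-"). use_as=negative declares a whole veto signature.
## ---------------------------------------------------------------------------

.parseTokens <- function(tokens, signatureName) {
    tokens <- trimws(tokens)
    tokens <- tokens[nzchar(tokens)]
    if (!length(tokens))
        .stopf("signature '%s' has no genes", signatureName)
    neg <- grepl("-$", tokens)
    genes <- ifelse(neg, trimws(sub("-$", "", tokens)), tokens)
    if (any(!nzchar(genes)))
        .stopf("signature '%s' contains an empty gene symbol", signatureName)
    new("Signature", name = signatureName, genes = genes,
        signs = ifelse(neg, -1L, 1L))
}

#' Build a marker signature from signed gene tokens
#'
#' @param name signature name.
#' @param genes character vector of gene tokens; a trailing `"-"` marks a
#'   negated gene (`"CD3D-"`).
#' @return a \linkS4class{Signature}.
#' @examples
#' markerSignature("NK", c("NCAM1", "KLRD1", "CD3D-"))
#' @export
markerSignature <- function(name, genes) {
    sig <- .parseTokens(as.character(genes), name)
    validObject(sig)
    sig
}

#' One-line construction of a single-level gating model
#'
#' Convenience builder mirroring the typical interactive use: one
#' positive signature, one level.
#'
#' @param name model (and signature) name.
#' @param signature gene tokens, trailing `"-"` negates
#'   (e.g. `c("NCAM1", "KLRD1", "CD3D-")`).
#' @return a \linkS4class{GatingModel} with one level.
#' @examples
#' gatingModel(name = "NK", signature = c("NCAM1", "KLRD1", "CD3D-"))
#' @export
gatingModel <- function(name, signature) {
    if (!length(signature)) .stopf("empty signature for model '%s'", name)
    sig <- markerSignature(name, signature)
    mdl <- new("GatingModel", name = name,
               levels = list(new("GatingLevel", positive = list(sig),
                                 negative = list())))
    validObject(mdl, complete = TRUE)
    mdl
}

#' @rdname GatingModel-class
setMethod("modelName", "GatingModel", function(x) x@name)

#' @rdname GatingModel-class
setMethod("modelLevels", "GatingModel", function(x) x@levels)

#' @rdname GatingModel-class
#' @return `modelSignatures()` returns a named list of every
#'   \linkS4class{Signature} in the model (all levels, positive and
#'   negative).
setMethod("modelSignatures", "GatingModel", function(x) {
    sigs <- unlist(lapply(x@levels, function(l) c(l@positive, l@negative)),
                   recursive = FALSE)
    names(sigs) <- vapply(sigs, function(s) s@name, character(1))
    sigs
})

.formatSignature <- function(sig) {
    paste0(sig@genes, ifelse(sig@signs < 0L, "-", ""), collapse = ";")
}

setMethod("show", "Signature", function(object) {
    cat(sprintf("Signature '%s': %s\n", object@name,
                gsub(";", "; ", .formatSignature(object))))
})

setMethod("show", "GatingModel", function(object) {
    cat(sprintf("GatingModel '%s' with %d level(s)\n", object@name,
                length(object@levels)))
    for (i in seq_along(object@levels)) {
        lvl <- object@levels[[i]]
        for (s in lvl@positive)
            cat(sprintf("  level%d  positive  %-12s %s\n", i, s@name,
                        .formatSignature(s)))
        for (s in lvl@negative)
            cat(sprintf("  level%d  negative  %-12s %s\n", i, s@name,
                        .formatSignature(s)))
    }
})

#' Parse a gating model from its tab-separated text form
#'
#' Required columns: `levels` (values `level1`, `level2`, ...),
#' `use_as` (`positive` or `negative`), `name` (signature name, unique
#' within the model) and `signature` (`;`-separated gene tokens, trailing
#' `"-"` negates a gene). Extra columns are ignored with a warning.
#' Level numbering must be consecutive from 1; every level needs at
#' least one positive signature; parsing is insensitive to row order
#' within a level and to surrounding whitespace.
#'
#' @param path TSV file path.
#' @param name model name; defaults to the file name without extension.
#' @return a \linkS4class{GatingModel}.
#' @seealso [serializeGatingTable()], [loadModelDB()]
#' @export
parseGatingTable <- function(path, name = sub("\\.[^.]*$", "", basename(path))) {
    if (!file.exists(path)) .stopf("file not found: '%s'", path)
    con <- .openText(path)
    on.exit(close(con))
    tab <- utils::read.table(con, sep = "\t", header = TRUE, quote = "",
                             comment.char = "", colClasses = "character",
                             check.names = FALSE)
    required <- c("levels", "use_as", "name", "signature")
    miss <- setdiff(required, colnames(tab))
    if (length(miss))
        .stopf("gating table '%s' lacks column(s): %s", path,
               paste(miss, collapse = ", "))
    extra <- setdiff(colnames(tab), required)
    if (length(extra))
        warning(sprintf("ignoring extra column(s) in '%s': %s", path,
                        paste(extra, collapse = ", ")), call. = FALSE)
    for (col in required) tab[[col]] <- trimws(tab[[col]])
    if (!nrow(tab)) .stopf("gating table '%s' has no rows", path)

    lvlMatch <- regmatches(tab$levels, regexec("^level([0-9]+)$", tab$levels))
    bad <- vapply(lvlMatch, length, integer(1)) != 2L
    if (any(bad))
        .stopf("bad levels value '%s' (expected 'level<N>')",
               tab$levels[bad][1L])
    lvlNum <- vapply(lvlMatch, function(m) as.integer(m[2L]), integer(1))
    if (any(!tab$use_as %in% c("positive", "negative")))
        .stopf("unknown use_as value '%s' (expected 'positive' or 'negative')",
               setdiff(tab$use_as, c("positive", "negative"))[1L])
    if (anyDuplicated(tab$name))
        .stopf("duplicated signature name '%s'", tab$name[anyDuplicated(tab$name)])

    seen <- sort(unique(lvlNum))
    if (!identical(seen, seq_along(seen)))
        .stopf("gap in level numbering: found levels %s",
               paste(seen, collapse = ", "))

    levels <- lapply(seq_along(seen), function(k) {
        rows <- which(lvlNum == k)
        rows <- rows[order(tab$use_as[rows] != "positive", rows)]
        pos <- list(); negl <- list()
        for (r in rows) {
            sig <- .parseTokens(strsplit(tab$signature[r], ";", fixed = TRUE)[[1L]],
                                tab$name[r])
            validObject(sig)
            if (tab$use_as[r] == "positive") pos[[length(pos) + 1L]] <- sig
            else negl[[length(negl) + 1L]] <- sig
        }
        if (!length(pos))
            .stopf("level %d of '%s' has no positive signature", k, name)
        new("GatingLevel", positive = pos, negative = negl)
    })
    mdl <- new("GatingModel", name = name, levels = levels)
    validObject(mdl, complete = TRUE)
    mdl
}

#' Serialize a gating model to canonical tab-separated form
#'
#' Canonical form orders rows by level, positive signatures before
#' negative ones, and alphabetically by signature name within each
#' block, so serialization is insensitive to input row order and one
#' canonicalization pass makes parse/serialize idempotent.
#'
#' @param model a \linkS4class{GatingModel}.
#' @param path optional output path; if `NULL` the canonical
#'   `data.frame` is returned instead of written.
#' @return the canonical table (invisibly when written to `path`).
#' @export
serializeGatingTable <- function(model, path = NULL) {
    stopifnot(is(model, "GatingModel"))
    block <- function(sigs, i, role) {
        if (!length(sigs)) return(NULL)
        df <- do.call(rbind, lapply(sigs, function(s)
            data.frame(levels = paste0("level", i), use_as = role,
                       name = s@name, signature = .formatSignature(s))))
        df[order(df$name), , drop = FALSE]
    }
    rows <- do.call(rbind, lapply(seq_along(model@levels), function(i) {
        lvl <- model@levels[[i]]
        rbind(block(lvl@positive, i, "positive"),
              block(lvl@negative, i, "negative"))
    }))
    rownames(rows) <- NULL
    if (is.null(path)) return(rows)
    .atomicWrite(path, function(tmp)
        utils::write.table(rows, tmp, sep = "\t", quote = FALSE,
                           row.names = FALSE))
    invisible(rows)
}

#' Load a directory of gating models
#'
#' Every `*.tsv` file in `dir` is parsed with [parseGatingTable()]; the
#' file name without extension becomes the model name. An unparseable
#' file aborts the load with an error naming the file -- models are never
#' silently skipped.
#'
#' @param dir directory of gating tables.
#' @return named list of \linkS4class{GatingModel}, sorted by name.
#' @export
loadModelDB <- function(dir) {
    if (!dir.exists(dir)) .stopf("directory not found: '%s'", dir)
    files <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
    models <- lapply(files, function(f)
        tryCatch(parseGatingTable(f),
                 error = function(e) .stopf(
                     "failed to parse gating model file '%s': %s",
                     basename(f), conditionMessage(e))))
    names(models) <- vapply(models, modelName, character(1))
    models
}

#' Check a gating model against the features of a matrix
#'
#' Reports model genes absent from the feature universe. A missing
#' negated gene merely weakens a signature; a signature that loses
#' \emph{all} its positive genes can no longer be scored and renders the
#' model unusable. Matching is exact and case sensitive after whitespace
#' stripping; set `ignoreCase = TRUE` for a case-insensitive fallback.
#'
#' @param model a \linkS4class{GatingModel}.
#' @param features character vector of available feature ids.
#' @param ignoreCase case-insensitive matching fallback (off by default;
#'   silent case folding can conflate gene symbols).
#' @return list with `missing` (data.frame: signature, gene, sign),
#'   `unusable` (names of signatures with no positive gene left) and
#'   `usable` (TRUE iff `unusable` is empty).
#' @export
validateModelFeatures <- function(model, features, ignoreCase = FALSE) {
    stopifnot(is(model, "GatingModel"))
    features <- trimws(features)
    match1 <- function(g) {
        if (g %in% features) return(TRUE)
        if (ignoreCase && tolower(g) %in% tolower(features)) return(TRUE)
        FALSE
    }
    missing <- data.frame(signature = character(), gene = character(),
                          sign = integer())
    unusable <- character()
    for (sig in modelSignatures(model)) {
        present <- vapply(sig@genes, match1, logical(1))
        if (any(!present))
            missing <- rbind(missing, data.frame(
                signature = sig@name, gene = sig@genes[!present],
                sign = sig@signs[!present]))
        if (!any(present & sig@signs == 1L))
            unusable <- c(unusable, sig@name)
    }
    rownames(missing) <- NULL
    list(missing = missing, unusable = unusable,
         usable = length(unusable) == 0L)
}
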