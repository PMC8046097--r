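#' Read tab-separated intensity, sample and pathway files
#'
#' `readIntensityTable()` reads the `intensities.tsv` dialect (first column
#' `id`, one column per sample, empty fields = missing) together with optional
#' sample metadata and metabolite annotation tables, and returns a raw-stage
#' [MetaboSet].  Schemas are validated strictly: duplicated metabolite or
#' sample ids, non-numeric cells and sample tables that do not cover the
#' intensity columns are rejected with messages naming the offender.
#'
#' @param path intensity table path.
#' @param samplePath optional `samples.tsv` path (first column `sample`).
#' @param annotationPath optional `annotations.tsv` path (column `id`).
#' @return a raw-stage [MetaboSet].
#' @export
readIntensityTable <- function(path, samplePath = NULL,
                               annotationPath = NULL) {
    .stopIfNot(file.exists(path), "file not found: %s", path)
    df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                     na.strings = c("", "NA"))
    .stopIfNot(ncol(df) >= 2L, "%s: need an id column plus sample columns",
               path)
    ids <- as.character(df[[1L]])
    dup <- ids[duplicated(ids)]
    .stopIfNot(length(dup) == 0L, "%s: duplicated metabolite id(s): %s", path,
               paste(unique(dup), collapse = ", "))
    sdup <- colnames(df)[-1L][duplicated(colnames(df)[-1L])]
    .stopIfNot(length(sdup) == 0L, "%s: duplicated sample column(s): %s",
               path, paste(unique(sdup), collapse = ", "))
    m <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(m)) {
        num <- suppressWarnings(matrix(as.numeric(m), nrow(m), ncol(m),
                                       dimnames = dimnames(m)))
        bad <- colnames(m)[colSums(is.na(num) & !is.na(m)) > 0]
        .stopIfNot(length(bad) == 0L, "%s: non-numeric values in column(s): %s",
                   path, paste(bad, collapse = ", "))
        m <- num
    }
    rownames(m) <- ids
    cd <- if (is.null(samplePath)) {
        data.frame(row.names = colnames(m))
    } else {
        readSampleTable(samplePath, expected = colnames(m))
    }
    rd <- NULL
    if (!is.null(annotationPath)) {
        rd <- read.delim(annotationPath, stringsAsFactors = FALSE)
        .stopIfNot("id" %in% colnames(rd), "%s: annotation needs an 'id' column",
                   annotationPath)
        .stopIfNot(!anyDuplicated(rd$id), "%s: duplicated annotation id",
                   annotationPath)
        rownames(rd) <- rd$id
        rd <- rd[ids, , drop = FALSE]
    }
    MetaboSet(m, cd, rowData = rd)
}

#' @rdname readIntensityTable
#' @param expected optional sample ids the table must cover, in order.
#' @export
readSampleTable <- function(path, expected = NULL) {
    .stopIfNot(file.exists(path), "file not found: %s", path)
    cd <- read.delim(path, stringsAsFactors = FALSE)
    .stopIfNot("sample" %in% colnames(cd),
               "%s: sample table needs a 'sample' column", path)
    dup <- cd$sample[duplicated(cd$sample)]
    .stopIfNot(length(dup) == 0L, "%s: duplicated sample id(s): %s", path,
               paste(unique(dup), collapse = ", "))
    rownames(cd) <- cd$sample
    if (!is.null(expected)) {
        missing <- setdiff(expected, cd$sample)
        .stopIfNot(length(missing) == 0L,
                   "%s: sample table lacks row(s) for: %s", path,
                   paste(missing, collapse = ", "))
        cd <- cd[expected, , drop = FALSE]
    }
    cd[, setdiff(colnames(cd), "sample"), drop = FALSE]
}

#' Read GMT-style pathway definitions and optional pathway edge lists
#'
#' The GMT dialect is one pathway per line:
#' `pathway_id TAB description TAB member TAB member ...`.
#' `readPathwayEdges()` reads a two-column tab-separated edge list
#' (`from`, `to`) describing the reaction graph of one pathway, for use with
#' [pathwayImpact()].
#'
#' @param path file path.
#' @return `readPathwayGMT()`: a named list of pathways, each a list with
#'   `name` and unique `members`.  `readPathwayEdges()`: a two-column
#'   character `data.frame`.
#' @export
readPathwayGMT <- function(path) {
    .stopIfNot(file.exists(path), "file not found: %s", path)
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    out <- list()
    for (i in seq_along(lines)) {
        f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
        .stopIfNot(length(f) >= 3L,
                   "%s line %d: need id, description and >=1 member", path, i)
        .stopIfNot(!f[1L] %in% names(out), "%s line %d: duplicated pathway id %s",
                   path, i, f[1L])
        out[[f[1L]]] <- list(name = f[2L], members = unique(f[-(1:2)]))
    }
    out
}

#' @rdname readPathwayGMT
#' @export
readPathwayEdges <- function(path) {
    .stopIfNot(file.exists(path), "file not found: %s", path)
    e <- read.delim(path, stringsAsFactors = FALSE)
    .stopIfNot(all(c("from", "to") %in% colnames(e)),
               "%s: edge list needs 'from' and 'to' columns", path)
    e[, c("from", "to")]
}

#' Write a differential-analysis table as TSV
#'
#' @param table a `data.frame`/`DataFrame` of per-metabolite results.
#' @param path output path.
#' @export
writeDifferentialTable <- function(table, path) {
    write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}
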