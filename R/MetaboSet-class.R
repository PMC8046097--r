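#' MetaboSet: a peak-intensity matrix with sample metadata and stage state
#'
#' `MetaboSet` extends [SummarizedExperiment::SummarizedExperiment] with a
#' processing-stage tag and a record of the original missingness pattern.
#' Rows are metabolites, columns are serum samples.  The `"intensity"` assay
#' holds non-negative peak intensities on the original (non-log) scale until
#' [logTransform()] is applied; missing cells are `NA` at the `"raw"` stage and
#' are filled in by [imputeCensored()].  The `"missing"` assay is a logical
#' matrix fixed at construction time: it records which cells were missing
#' before imputation, which is what the missingness filter must consult.
#'
#' The processing chain is a one-way state machine
#' `raw -> imputed -> filtered -> normalized -> log`; each stage function
#' checks the tag and refuses to run out of order.
#'
#' @param intensity numeric matrix, metabolites x samples, with `NA` for
#'   missing cells.  Must have unique row and column names.
#' @param sampleData a `data.frame` or `DataFrame` of per-sample metadata
#'   (e.g. `subject`, `arm`, `time` for the trial layout; `age`, `bmi`,
#'   `vbmd` for the cohort layout), one row per column of `intensity`.
#' @param rowData optional per-metabolite annotation (name, class, pathway).
#' @param stage processing stage tag; new objects are `"raw"`.
#' @param x a `MetaboSet`.
#'
#' @return `MetaboSet()` returns a `MetaboSet` object.  `intensities()`
#'   returns the intensity matrix, `missingMask()` the original missingness
#'   mask, and `procStage()` the stage tag.
#'
#' @examples
#' m <- matrix(c(100, 200, NA, 400), 2, 2,
#'             dimnames = list(c("M1", "M2"), c("S1", "S2")))
#' ms <- MetaboSet(m, data.frame(subject = c("A", "B"), row.names = c("S1", "S2")))
#' procStage(ms)
#' missingMask(ms)["M2", "S1"]
#'
#' @aliases intensities missingMask procStage
#' @export
MetaboSet <- function(intensity, sampleData, rowData = NULL, stage = "raw") {
    intensity <- as.matrix(intensity)
    storage.mode(intensity) <- "double"
    mask <- is.na(intensity)
    args <- list(
        assays = list(intensity = intensity, missing = mask),
        colData = S4Vectors::DataFrame(sampleData)
    )
    if (!is.null(rowData)) args$rowData <- S4Vectors::DataFrame(rowData)
    se <- do.call(SummarizedExperiment::SummarizedExperiment, args)
    new("MetaboSet", se, procStage = stage)
}

.STAGES <- c("raw", "imputed", "filtered", "normalized", "log")

#' @rdname MetaboSet-class
#' @export
setClass("MetaboSet",
    contains = "SummarizedExperiment",
    representation(procStage = "character"))

setValidity("MetaboSet", function(object) {
    msg <- character()
    if (length(object@procStage) != 1L || !object@procStage %in% .STAGES)
        msg <- c(msg, sprintf("procStage must be one of %s",
                              paste(.STAGES, collapse = ", ")))
    if (!all(c("intensity", "missing") %in%
             SummarizedExperiment::assayNames(object)))
        msg <- c(msg, "assays 'intensity' and 'missing' are required")
    else {
        v <- SummarizedExperiment::assay(object, "intensity")
        if (object@procStage != "log" && any(v[is.finite(v)] < 0))
            msg <- c(msg, "negative intensities are not allowed before log stage")
    }
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "metabolite ids (rownames) must be unique")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids (colnames) must be unique")
    if (length(msg)) msg else TRUE
})

#' @rdname MetaboSet-class
#' @export
setMethod("intensities", "MetaboSet", function(x)
    SummarizedExperiment::assay(x, "intensity"))

#' @rdname MetaboSet-class
#' @export
setMethod("missingMask", "MetaboSet", function(x)
    SummarizedExperiment::assay(x, "missing"))

#' @rdname MetaboSet-class
#' @export
setMethod("procStage", "MetaboSet", function(x) x@procStage)

setMethod("show", "MetaboSet", function(object) {
    cat(sprintf("MetaboSet: %d metabolites x %d samples [stage: %s]\n",
                nrow(object), ncol(object), object@procStage))
    cat(sprintf("  missing cells (original): %d (%.1f%%)\n",
                sum(missingMask(object)),
                100 * mean(missingMask(object))))
    callNextMethod()
})

## internal: advance the stage state machine, refusing out-of-order calls
.advanceStage <- function(x, from, to) {
    if (!identical(x@procStage, from))
        stop(sprintf("stage violation: expected a '%s' MetaboSet but got '%s' (chain is %s)",
                     from, x@procStage, paste(.STAGES, collapse = " -> ")),
             call. = FALSE)
    x@procStage <- to
    validObject(x)
    x
}

.setIntensity <- function(x, value) {
    SummarizedExperiment::assay(x, "intensity") <- value
    x
}
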