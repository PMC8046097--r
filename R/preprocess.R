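#' Impute left-censored missing intensities from a down-shifted normal
#'
#' Untargeted LC-MS missingness is concentrated at low abundance (detection
#' limit censoring), so missing cells are replaced by draws from a normal
#' distribution shifted below the observed values: within each scope unit the
#' mean `mu` and SD `sigma` of the observed log-scale intensities are taken
#' and missing cells receive
#' `exp(Normal(mu - shiftFactor * sigma, (widthFactor * sigma)^2))`.
#' The defaults (width 0.5 SD, down-shift 2.5 SD) are the standard
#' left-censored imputation used for this kind of data.  Draws falling below
#' the floor (`floorFraction` times the smallest observed positive intensity)
#' are clipped to it, preserving positivity.  Observed cells are never
#' altered.
#'
#' @param x a raw-stage [MetaboSet].
#' @param widthFactor SD multiplier for the imputation distribution width
#'   (default 0.5).
#' @param shiftFactor SD multiplier for the down-shift (default 2.5).
#' @param scope `"per_sample"` (default; mu/sigma per sample column),
#'   `"per_metabolite"` or `"global"`.
#' @param floorFraction clip floor as a fraction of the smallest observed
#'   positive intensity.
#' @param seed RNG seed; imputation is deterministic given the seed.
#' @return an imputed-stage `MetaboSet`; `missingMask()` still records which
#'   cells were imputed.
#' @examples
#' sim <- simulateRCT(simConfig(nMetabolites = 40, nSubjectsPerArm = 4))
#' imp <- imputeCensored(sim$mset, seed = 7)
#' procStage(imp)
#' @export
imputeCensored <- function(x, widthFactor = 0.5, shiftFactor = 2.5,
                           scope = c("per_sample", "per_metabolite", "global"),
                           floorFraction = 1e-3, seed = 1L) {
    scope <- match.arg(scope)
    .stopIfNot(widthFactor > 0, "widthFactor must be > 0")
    .stopIfNot(shiftFactor >= 0, "shiftFactor must be >= 0")
    x <- .advanceStage(x, "raw", "imputed")
    m <- intensities(x)
    mask <- is.na(m)
    if (!any(mask)) return(x)
    floor <- min(m[!mask & m > 0], na.rm = TRUE) * floorFraction
    set.seed(seed)
    drawUnit <- function(vals, nMiss, unit) {
        obs <- log(vals[!is.na(vals) & vals > 0])
        if (length(obs) < 2L)
            stop(sprintf("imputation scope unit '%s' has fewer than 2 observed values",
                         unit), call. = FALSE)
        exp(rnorm(nMiss, mean(obs) - shiftFactor * sd(obs),
                  widthFactor * sd(obs)))
    }
    if (scope == "global") {
        m[mask] <- drawUnit(as.vector(m), sum(mask), "global")
    } else if (scope == "per_sample") {
        for (j in seq_len(ncol(m))) {
            nj <- sum(mask[, j])
            if (nj > 0)
                m[mask[, j], j] <- drawUnit(m[, j], nj, colnames(m)[j])
        }
    } else {
        for (i in seq_len(nrow(m))) {
            ni <- sum(mask[i, ])
            if (ni > 0)
                m[i, mask[i, ]] <- drawUnit(m[i, ], ni, rownames(m)[i])
        }
    }
    m[m < floor] <- floor
    .setIntensity(x, m)
}

#' Filter metabolites by original missingness fraction
#'
#' Retains exactly the metabolites whose pre-imputation missing fraction
#' (from `missingMask()`) is strictly below `maxMissingFraction`; a
#' metabolite missing in exactly 25% of samples is dropped under the default.
#'
#' @param x an imputed-stage [MetaboSet].
#' @param maxMissingFraction strict upper bound, default 0.25.
#' @return a filtered-stage `MetaboSet`; retained/dropped counts are stored in
#'   `metadata(x)$filter` and reported via `message()`.
#' @export
filterMissing <- function(x, maxMissingFraction = 0.25) {
    .stopIfNot(maxMissingFraction >= 0 && maxMissingFraction <= 1,
               "maxMissingFraction must be in [0, 1]")
    x <- .advanceStage(x, "imputed", "filtered")
    frac <- rowMeans(missingMask(x))
    keep <- frac < maxMissingFraction
    if (!any(keep))
        stop(sprintf("no metabolite has missing fraction < %g; review the threshold",
                     maxMissingFraction), call. = FALSE)
    out <- x[keep, ]
    S4Vectors::metadata(out)$filter <- list(retained = sum(keep),
                                            dropped = sum(!keep),
                                            threshold = maxMissingFraction)
    message(sprintf("missingness filter: retained %d, dropped %d (threshold < %g)",
                    sum(keep), sum(!keep), maxMissingFraction))
    out
}

#' Normalize each sample to the minimum total intensity
#'
#' Assumes equal total intensity across serum samples (differences reflect
#' sample volume): the correction factor of sample `i` is its total intensity
#' divided by the smallest total across samples, and every cell of sample `i`
#' is divided by that factor.  After normalization all sample totals equal
#' the minimum original total, all factors are >= 1 with at least one exactly
#' 1, and within-sample intensity ratios are preserved exactly.
#'
#' @param x a filtered-stage [MetaboSet].
#' @return a normalized-stage `MetaboSet`; the per-sample correction factors
#'   are stored in `metadata(x)$correctionFactors`.
#' @export
normalizeTotal <- function(x) {
    x <- .advanceStage(x, "filtered", "normalized")
    m <- intensities(x)
    .stopIfNot(all(is.finite(m)), "normalization requires a complete matrix (impute first)")
    totals <- colSums(m)
    bad <- colnames(m)[totals <= 0]
    .stopIfNot(length(bad) == 0L, "non-positive total intensity in sample(s): %s",
               paste(bad, collapse = ", "))
    factors <- totals / min(totals)
    m <- sweep(m, 2L, factors, "/")
    x <- .setIntensity(x, m)
    S4Vectors::metadata(x)$correctionFactors <- setNames(factors, colnames(m))
    x
}

#' Natural-log transform a normalized intensity matrix
#'
#' @param x a normalized-stage [MetaboSet] with strictly positive values.
#' @return a log-stage `MetaboSet`.
#' @export
logTransform <- function(x) {
    x <- .advanceStage(x, "normalized", "log")
    m <- intensities(x)
    bad <- which(m <= 0, arr.ind = TRUE)
    if (nrow(bad) > 0)
        stop(sprintf("non-positive value at [%s, %s]; cannot log-transform",
                     rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]),
             call. = FALSE)
    .setIntensity(x, log(m))
}

#' Run the full preprocessing chain
#'
#' Convenience wrapper: impute, filter by original missingness, normalize to
#' total intensity, log-transform.
#'
#' @inheritParams imputeCensored
#' @inheritParams filterMissing
#' @param log if `FALSE`, stop after normalization (e.g. when raw-scale fold
#'   changes are needed).
#' @return a log-stage (or normalized-stage) `MetaboSet`.
#' @export
preprocess <- function(x, widthFactor = 0.5, shiftFactor = 2.5,
                       scope = "per_sample", maxMissingFraction = 0.25,
                       seed = 1L, log = TRUE) {
    x <- imputeCensored(x, widthFactor, shiftFactor, scope, seed = seed)
    x <- filterMissing(x, maxMissingFraction)
    x <- normalizeTotal(x)
    if (log) x <- logTransform(x) else x
}
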