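#' Pipeline run configuration
#'
#' Collects every tunable threshold of the two pipelines with the standard
#' defaults: missingness filter < 0.25, VIP > 1, p < 0.05, FDR cutoff 0.1,
#' minimum cluster size 10, 1000 trees, 70/30 split.  A seed is mandatory;
#' each stochastic stage derives its own substream from it (hashed with the
#' stage name), so enabling or disabling one stage never perturbs another's
#' draws.
#'
#' @param seed integer seed.
#' @param maxMissingFraction,vipThreshold,pThreshold,fdrAlpha,minClusterSize
#'   analysis thresholds.
#' @param nTrees,trainFraction random-forest settings.
#' @param nCases,nControls extreme-selection sizes for the cohort pipeline.
#' @param imputeScope imputation scope (see [imputeCensored()]).
#' @return a named list of validated settings.
#' @export
runConfig <- function(seed, maxMissingFraction = 0.25, vipThreshold = 1,
                      pThreshold = 0.05, fdrAlpha = 0.1, minClusterSize = 10L,
                      nTrees = 1000L, trainFraction = 0.7, nCases = 120L,
                      nControls = 120L, imputeScope = "per_sample") {
    .stopIfNot(!missing(seed) && is.finite(seed), "a seed is mandatory")
    .stopIfNot(maxMissingFraction > 0 && maxMissingFraction <= 1 &&
               vipThreshold >= 0 && pThreshold > 0 && pThreshold <= 1 &&
               fdrAlpha > 0 && fdrAlpha <= 1 && trainFraction > 0 &&
               trainFraction < 1 && nTrees >= 1 && minClusterSize >= 1,
               "threshold out of range")
    list(seed = as.integer(seed), maxMissingFraction = maxMissingFraction,
         vipThreshold = vipThreshold, pThreshold = pThreshold,
         fdrAlpha = fdrAlpha, minClusterSize = as.integer(minClusterSize),
         nTrees = as.integer(nTrees), trainFraction = trainFraction,
         nCases = as.integer(nCases), nControls = as.integer(nControls),
         imputeScope = imputeScope)
}

.writeManifest <- function(manifest, outDir) {
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the full intervention-trial pipeline
#'
#' preprocess (impute, filter, normalize) -> baseline-ratio responses ->
#' per-time dual-criterion selection and union -> response-pattern
#' clustering -> within-arm time courses -> optional clinical correlation
#' screen.  All tables are written as TSV under `outDir` together with a
#' `manifest.json` recording the seed, thresholds and stage counts; runs are
#' fully reproducible from config + seed.
#'
#' @param x a raw-stage [MetaboSet] with `subject`, `arm`, `time` columns.
#' @param config a [runConfig()].
#' @param outDir output directory.
#' @param clinical optional data.frame of clinical variables (one row per
#'   sample) for the correlation screen.
#' @return invisibly, a list with the key objects (`normalized`,
#'   `responses`, `selection`, `clusters`, `timeCourses`, `distance`,
#'   `manifest`).
#' @export
runRCTPipeline <- function(x, config, outDir, clinical = NULL) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    rule <- selectionRule(config$vipThreshold, config$pThreshold)
    imp <- imputeCensored(x, scope = config$imputeScope,
                          seed = stageSeed(config$seed, "impute"))
    flt <- filterMissing(imp, config$maxMissingFraction)
    nrm <- normalizeTotal(flt)
    lg <- logTransform(nrm)
    responses <- computeResponses(nrm)
    sel <- selectDifferentialAllTimes(responses, rule)
    for (nm in names(sel$tables))
        writeDifferentialTable(sel$tables[[nm]],
                               file.path(outDir, paste0("selection_", nm, ".tsv")))
    cl <- if (length(sel$unionIds) >= config$minClusterSize)
        clusterResponses(responses, sel$unionIds, config$minClusterSize)
    else list(assignment = setNames(integer(0), character(0)),
              sizes = integer(0), divisiveCoefficient = NA_real_)
    writeDifferentialTable(
        data.frame(id = names(cl$assignment), cluster = cl$assignment),
        file.path(outDir, "clusters.tsv"))
    tc <- lapply(unique(SummarizedExperiment::colData(x)$arm), function(a)
        withinArmTimeCourse(lg, a, config$fdrAlpha))
    names(tc) <- unique(SummarizedExperiment::colData(x)$arm)
    gtd <- groupTimeDistance(lg)
    write.table(gtd$dist, file.path(outDir, "group_time_distance.tsv"),
                sep = "\t", quote = FALSE)
    corr <- NULL
    if (!is.null(clinical)) {
        corr <- clinicalCorrelations(intensities(lg), clinical)
        writeDifferentialTable(corr, file.path(outDir, "clinical_correlations.tsv"))
    }
    perTime <- vapply(sel$tables, function(tb) sum(tb$selected), integer(1))
    manifest <- list(
        pipeline = "rct", seed = config$seed,
        thresholds = config[c("maxMissingFraction", "vipThreshold",
                              "pThreshold", "fdrAlpha", "minClusterSize")],
        counts = list(
            metabolitesInput = nrow(x),
            metabolitesRetained = nrow(flt),
            subjectsAnalyzed = length(unique(
                SummarizedExperiment::colData(responses)$subject)),
            subjectsExcluded = length(S4Vectors::metadata(responses)$excludedSubjects),
            selectedPerTime = as.list(perTime),
            selectedUnion = length(sel$unionIds),
            selectedAtTwoTimes = sum(sel$timesSelected == 2),
            selectedAtThreeTimes = sum(sel$timesSelected == 3),
            clustersRetained = length(cl$sizes)),
        divisiveCoefficient = cl$divisiveCoefficient,
        timeCourseCounts = lapply(tc, `[[`, "counts"))
    .writeManifest(manifest, outDir)
    invisible(list(normalized = nrm, log = lg, responses = responses,
                   selection = sel, clusters = cl, timeCourses = tc,
                   distance = gtd, correlations = corr, manifest = manifest))
}

#' Run the full case-control cohort pipeline
#'
#' extreme-phenotype selection -> propensity matching -> preprocessing of
#' the matched subjects -> covariate-adjusted dual-criterion differential
#' analysis -> random-forest discrimination with held-out ROC/AUC ->
#' optional pathway over-representation of the selected metabolites.
#'
#' @param x a raw-stage [MetaboSet] of the screening population (one sample
#'   per subject; `colData` with the matching covariates and `vbmd`).
#' @param config a [runConfig()].
#' @param outDir output directory.
#' @param pathways,graphs optional pathway definitions for [enrich()].
#' @return invisibly, a list with `match`, `differential`, `classifier`,
#'   `enrichment`, `manifest`.
#' @export
runCohortPipeline <- function(x, config, outDir, pathways = NULL,
                              graphs = NULL) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    cd <- as.data.frame(SummarizedExperiment::colData(x))
    ext <- selectExtremes(cd, "vbmd", config$nCases, config$nControls)
    mr <- propensityMatch(cd, ext$caseIds, ext$controlPoolIds)
    ids <- c(mr@caseIds, mr@controlIds)
    group <- rep(c("case", "control"),
                 c(length(mr@caseIds), length(mr@controlIds)))
    sub <- x[, ids]
    nrm <- preprocess(sub, scope = config$imputeScope,
                      maxMissingFraction = config$maxMissingFraction,
                      seed = stageSeed(config$seed, "impute"), log = FALSE)
    rule <- selectionRule(config$vipThreshold, config$pThreshold)
    diffTab <- caseControlDifferential(nrm, group, rule)
    writeDifferentialTable(diffTab, file.path(outDir, "differential.tsv"))
    selIds <- diffTab$id[diffTab$selected]
    clf <- NULL
    if (length(selIds) >= 2L) {
        X <- t(log(intensities(nrm)[selIds, , drop = FALSE]))
        clf <- trainRF(X, group, config$trainFraction, config$nTrees,
                       seed = stageSeed(config$seed, "forest"))
        write.table(clf@roc, file.path(outDir, "roc.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        writeDifferentialTable(topImportance(clf),
                               file.path(outDir, "importance_top30.tsv"))
    }
    enr <- NULL
    if (!is.null(pathways) && length(selIds) > 0) {
        enr <- enrich(selIds, diffTab$id, pathways, graphs)
        writeDifferentialTable(enr, file.path(outDir, "enrichment.tsv"))
    }
    manifest <- list(
        pipeline = "cohort", seed = config$seed,
        thresholds = config[c("maxMissingFraction", "vipThreshold",
                              "pThreshold", "nTrees", "trainFraction")],
        counts = list(
            population = nrow(cd),
            matchedCases = length(mr@caseIds),
            matchedControls = length(mr@controlIds),
            metabolitesRetained = nrow(nrm),
            selected = length(selIds),
            selectedDown = sum(diffTab$selected & diffTab$direction == "down"),
            selectedUp = sum(diffTab$selected & diffTab$direction == "up")),
        balance = mr@balance,
        auc = if (!is.null(clf)) clf@auc else NA_real_)
    .writeManifest(manifest, outDir)
    invisible(list(match = mr, normalized = nrm, differential = diffTab,
                   classifier = clf, enrichment = enr, manifest = manifest))
}
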