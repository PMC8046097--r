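#' Configuration for the synthetic randomized-trial generator
#'
#' Defaults emulate the shape of an untargeted serum metabolomics study of a
#' one-year probiotic intervention: ~1232 metabolites measured on two arms of
#' elderly women at months 0, 3, 6 and 12, with intensity-dependent
#' (left-censored) missingness and per-sample total-intensity scale factors.
#'
#' Intensities are generated on the natural-log scale and exponentiated:
#' latent log intensity = metabolite base level + between-subject effect +
#' planted arm-by-time effect (responsive metabolites, treatment arm,
#' follow-up times only) + residual noise + per-sample log scale factor.
#' A cell is censored to missing with probability
#' `plogis(-missingSteepness * (latent - missingMid))`, i.e. the lower the
#' latent log intensity the more likely the cell is missing, so the
#' left-shifted imputation model is literally true in simulation.
#'
#' @param nMetabolites number of metabolites.
#' @param nSubjectsPerArm subjects per arm (treatment and placebo).
#' @param timePoints ordered months, starting at baseline 0.
#' @param nResponsive number of planted treatment-responsive metabolites.
#' @param effectLog2 planted response size: log2 follow-up/baseline ratio in
#'   the treatment arm (sign randomized per metabolite).
#' @param subjectSd between-subject SD of log intensity.
#' @param noiseSd residual SD of log intensity.
#' @param missingSteepness,missingMid logistic censoring slope and midpoint on
#'   the latent natural-log intensity.
#' @param sampleScaleSd SD of the per-sample log scale factor (sample-volume
#'   differences that total-intensity normalization removes).
#' @param baseMeanLog,baseSdLog mean and SD of per-metabolite base log
#'   intensity (natural log of LC-MS peak areas).
#' @param seed RNG seed (R's default Mersenne-Twister generator).
#' @return a `SimConfig` object.
#' @export
simConfig <- function(nMetabolites = 1232L, nSubjectsPerArm = 34L,
                      timePoints = c(0, 3, 6, 12), nResponsive = 97L,
                      effectLog2 = 1, subjectSd = 0.5, noiseSd = 0.3,
                      missingSteepness = 1.2, missingMid = 10.5,
                      sampleScaleSd = 0.2, baseMeanLog = 13, baseSdLog = 1.5,
                      seed = 1L) {
    new("SimConfig", nMetabolites = as.integer(nMetabolites),
        nSubjectsPerArm = as.integer(nSubjectsPerArm),
        timePoints = as.numeric(timePoints),
        nResponsive = as.integer(nResponsive),
        effectLog2 = effectLog2, subjectSd = subjectSd, noiseSd = noiseSd,
        missingSteepness = missingSteepness, missingMid = missingMid,
        sampleScaleSd = sampleScaleSd, baseMeanLog = baseMeanLog,
        baseSdLog = baseSdLog, seed = as.integer(seed))
}

#' @rdname simConfig
#' @export
setClass("SimConfig", representation(
    nMetabolites = "integer", nSubjectsPerArm = "integer",
    timePoints = "numeric", nResponsive = "integer", effectLog2 = "numeric",
    subjectSd = "numeric", noiseSd = "numeric", missingSteepness = "numeric",
    missingMid = "numeric", sampleScaleSd = "numeric", baseMeanLog = "numeric",
    baseSdLog = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
    msg <- character()
    if (object@nMetabolites < 1L || object@nSubjectsPerArm < 1L)
        msg <- c(msg, "dimensions must be positive")
    if (object@nResponsive > object@nMetabolites || object@nResponsive < 0L)
        msg <- c(msg, "nResponsive must be between 0 and nMetabolites")
    if (any(c(object@subjectSd, object@noiseSd, object@sampleScaleSd,
              object@baseSdLog) <= 0))
        msg <- c(msg, "all SDs must be > 0")
    tp <- object@timePoints
    if (length(tp) < 2L || tp[1] != 0 || any(diff(tp) <= 0))
        msg <- c(msg, "timePoints must start at 0 and be strictly increasing")
    if (length(msg)) msg else TRUE
})

#' Configuration for the synthetic screening-cohort generator
#'
#' Defaults emulate a population screening of elderly women (age 78 +/- 1.7 y,
#' BMI 24.4 +/- 3.6 kg/m^2; generator defaults, overridable) from which the
#' lowest- and highest-BMD extremes are later selected and matched.  Tibia
#' volumetric BMD depends on age, BMI and a latent bone-status factor; planted
#' marker metabolites co-vary with standardized vBMD, scaled analytically
#' (truncated-normal tail mean for the configured selection fractions) so the
#' realized case-vs-control log2 difference after extreme selection is
#' approximately `groupEffectLog2` (sign randomized per marker, with the
#' configured fraction of markers lower in cases).  All metabolites receive a
#' `confounderStrength` log2-per-SD contribution from age and BMI, which
#' induces confounding via the selection on vBMD.
#'
#' @param nPopulation screening-population size.
#' @param nCases,nControls sizes of the low-BMD case and high-BMD control
#'   extremes drawn later by [selectExtremes()].
#' @param nMetabolites number of metabolites.
#' @param nGroupMarkers planted group-differential metabolites.
#' @param groupEffectLog2 planted case-vs-control log2 effect.
#' @param propMarkersDown fraction of markers lower in cases.
#' @param confounderStrength log2 change per SD of age and of BMI applied to
#'   every metabolite.
#' @param ageMean,ageSd,bmiMean,bmiSd,heightMean,heightSd clinical covariate
#'   distributions.
#' @param noiseSd,missingSteepness,missingMid,sampleScaleSd,baseMeanLog,baseSdLog
#'   as in [simConfig()].
#' @param seed RNG seed.
#' @return a `CohortConfig` object.
#' @export
cohortConfig <- function(nPopulation = 3028L, nCases = 120L, nControls = 120L,
                         nMetabolites = 1232L, nGroupMarkers = 104L,
                         groupEffectLog2 = 0.2, propMarkersDown = 0.78,
                         confounderStrength = 0.1,
                         ageMean = 78.2, ageSd = 1.7, bmiMean = 24.4,
                         bmiSd = 3.6, heightMean = 162, heightSd = 6,
                         noiseSd = 0.35, missingSteepness = 1.2,
                         missingMid = 10.5, sampleScaleSd = 0.2,
                         baseMeanLog = 13, baseSdLog = 1.5, seed = 1L) {
    new("CohortConfig", nPopulation = as.integer(nPopulation),
        nCases = as.integer(nCases), nControls = as.integer(nControls),
        nMetabolites = as.integer(nMetabolites),
        nGroupMarkers = as.integer(nGroupMarkers),
        groupEffectLog2 = groupEffectLog2, propMarkersDown = propMarkersDown,
        confounderStrength = confounderStrength,
        ageMean = ageMean, ageSd = ageSd, bmiMean = bmiMean, bmiSd = bmiSd,
        heightMean = heightMean, heightSd = heightSd, noiseSd = noiseSd,
        missingSteepness = missingSteepness, missingMid = missingMid,
        sampleScaleSd = sampleScaleSd, baseMeanLog = baseMeanLog,
        baseSdLog = baseSdLog, seed = as.integer(seed))
}

#' @rdname cohortConfig
#' @export
setClass("CohortConfig", representation(
    nPopulation = "integer", nCases = "integer", nControls = "integer",
    nMetabolites = "integer", nGroupMarkers = "integer",
    groupEffectLog2 = "numeric", propMarkersDown = "numeric",
    confounderStrength = "numeric", ageMean = "numeric", ageSd = "numeric",
    bmiMean = "numeric", bmiSd = "numeric", heightMean = "numeric",
    heightSd = "numeric", noiseSd = "numeric", missingSteepness = "numeric",
    missingMid = "numeric", sampleScaleSd = "numeric", baseMeanLog = "numeric",
    baseSdLog = "numeric", seed = "integer"))

setValidity("CohortConfig", function(object) {
    msg <- character()
    if (any(c(object@nPopulation, object@nCases, object@nControls,
              object@nMetabolites) < 1L))
        msg <- c(msg, "counts must be positive")
    if (object@nCases + object@nControls > object@nPopulation)
        msg <- c(msg, "nCases + nControls must not exceed nPopulation")
    if (object@nGroupMarkers > object@nMetabolites)
        msg <- c(msg, "nGroupMarkers must not exceed nMetabolites")
    if (length(msg)) msg else TRUE
})

.metIds <- function(n) sprintf("M%04d", seq_len(n))

.metAnnotation <- function(ids, seed) {
    classes <- c("Amino acid", "Lipid", "Peptide", "Carbohydrate",
                 "Cofactor and vitamin", "Nucleotide", "Xenobiotic")
    set.seed(stageSeed(seed, "annotation"))
    data.frame(id = ids,
               name = paste0("metabolite_", ids),
               class = sample(classes, length(ids), replace = TRUE),
               subPathway = paste0("subpathway_",
                                   sample(50L, length(ids), replace = TRUE)),
               row.names = ids, stringsAsFactors = FALSE)
}

#' Simulate a two-arm longitudinal metabolomics trial with known ground truth
#'
#' @param config a [simConfig()] object.
#' @return a list with `mset` (a raw-stage [MetaboSet] whose `colData` carries
#'   `subject`, `arm` and `time`) and `truth` (a list with `responsiveIds`,
#'   the named per-metabolite signed `effectsLog2`, and empty
#'   `groupMarkerIds`).  Identical configs (including seed) give
#'   byte-identical output.
#' @examples
#' sim <- simulateRCT(simConfig(nMetabolites = 50, nSubjectsPerArm = 6))
#' table(SummarizedExperiment::colData(sim$mset)$arm)
#' @export
simulateRCT <- function(config) {
    validObject(config)
    set.seed(config@seed)
    nm <- config@nMetabolites
    ns <- config@nSubjectsPerArm
    tp <- config@timePoints
    mets <- .metIds(nm)
    subjects <- c(sprintf("T%03d", seq_len(ns)), sprintf("P%03d", seq_len(ns)))
    arm <- rep(c("treatment", "placebo"), each = ns)
    samples <- as.vector(outer(subjects, tp,
                               function(s, t) sprintf("%s_m%02d", s, t)))
    sampleSubject <- rep(subjects, times = length(tp))
    sampleArm <- rep(arm, times = length(tp))
    sampleTime <- rep(tp, each = 2L * ns)

    base <- rnorm(nm, config@baseMeanLog, config@baseSdLog)
    responsive <- sort(sample(mets, config@nResponsive))
    sign <- setNames(numeric(nm), mets)
    sign[responsive] <- sample(c(-1, 1), config@nResponsive, replace = TRUE)
    effects <- sign * config@effectLog2

    subjEff <- setNames(rnorm(2L * ns, 0, config@subjectSd), subjects)
    scaleLog <- setNames(rnorm(length(samples), 0, config@sampleScaleSd),
                         samples)

    latent <- matrix(base, nm, length(samples)) +
        matrix(subjEff[sampleSubject], nm, length(samples), byrow = TRUE) +
        (effects * log(2)) %o% as.numeric(sampleArm == "treatment" &
                                          sampleTime > 0) +
        matrix(rnorm(nm * length(samples), 0, config@noiseSd),
               nm, length(samples)) +
        matrix(scaleLog, nm, length(samples), byrow = TRUE)
    dimnames(latent) <- list(mets, samples)

    pMiss <- plogis(-config@missingSteepness * (latent - config@missingMid))
    obs <- exp(latent)
    obs[matrix(runif(length(pMiss)) < pMiss, nm)] <- NA_real_

    cd <- data.frame(subject = sampleSubject, arm = sampleArm,
                     time = sampleTime, row.names = samples,
                     stringsAsFactors = FALSE)
    mset <- MetaboSet(obs, cd, rowData = .metAnnotation(mets, config@seed))
    truth <- list(responsiveIds = responsive,
                  effectsLog2 = effects[responsive],
                  groupMarkerIds = character(0))
    list(mset = mset, truth = truth)
}

## E[Z | Z > qnorm(1 - frac)] for a standard normal: mean of the selected tail
.tailMean <- function(frac) {
    q <- qnorm(1 - frac)
    dnorm(q) / frac
}

#' Simulate a screening cohort for extreme-BMD case-control analysis
#'
#' Generates the full screening population (clinical covariates, tibia
#' volumetric BMD and serum metabolite intensities).  Case/control labels are
#' not assigned here: they come from [selectExtremes()] and
#' [propensityMatch()] downstream, mirroring an extreme-phenotype design.
#'
#' @param config a [cohortConfig()] object.
#' @return a list with `mset` (raw-stage [MetaboSet], one sample per subject;
#'   `colData` columns `subject`, `age`, `height`, `weight`, `bmi`, `vbmd`)
#'   and `truth` (`groupMarkerIds`, named signed `effectsLog2` on the
#'   case-vs-control scale, empty `responsiveIds`).
#' @export
simulateCohort <- function(config) {
    validObject(config)
    set.seed(config@seed)
    np <- config@nPopulation
    nm <- config@nMetabolites
    mets <- .metIds(nm)
    subjects <- sprintf("S%04d", seq_len(np))

    age <- rnorm(np, config@ageMean, config@ageSd)
    height <- rnorm(np, config@heightMean, config@heightSd)
    bmi <- pmax(rnorm(np, config@bmiMean, config@bmiSd), 15)
    weight <- bmi * (height / 100)^2
    zAge <- (age - config@ageMean) / config@ageSd
    zBmi <- (bmi - config@bmiMean) / config@bmiSd

    u <- rnorm(np)                       # latent bone-status factor
    vbmd <- 240 - 6 * zAge - 4 * zBmi - 30 * u + rnorm(np, 0, 10)
    zV <- (vbmd - mean(vbmd)) / sd(vbmd)

    base <- rnorm(nm, config@baseMeanLog, config@baseSdLog)
    markers <- sort(sample(mets, config@nGroupMarkers))
    nDown <- round(config@propMarkersDown * config@nGroupMarkers)
    sgn <- setNames(numeric(nm), mets)
    sgn[markers] <- sample(rep(c(-1, 1), c(nDown,
                                           config@nGroupMarkers - nDown)))
    ## scale so the realized case - control log2 gap after extreme selection
    ## is ~ groupEffectLog2: tails of the standardized vBMD have mean +/- mbar
    mbar <- (.tailMean(config@nControls / np) +
             .tailMean(config@nCases / np)) / 2
    beta <- -sgn * config@groupEffectLog2 * log(2) / (2 * mbar)

    confLog <- config@confounderStrength * log(2)
    scaleLog <- rnorm(np, 0, config@sampleScaleSd)
    latent <- matrix(base, nm, np) +
        beta %o% zV +
        matrix(confLog * (zAge + zBmi), nm, np, byrow = TRUE) +
        matrix(rnorm(nm * np, 0, config@noiseSd), nm, np) +
        matrix(scaleLog, nm, np, byrow = TRUE)
    dimnames(latent) <- list(mets, subjects)

    pMiss <- plogis(-config@missingSteepness * (latent - config@missingMid))
    obs <- exp(latent)
    obs[matrix(runif(length(pMiss)) < pMiss, nm)] <- NA_real_

    cd <- data.frame(subject = subjects, age = age, height = height,
                     weight = weight, bmi = bmi, vbmd = vbmd,
                     row.names = subjects, stringsAsFactors = FALSE)
    mset <- MetaboSet(obs, cd, rowData = .metAnnotation(mets, config@seed))
    truth <- list(responsiveIds = character(0),
                  groupMarkerIds = markers,
                  effectsLog2 = (sgn * config@groupEffectLog2)[markers])
    list(mset = mset, truth = truth)
}

#' Write / read a synthetic dataset as plain-text fixture files
#'
#' Writes `intensities.tsv` (first column `id`, then one column per sample;
#' missing cells serialized as empty fields), `samples.tsv`,
#' `annotations.tsv` and `truth.json` into `dir`.  [readFixture()] reverses
#' the operation losslessly (finite cells and missingness masks round-trip).
#'
#' @param sim a list as returned by [simulateRCT()] or [simulateCohort()].
#' @param dir output directory (created if needed).
#' @return `writeFixture()` returns the paths invisibly; `readFixture()`
#'   returns a list with `mset` and `truth`.
#' @export
writeFixture <- function(sim, dir) {
    if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
        stop("cannot create fixture directory: ", dir, call. = FALSE)
    paths <- file.path(dir, c("intensities.tsv", "samples.tsv",
                              "annotations.tsv", "truth.json"))
    m <- intensities(sim$mset)
    df <- data.frame(id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    ok <- try({
        write.table(df, paths[1], sep = "\t", quote = FALSE, na = "",
                    row.names = FALSE)
        cd <- as.data.frame(SummarizedExperiment::colData(sim$mset))
        write.table(data.frame(sample = rownames(cd), cd,
                               check.names = FALSE),
                    paths[2], sep = "\t", quote = FALSE, row.names = FALSE)
        rd <- as.data.frame(SummarizedExperiment::rowData(sim$mset))
        write.table(rd, paths[3], sep = "\t", quote = FALSE, row.names = FALSE)
        jsonlite::write_json(sim$truth, paths[4], auto_unbox = FALSE,
                             digits = NA)
    }, silent = TRUE)
    if (inherits(ok, "try-error"))
        stop("fixture write failed under ", dir, ": ",
             attr(ok, "condition")$message, call. = FALSE)
    invisible(paths)
}

#' @rdname writeFixture
#' @export
readFixture <- function(dir) {
    mset <- readIntensityTable(file.path(dir, "intensities.tsv"),
                               file.path(dir, "samples.tsv"),
                               file.path(dir, "annotations.tsv"))
    truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                                 simplifyVector = TRUE)
    if (!is.null(truth$effectsLog2))
        truth$effectsLog2 <- unlist(truth$effectsLog2)
    list(mset = mset, truth = truth)
}
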