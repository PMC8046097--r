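test_that("identical seeds give byte-identical simulations", {
    cfg <- simConfig(nMetabolites = 60, nSubjectsPerArm = 5, nResponsive = 6,
                     seed = 1)
    s1 <- simulateRCT(cfg); s2 <- simulateRCT(cfg)
    expect_identical(intensities(s1$mset), intensities(s2$mset))
    expect_identical(s1$truth, s2$truth)
    s3 <- simulateRCT(simConfig(nMetabolites = 60, nSubjectsPerArm = 5,
                                nResponsive = 6, seed = 2))
    expect_false(identical(intensities(s1$mset), intensities(s3$mset)))
})

test_that("config invariants are enforced", {
    expect_error(simConfig(nMetabolites = 10, nResponsive = 11), "nResponsive")
    expect_error(simConfig(nMetabolites = 0), "positive")
    expect_error(simConfig(timePoints = c(3, 6)), "start at 0")
    expect_error(simConfig(noiseSd = 0), "SDs")
    expect_error(cohortConfig(nPopulation = 100, nCases = 60, nControls = 60),
                 "exceed")
})

test_that("censoring is left-shifted, monotone in intensity, and matches the logistic rate", {
    cfg <- simConfig(nMetabolites = 400, nSubjectsPerArm = 20,
                     nResponsive = 0, missingSteepness = 30,
                     seed = 42)
    # midpoint at the 10th percentile of the latent log-intensity distribution
    sdTot <- sqrt(cfg@baseSdLog^2 + cfg@subjectSd^2 + cfg@noiseSd^2 +
                  cfg@sampleScaleSd^2)
    cfg@missingMid <- qnorm(0.10, cfg@baseMeanLog, sdTot)
    sim <- simulateRCT(cfg)
    frac <- mean(missingMask(sim$mset))
    # oracle: empirical censoring rate from 1e5 Bernoulli draws at known
    # latent intensities
    set.seed(99)
    lat <- rnorm(1e5, cfg@baseMeanLog, sdTot)
    pM <- plogis(-cfg@missingSteepness * (lat - cfg@missingMid))
    expected <- mean(runif(1e5) < pM)
    tol <- 3 * sqrt(expected * (1 - expected)) *
        (1 / sqrt(1e5) + 1 / sqrt(length(missingMask(sim$mset))))
    expect_lt(abs(frac - expected), tol + 0.01)
    # monotone: low-intensity metabolites are missing more often
    rowMed <- apply(intensities(sim$mset), 1, median, na.rm = TRUE)
    rowMiss <- rowMeans(missingMask(sim$mset))
    ok <- is.finite(rowMed)           # fully censored rows have no median
    expect_gt(mean(rowMiss[!ok]), 0.99)
    terc <- cut(rowMed[ok], quantile(rowMed[ok], c(0, 1/3, 2/3, 1)),
                include.lowest = TRUE, labels = FALSE)
    byTerc <- tapply(rowMiss[ok], terc, mean)
    expect_true(byTerc[1] > byTerc[2] && byTerc[2] >= byTerc[3])
})

test_that("null trial data give uniform arm-comparison p-values", {
    sim <- simulateRCT(simConfig(nMetabolites = 800, nSubjectsPerArm = 15,
                                 nResponsive = 0, missingSteepness = 5,
                                 missingMid = 5, seed = 7))  # ~no missing
    nrm <- suppressMessages(preprocess(sim$mset, seed = 7, log = FALSE))
    resp <- computeResponses(nrm)
    tab <- selectDifferential(resp, 3)
    expect_gt(suppressWarnings(stats::ks.test(tab$p, "punif"))$p.value, 1e-3)
})

test_that("fixtures round-trip losslessly through the readers", {
    sim <- simulateRCT(simConfig(nMetabolites = 80, nSubjectsPerArm = 4,
                                 nResponsive = 5, seed = 3))
    dir <- file.path(tempdir(), "fx1")
    writeFixture(sim, dir)
    back <- readFixture(dir)
    m0 <- intensities(sim$mset); m1 <- intensities(back$mset)
    expect_identical(is.na(m0), is.na(m1))
    expect_equal(m0[!is.na(m0)], m1[!is.na(m1)], tolerance = 1e-12)
    expect_identical(sort(back$truth$responsiveIds),
                     sort(sim$truth$responsiveIds))
    cd0 <- as.data.frame(SummarizedExperiment::colData(sim$mset))
    cd1 <- as.data.frame(SummarizedExperiment::colData(back$mset))
    expect_equal(cd0$arm, cd1$arm)
})

test_that("a complete matrix serializes with no empty fields; annotations cover all metabolites", {
    cfg <- simConfig(nMetabolites = 1232, nSubjectsPerArm = 3,
                     nResponsive = 0, missingSteepness = 5, missingMid = 0,
                     seed = 1)   # midpoint far below: nothing censored
    sim <- simulateRCT(cfg)
    expect_equal(sum(missingMask(sim$mset)), 0L)
    dir <- file.path(tempdir(), "fx2")
    writeFixture(sim, dir)
    lines <- readLines(file.path(dir, "intensities.tsv"))
    expect_false(any(grepl("\t\t|\t$", lines)))
    ann <- read.delim(file.path(dir, "annotations.tsv"))
    expect_equal(nrow(ann), 1232L)
    expect_equal(nrow(readIntensityTable(file.path(dir, "intensities.tsv"))),
                 1232L)
})

test_that("cohort generator produces the screening population with planted structure", {
    cfg <- cohortConfig(nPopulation = 3028, nCases = 120, nControls = 120,
                        nMetabolites = 40, nGroupMarkers = 8, seed = 2)
    sim <- simulateCohort(cfg)
    expect_equal(ncol(sim$mset), 3028L)
    cd <- as.data.frame(SummarizedExperiment::colData(sim$mset))
    expect_true(all(c("age", "height", "weight", "bmi", "vbmd") %in%
                    colnames(cd)))
    expect_lt(abs(mean(cd$age) - 78.2), 0.2)
    expect_equal(length(sim$truth$groupMarkerIds), 8L)
})

test_that("with zero group effect, marker and null metabolites are exchangeable", {
    cfg <- cohortConfig(nPopulation = 300, nCases = 40, nControls = 40,
                        nMetabolites = 200, nGroupMarkers = 100,
                        groupEffectLog2 = 0, confounderStrength = 0,
                        missingSteepness = 5, missingMid = 0, seed = 11)
    sim <- simulateCohort(cfg)
    ext <- selectExtremes(as.data.frame(SummarizedExperiment::colData(sim$mset)),
                          nLow = 40, nHigh = 40)
    m <- log(intensities(sim$mset))
    p <- apply(m, 1, function(v)
        t.test(v[ext$caseIds], v[ext$controlPoolIds])$p.value)
    isMarker <- rownames(m) %in% sim$truth$groupMarkerIds
    # both sets calibrated at nominal alpha
    expect_lt(abs(mean(p[isMarker] < 0.05) - 0.05), 0.06)
    expect_lt(abs(mean(p[!isMarker] < 0.05) - 0.05), 0.06)
})

test_that("age/BMI confounding biases unadjusted contrasts and adjustment removes it", {
    cfg <- cohortConfig(nPopulation = 400, nCases = 50, nControls = 50,
                        nMetabolites = 150, nGroupMarkers = 0,
                        groupEffectLog2 = 0, confounderStrength = 0.5,
                        missingSteepness = 5, missingMid = 0, seed = 13)
    sim <- simulateCohort(cfg)
    cd <- as.data.frame(SummarizedExperiment::colData(sim$mset))
    ext <- selectExtremes(cd, nLow = 50, nHigh = 50)
    grp <- factor(rep(c("case", "control"), each = 50),
                  levels = c("control", "case"))
    ids <- c(ext$caseIds, ext$controlPoolIds)
    m <- log(intensities(sim$mset)[, ids])
    # analytic omitted-variable bias given the realized covariates
    zA <- (cd[ids, "age"] - cfg@ageMean) / cfg@ageSd
    zB <- (cd[ids, "bmi"] - cfg@bmiMean) / cfg@bmiSd
    predBias <- 0.5 * log(2) *
        (mean((zA + zB)[grp == "case"]) - mean((zA + zB)[grp == "control"]))
    rawDiff <- rowMeans(m[, grp == "case"]) - rowMeans(m[, grp == "control"])
    mcSe <- sd(rawDiff) / sqrt(nrow(m))
    expect_gt(abs(predBias), 0.1)              # the confounding is material
    expect_lt(abs(mean(rawDiff) - predBias), 2 * mcSe + 0.02)
    adj <- vapply(rownames(m), function(id)
        lmGroupContrast(m[id, ], grp, cd[ids, "age"], cd[ids, "bmi"])$estimate,
        numeric(1))
    expect_lt(abs(mean(adj)), 2 * sd(adj) / sqrt(length(adj)) + 0.02)
})
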