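.toyTrial <- function(nSubjPerArm = 4, times = c(0, 3, 6, 12), nMet = 6,
                      seed = 1) {
    set.seed(seed)
    subj <- c(sprintf("T%02d", 1:nSubjPerArm), sprintf("P%02d", 1:nSubjPerArm))
    arm <- rep(c("treatment", "placebo"), each = nSubjPerArm)
    cols <- as.vector(outer(subj, times, paste, sep = "_t"))
    m <- matrix(exp(rnorm(nMet * length(cols), 10)), nMet, length(cols),
                dimnames = list(sprintf("M%02d", 1:nMet), cols))
    makeMset(m, subject = rep(subj, length(times)),
             arm = rep(arm, length(times)),
             time = rep(times, each = 2 * nSubjPerArm), stage = "normalized")
}

test_that("baseline ratios are per-subject level ratios", {
    ms <- .toyTrial()
    m <- intensities(ms)
    # make one cell a known ratio: subject T01, M01 baseline 10, month-3 15
    m[1, "T01_t0"] <- 10; m[1, "T01_t3"] <- 15
    ms <- makeMset(m, subject = SummarizedExperiment::colData(ms)$subject,
                   arm = SummarizedExperiment::colData(ms)$arm,
                   time = SummarizedExperiment::colData(ms)$time,
                   stage = "normalized")
    resp <- computeResponses(ms)
    r <- SummarizedExperiment::assay(resp, "ratio")
    expect_equal(r["M01", "T01_t3"], 1.5)
    # a follow-up equal to baseline gives ratio 1 everywhere
    m2 <- intensities(ms); m2[, "T02_t6"] <- m2[, "T02_t0"]
    ms2 <- makeMset(m2, subject = SummarizedExperiment::colData(ms)$subject,
                    arm = SummarizedExperiment::colData(ms)$arm,
                    time = SummarizedExperiment::colData(ms)$time,
                    stage = "normalized")
    r2 <- SummarizedExperiment::assay(computeResponses(ms2), "ratio")
    expect_equal(unname(r2[, "T02_t6"]), rep(1, nrow(r2)))
    expect_true(all(r > 0))
})

test_that("subjects with incomplete series are excluded and logged", {
    # 71 subjects, 3 of them missing a follow-up sample: 68 analyzed
    ms <- .toyTrial(nSubjPerArm = 36, nMet = 5, seed = 2)
    drop <- c("T05_t12", "P07_t6", "P20_t3")
    ms <- ms[, setdiff(colnames(ms), c(drop, paste0("T36_t", c(0, 3, 6, 12))))]
    expect_equal(length(unique(SummarizedExperiment::colData(ms)$subject)), 71L)
    expect_message(resp <- computeResponses(ms), "excluding 3 subject")
    expect_equal(length(unique(SummarizedExperiment::colData(resp)$subject)),
                 68L)
    expect_identical(sort(S4Vectors::metadata(resp)$excludedSubjects),
                     c("P07", "P20", "T05"))
})

test_that("dual-criterion selection is a strict conjunction and monotone in thresholds", {
    rule <- selectionRule()
    expect_false(applySelectionRule(1.2, 0.2, rule))    # VIP passes, p fails
    expect_false(applySelectionRule(0.8, 0.001, rule))  # p passes, VIP fails
    expect_true(applySelectionRule(1.2, 0.01, rule))
    expect_false(applySelectionRule(NA, 0.01, rule))
    set.seed(40)
    vip <- runif(500, 0, 3); p <- runif(500)
    base <- applySelectionRule(vip, p, selectionRule(1, 0.05))
    stricter <- applySelectionRule(vip, p, selectionRule(1.5, 0.01))
    expect_true(all(stricter <= base))   # raising VIP / lowering p never adds
})

test_that("planted responders are selected and nulls are not (small trial)", {
    sim <- simulateRCT(simConfig(nMetabolites = 120, nSubjectsPerArm = 20,
                                 nResponsive = 12, effectLog2 = 2,
                                 missingSteepness = 5, missingMid = 5,
                                 seed = 41))
    nrm <- suppressMessages(preprocess(sim$mset, seed = 41, log = FALSE))
    resp <- computeResponses(nrm)
    tab <- selectDifferential(resp, 6)
    hits <- tab$id[tab$selected]
    expect_gte(mean(sim$truth$responsiveIds %in% hits), 0.9)
    # direction agrees with the planted sign
    sel <- tab[tab$id %in% sim$truth$responsiveIds, ]
    sgn <- sign(sim$truth$effectsLog2[sel$id])
    expect_gte(mean((sel$direction == "up") == (sgn > 0)), 0.9)
})

test_that("two planted correlation blocks are recovered as two clusters", {
    set.seed(42)
    ar <- archetypeResponses(nPer = 15, nSubj = 12, noiseSd = 0.05, seed = 42)
    # use only archetypes B and D as two blocks
    ids <- names(ar$truth)[ar$truth %in% c("B", "D")]
    cl <- clusterResponses(ar$responses, ids, minClusterSize = 10)
    expect_equal(length(cl$sizes), 2L)
    agree <- table(cl$assignment, ar$truth[names(cl$assignment)])
    expect_true(all(rowSums(agree > 0) == 1))
    # a duplicated metabolite (correlation distance 0) always co-clusters
    r <- SummarizedExperiment::assay(ar$responses, "ratio")
    r2 <- rbind(r, DUP = r[ids[1], ])
    se2 <- SummarizedExperiment::SummarizedExperiment(
        assays = list(ratio = r2),
        colData = SummarizedExperiment::colData(ar$responses))
    cl3 <- clusterResponses(se2, c(ids, "DUP"), minClusterSize = 10)
    expect_equal(unname(cl3$assignment["DUP"]),
                 unname(cl3$assignment[ids[1]]))
})

test_that("four planted response archetypes yield four retained clusters", {
    ar <- archetypeResponses(nPer = 12, nSubj = 15, noiseSd = 0.08, seed = 43)
    cl <- clusterResponses(ar$responses, names(ar$truth), minClusterSize = 10)
    expect_equal(length(cl$sizes), 4L)
    tab <- table(cl$assignment, ar$truth[names(cl$assignment)])
    expect_true(all(rowSums(tab > 0) == 1))   # clusters are pure
    expect_true(all(cl$sizes >= 10))
    expect_true(cl$divisiveCoefficient > 0 && cl$divisiveCoefficient < 1)
    # order invariance: shuffled input gives the same partition
    set.seed(44)
    cl2 <- clusterResponses(ar$responses, sample(names(ar$truth)),
                            minClusterSize = 10)
    expect_identical(cl$assignment, cl2$assignment)
    # fewer metabolites than the minimum size: warning, empty assignment
    expect_warning(empty <- clusterResponses(ar$responses,
                                             names(ar$truth)[1:5],
                                             minClusterSize = 10), "fewer")
    expect_true(all(is.na(empty$assignment)))
})

test_that("divisive tree topology matches the splinter-procedure reference", {
    set.seed(45)
    for (rep in 1:5)
        expect_true(dianaTopologyMatches(dist(matrix(rnorm(15 * 3), 15, 3))))
})

test_that("arm-by-time distance matrix is a metric with baseline arms closest", {
    ms <- .toyTrial(nSubjPerArm = 10, nMet = 40, seed = 46)
    m <- intensities(ms)
    cd <- as.data.frame(SummarizedExperiment::colData(ms))
    # arms identical at baseline, divergent later
    base <- exp(rnorm(40, 10))
    for (j in which(cd$time == 0)) m[, j] <- base * exp(rnorm(40, 0, 0.01))
    for (j in which(cd$time > 0))
        m[, j] <- base * exp(rnorm(40, ifelse(cd$arm[j] == "treatment", 1, -1),
                                   0.05))
    lg <- logTransform(normalizeTotal(makeMset(m, subject = cd$subject,
                                               arm = cd$arm, time = cd$time,
                                               stage = "filtered")))
    gtd <- groupTimeDistance(lg)
    D <- gtd$dist
    expect_equal(unname(diag(D)), rep(0, nrow(D)))
    expect_equal(D, t(D))
    offDiag <- D[upper.tri(D)]
    expect_equal(min(offDiag), D["placebo_m0", "treatment_m0"])
    # triangle inequality over all triples
    n <- nrow(D)
    for (i in 1:n) for (j in 1:n) for (k in 1:n)
        expect_lte(D[i, j], D[i, k] + D[k, j] + 1e-12)
})

test_that("within-arm time course counts up/down at the FDR cutoff", {
    ms <- .toyTrial(nSubjPerArm = 15, nMet = 80, seed = 47)
    m <- intensities(ms)
    cd <- as.data.frame(SummarizedExperiment::colData(ms))
    # plant a strong downshift at month 3 in the placebo arm, metabolites 1:30
    j3 <- which(cd$time == 3 & cd$arm == "placebo")
    m[1:30, j3] <- m[1:30, j3] * 2^-4
    lg <- logTransform(normalizeTotal(makeMset(m, subject = cd$subject,
                                               arm = cd$arm, time = cd$time,
                                               stage = "filtered")))
    tc <- withinArmTimeCourse(lg, "placebo")
    c03 <- tc$counts[tc$counts$comparison == "m0_vs_m3", ]
    expect_gte(c03$down, 25)
    expect_equal(c03$n, c03$up + c03$down)    # partition
    tab03 <- tc$table[tc$table$comparison == "m0_vs_m3", ]
    planted <- tab03[tab03$id %in% sprintf("M%02d", 1:30), ]
    expect_true(all(planted$direction[planted$padj < 0.1] == "down"))
    # the untouched arm is null: essentially nothing significant
    tcT <- withinArmTimeCourse(lg, "treatment")
    expect_true(all(tcT$counts$n <= 2))
})
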