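test_that("extreme selection takes the phenotype tails, ties broken by id", {
    sd <- data.frame(vbmd = 1:10 * 10.0, row.names = sprintf("S%02d", 1:10))
    ext <- selectExtremes(sd, nLow = 3, nHigh = 3)
    expect_identical(ext$caseIds, sprintf("S%02d", 1:3))
    expect_identical(sort(ext$controlPoolIds), sprintf("S%02d", 8:10))
    expect_length(intersect(ext$caseIds, ext$controlPoolIds), 0)
    expect_error(selectExtremes(sd, nLow = 6, nHigh = 6), "smaller")
    # 3028 -> 120 + 120 leaves 2788 unselected
    big <- data.frame(vbmd = rnorm(3028), row.names = sprintf("X%04d", 1:3028))
    e2 <- selectExtremes(big, nLow = 120, nHigh = 120)
    expect_equal(3028 - length(e2$caseIds) - length(e2$controlPoolIds), 2788)
})

test_that("propensity matching balances planted age confounding", {
    ok <- 0; tried <- 0
    for (s in 1:10) {
        cp <- .confoundedPool(s)
        pre <- t.test(cp$sd[cp$cases, "age"], cp$sd[cp$pool, "age"])$p.value
        if (pre >= 0.05) next
        tried <- tried + 1
        mr <- propensityMatch(cp$sd, cp$cases, cp$pool)
        expect_length(mr@controlIds, length(cp$cases))
        expect_length(intersect(mr@caseIds, mr@controlIds), 0)
        bal <- mr@balance[mr@balance$covariate == "age", ]
        expect_lt(bal$smdPost, bal$smdPre)
        if (bal$pPost >= 0.05) ok <- ok + 1
    }
    expect_gte(tried, 8)
    expect_gte(ok / tried, 0.8)
})

test_that("matching a pool drawn from the case distribution changes little", {
    set.seed(50)
    n <- 200
    sd <- data.frame(age = rnorm(n, 78, 1.7), height = rnorm(n, 162, 6),
                     weight = rnorm(n, 65, 8), bmi = rnorm(n, 24.4, 3.6),
                     row.names = sprintf("S%03d", 1:n))
    mr <- propensityMatch(sd, rownames(sd)[1:50], rownames(sd)[51:200])
    expect_true(all(mr@balance$smdPost < 0.35))
    expect_true(all(mr@balance$smdPre < 0.35))
    expect_true(all(mr@balance$pPost > 0.05))
})

test_that("covariate separation is diagnosed", {
    cp <- .confoundedPool(1)
    cp$sd$age[match(cp$cases, rownames(cp$sd))] <- 200  # perfectly separated
    expect_error(suppressWarnings(propensityMatch(cp$sd, cp$cases, cp$pool)),
                 "separation")
})

test_that("case-control differential recovers planted markers with directions", {
    cfg <- cohortConfig(nPopulation = 260, nCases = 40, nControls = 40,
                        nMetabolites = 250, nGroupMarkers = 30,
                        groupEffectLog2 = 0.8, propMarkersDown = 0.7,
                        confounderStrength = 0.1, missingSteepness = 5,
                        missingMid = 5, seed = 51)
    sim <- simulateCohort(cfg)
    cd <- as.data.frame(SummarizedExperiment::colData(sim$mset))
    ext <- selectExtremes(cd, nLow = 40, nHigh = 40)
    ids <- c(ext$caseIds, ext$controlPoolIds)
    group <- rep(c("case", "control"), each = 40)
    nrm <- suppressMessages(preprocess(sim$mset[, ids], seed = 51, log = FALSE))
    tab <- caseControlDifferential(nrm, group)
    sel <- tab[tab$selected, ]
    markers <- intersect(sim$truth$groupMarkerIds, tab$id)
    expect_gte(mean(markers %in% sel$id), 0.85)
    hit <- sel[sel$id %in% markers, ]
    sgn <- sign(sim$truth$effectsLog2[hit$id])
    expect_gte(mean((hit$direction == "up") == (sgn > 0)), 0.95)
    # the fold change gates nothing: selection uses only VIP and p
    expect_identical(tab$selected,
                     unname(applySelectionRule(tab$vip, tab$p)))
})

test_that("ROC/AUC: threshold sweep, monotone-transform invariance, pROC agreement", {
    set.seed(52)
    scores <- c(rnorm(30, 1), rnorm(40, 0))
    labels <- rep(c("case", "control"), c(30, 40))
    rc <- rocCurve(scores, labels)
    expect_true(rc$auc >= 0 && rc$auc <= 1)
    rc2 <- rocCurve(exp(scores), labels)          # strictly monotone map
    expect_equal(rc$auc, rc2$auc, tolerance = 1e-12)
    # Mann-Whitney identity as an independent check
    w <- wilcox.test(scores[labels == "case"],
                     scores[labels == "control"])$statistic
    expect_equal(rc$auc, unname(w) / (30 * 40), tolerance = 1e-12)
    skip_if_not_installed("pROC")
    pr <- pROC::roc(labels, scores, levels = c("control", "case"),
                    direction = "<", quiet = TRUE)
    expect_equal(rc$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-10)
})

test_that("random forest report: separable AUC, stratification, noise importance", {
    set.seed(53)
    n <- 60
    labels <- rep(c("case", "control"), each = n / 2)
    X <- matrix(rnorm(n * 23), n, 23,
                dimnames = list(NULL, paste0("f", 1:23)))
    X[labels == "case", 1:3] <- X[labels == "case", 1:3] + 6  # separable
    clf <- trainRF(X, labels, nTrees = 500, seed = 1)
    expect_equal(clf@auc, 1.0)
    expect_length(intersect(clf@trainIdx, clf@validIdx), 0)
    # stratified split preserves the class ratio within one subject
    trTab <- table(labels[clf@trainIdx])
    expect_lte(abs(trTab[1] - trTab[2]), 1)
    # informative features dominate; pure-noise importance ~ 0
    noise <- paste0("f", 4:23)
    expect_true(all(clf@importance[paste0("f", 1:3)] >
                    max(clf@importance[noise])))
    expect_lt(mean(abs(clf@importance[noise])),
              2 * mean(clf@importanceSd[noise]) + 1e-6)
    # AUC recomputed from the stored ROC points matches
    reAuc <- with(clf@roc, sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2))
    expect_equal(clf@auc, reAuc, tolerance = 1e-12)
})

test_that("permuted labels give chance-level AUC (small sweep)", {
    set.seed(54)
    n <- 120
    X <- matrix(rnorm(n * 20), n, 20,
                dimnames = list(NULL, paste0("f", 1:20)))
    aucs <- vapply(1:10, function(s) {
        set.seed(1000 + s)
        lab <- sample(rep(c("case", "control"), each = n / 2))
        trainRF(X, lab, nTrees = 300, seed = s)@auc
    }, numeric(1))
    expect_gt(mean(aucs), 0.38)
    expect_lt(mean(aucs), 0.62)
})
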