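#' Extreme-phenotype selection
#'
#' Picks the `nLow` subjects with the lowest and the `nHigh` subjects with
#' the highest phenotype value (e.g. tibia total volumetric BMD) from a
#' screening population.  Ties are broken by subject id (and reported).
#'
#' @param sampleData data.frame of per-subject metadata with row names =
#'   subject ids.
#' @param phenotype column name to rank on (default `"vbmd"`).
#' @param nLow,nHigh pool sizes.
#' @return a list with `caseIds` (lowest), `controlPoolIds` (highest) and
#'   `nTies` (count of boundary ties broken by id).
#' @export
selectExtremes <- function(sampleData, phenotype = "vbmd", nLow = 120L,
                           nHigh = 120L) {
    .stopIfNot(phenotype %in% colnames(sampleData),
               "phenotype column '%s' not found", phenotype)
    .stopIfNot(nrow(sampleData) >= nLow + nHigh,
               "population (%d) smaller than nLow + nHigh (%d)",
               nrow(sampleData), nLow + nHigh)
    ids <- rownames(sampleData)
    v <- sampleData[[phenotype]]
    ordLow <- ids[order(v, ids)]
    ordHigh <- ids[order(-v, ids)]
    nTies <- sum(duplicated(v[match(c(head(ordLow, nLow),
                                      head(ordHigh, nHigh)), ids)]))
    if (nTies > 0) message(nTies, " phenotype tie(s) broken by id")
    list(caseIds = head(ordLow, nLow), controlPoolIds = head(ordHigh, nHigh),
         nTies = nTies)
}

#' Propensity-score matched case/control sets
#'
#' Fits a logistic regression of case status on the covariates over cases
#' plus control pool, and matches each case to one control by greedy
#' nearest-neighbour on the logit of the propensity score, without
#' replacement, processing cases in descending propensity order.  Balance is
#' summarized per covariate before and after matching (standardized mean
#' difference and two-sample t-test p).
#'
#' @param sampleData per-subject metadata, row names = subject ids.
#' @param caseIds,controlPoolIds id vectors (pool must be at least as large
#'   as the case set; the two must be disjoint).
#' @param covariates covariate column names (default age, height, weight,
#'   BMI).
#' @return a [MatchResult-class] object.
#' @export
propensityMatch <- function(sampleData, caseIds, controlPoolIds,
                            covariates = c("age", "height", "weight", "bmi")) {
    .stopIfNot(length(controlPoolIds) >= length(caseIds),
               "control pool (%d) smaller than case set (%d)",
               length(controlPoolIds), length(caseIds))
    .stopIfNot(length(intersect(caseIds, controlPoolIds)) == 0L,
               "case and control pools overlap")
    .stopIfNot(all(covariates %in% colnames(sampleData)),
               "missing covariate column(s)")
    ids <- c(caseIds, controlPoolIds)
    df <- sampleData[ids, covariates, drop = FALSE]
    df$.case <- rep(c(1L, 0L), c(length(caseIds), length(controlPoolIds)))
    fit <- glm(.case ~ ., data = df, family = binomial())
    eps <- 1e-8
    if (!fit$converged || any(fit$fitted.values > 1 - eps) ||
        any(fit$fitted.values < eps))
        stop("propensity model did not converge (likely covariate separation between groups)",
             call. = FALSE)
    ps <- setNames(fit$fitted.values, ids)
    lp <- setNames(qlogis(ps), ids)

    avail <- controlPoolIds
    matched <- character(length(caseIds))
    ord <- caseIds[order(-ps[caseIds], caseIds)]
    for (k in seq_along(ord)) {
        d <- abs(lp[avail] - lp[ord[k]])
        pick <- avail[order(d, avail)][1]
        matched[k] <- pick
        avail <- setdiff(avail, pick)
    }
    names(matched) <- ord

    balance <- do.call(rbind, lapply(covariates, function(cv) {
        ca <- sampleData[caseIds, cv]; poolV <- sampleData[controlPoolIds, cv]
        mc <- sampleData[matched, cv]
        data.frame(covariate = cv,
                   smdPre = smd(ca, poolV), pPre = t.test(ca, poolV)$p.value,
                   smdPost = smd(ca, mc), pPost = t.test(ca, mc)$p.value)
    }))
    new("MatchResult", caseIds = unname(ord), controlIds = unname(matched),
        propensity = ps, balance = balance)
}

#' Propensity-matching result
#'
#' Matched case/control id vectors (aligned pairwise), propensity scores for
#' all candidates, and the pre/post covariate balance table.
#'
#' @name MatchResult-class
#' @aliases MatchResult
#' @export
setClass("MatchResult", representation(
    caseIds = "character", controlIds = "character", propensity = "numeric",
    balance = "data.frame"))

setValidity("MatchResult", function(object) {
    if (length(object@caseIds) != length(object@controlIds))
        return("1:1 matching requires equally many cases and controls")
    if (length(intersect(object@caseIds, object@controlIds)))
        return("a subject cannot be both case and control")
    TRUE
})

setMethod("show", "MatchResult", function(object) {
    cat(sprintf("MatchResult: %d matched pairs\n", length(object@caseIds)))
    print(object@balance, row.names = FALSE, digits = 3)
})

#' Case-control differential metabolites (VIP and adjusted p conjunction)
#'
#' Per metabolite: VIP from a case-vs-control PLS-DA on the log matrix, a
#' covariate-adjusted p-value from [lmGroupContrast()] (log level ~ group +
#' age + BMI), and the raw-scale fold change mean(case)/mean(control).
#' Selected iff VIP > threshold AND p < threshold; the fold change gates
#' nothing and only gives the direction.
#'
#' @param x a normalized-stage [MetaboSet] restricted to the matched
#'   subjects, with `age` and `bmi` in `colData`.
#' @param group factor/character per sample, `"case"` or `"control"`.
#' @param rule a [selectionRule()].
#' @param nComponents PLS-DA components (default 2).
#' @return a `data.frame`: `id`, `vip`, `estimate`, `p`, `padj`, `fc`,
#'   `direction` (`fc` vs 1), `selected`.
#' @export
caseControlDifferential <- function(x, group, rule = selectionRule(),
                                    nComponents = 2L) {
    .stopIfNot(procStage(x) == "normalized",
               "expected a normalized-stage MetaboSet (fold changes need the raw scale)")
    cd <- as.data.frame(SummarizedExperiment::colData(x))
    .stopIfNot(all(c("age", "bmi") %in% colnames(cd)),
               "colData needs age and bmi covariates")
    group <- factor(as.character(group), levels = c("control", "case"))
    .stopIfNot(!anyNA(group), "group labels must be 'case' or 'control'")
    m <- intensities(x)
    lm_ <- lapply(rownames(m), function(id)
        lmGroupContrast(log(m[id, ]), group, cd$age, cd$bmi, yRaw = m[id, ]))
    fit <- fitPLSDA(t(log(m)), group, nComponents = nComponents)
    v <- vip(fit)
    p <- vapply(lm_, `[[`, numeric(1), "p")
    fc <- vapply(lm_, `[[`, numeric(1), "fc")
    data.frame(id = rownames(m), vip = unname(v[rownames(m)]),
               estimate = vapply(lm_, `[[`, numeric(1), "estimate"),
               p = p, padj = adjustP(p), fc = fc,
               direction = ifelse(fc >= 1, "up", "down"),
               selected = applySelectionRule(v[rownames(m)], p, rule),
               stringsAsFactors = FALSE)
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps every observed score threshold, computing the false and true
#' positive rates, and integrates by the trapezoid rule.  The AUC is
#' invariant under strictly monotone transforms of the scores.
#'
#' @param scores numeric scores, higher = more case-like.
#' @param labels factor/character, `"case"` positive.
#' @param positive positive class label (default `"case"`).
#' @return a list with `roc` (data.frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
rocCurve <- function(scores, labels, positive = "case") {
    pos <- as.character(labels) == positive
    .stopIfNot(any(pos) && any(!pos), "need both classes to compute a ROC")
    th <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
    tpr <- vapply(th, function(t) mean(scores[pos] >= t), numeric(1))
    fpr <- vapply(th, function(t) mean(scores[!pos] >= t), numeric(1))
    auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
    list(roc = data.frame(threshold = th, fpr = fpr, tpr = tpr), auc = auc)
}

#' Random-forest case/control discrimination
#'
#' Stratified 70/30 split into training and validation sets, a
#' [randomForest::randomForest] of `nTrees` trees on the training set,
#' validation scores = fraction of trees voting "case", ROC/AUC on the
#' held-out validation set only, and feature importance as the forest's
#' out-of-bag permutation mean decrease in accuracy.
#'
#' @param X samples x features matrix (log-scale levels of the selected
#'   metabolites).
#' @param labels factor/character per sample, `"case"`/`"control"`.
#' @param trainFraction training share (default 0.7).
#' @param nTrees forest size (default 1000).
#' @param seed RNG seed (split and forest).
#' @return a [ClassifierReport-class] object.
#' @export
trainRF <- function(X, labels, trainFraction = 0.7, nTrees = 1000L,
                    seed = 1L) {
    X <- as.matrix(X)
    labels <- factor(as.character(labels), levels = c("control", "case"))
    .stopIfNot(!anyNA(labels), "labels must be 'case' or 'control'")
    .stopIfNot(all(table(labels) >= 2L), "need >= 2 samples per class")
    set.seed(seed)
    trainIdx <- sort(unlist(lapply(levels(labels), function(lv) {
        idx <- which(labels == lv)
        sample(idx, round(trainFraction * length(idx)))
    })))
    validIdx <- setdiff(seq_len(nrow(X)), trainIdx)
    .stopIfNot(all(table(labels[trainIdx]) >= 1L) &&
               all(table(labels[validIdx]) >= 1L),
               "a class is absent from a partition; adjust trainFraction")
    rf <- randomForest::randomForest(x = X[trainIdx, , drop = FALSE],
                                     y = labels[trainIdx],
                                     ntree = nTrees, importance = TRUE)
    scores <- predict(rf, X[validIdx, , drop = FALSE],
                      type = "prob")[, "case"]
    rc <- rocCurve(scores, labels[validIdx])
    imp <- rf$importance[, "MeanDecreaseAccuracy"]
    impSd <- rf$importanceSD[, "MeanDecreaseAccuracy"]
    new("ClassifierReport", trainIdx = as.integer(trainIdx),
        validIdx = as.integer(validIdx),
        scores = setNames(scores, rownames(X)[validIdx]),
        roc = rc$roc, auc = rc$auc,
        importance = setNames(imp, colnames(X)),
        importanceSd = setNames(impSd, colnames(X)),
        nTrees = as.integer(nTrees), seed = as.integer(seed))
}

#' Random-forest discrimination report
#'
#' Train/validation index sets, per-sample validation scores, ROC points,
#' AUC, and the per-feature out-of-bag permutation importance (mean decrease
#' in accuracy) with its between-tree SE.
#'
#' @name ClassifierReport-class
#' @aliases ClassifierReport
#' @export
setClass("ClassifierReport", representation(
    trainIdx = "integer", validIdx = "integer", scores = "numeric",
    roc = "data.frame", auc = "numeric", importance = "numeric",
    importanceSd = "numeric", nTrees = "integer", seed = "integer"))

setValidity("ClassifierReport", function(object) {
    if (length(intersect(object@trainIdx, object@validIdx)))
        return("train and validation sets overlap")
    if (object@auc < 0 || object@auc > 1) return("AUC must be in [0, 1]")
    TRUE
})

setMethod("show", "ClassifierReport", function(object) {
    cat(sprintf("ClassifierReport: %d trees, %d train / %d validation samples\n",
                object@nTrees, length(object@trainIdx),
                length(object@validIdx)))
    cat(sprintf("  validation AUC: %.3f\n", object@auc))
    top <- sort(object@importance, decreasing = TRUE)
    cat("  top importance:",
        paste(names(head(top, 5)), collapse = ", "), "\n")
})

#' @describeIn ClassifierReport-class top-k importance table (mean decrease
#'   in accuracy, descending).
#' @param report a `ClassifierReport`.
#' @param k number of features (default 30).
#' @export
topImportance <- function(report, k = 30L) {
    ord <- order(-report@importance)
    head(data.frame(id = names(report@importance)[ord],
                    meanDecreaseAccuracy = unname(report@importance[ord]),
                    se = unname(report@importanceSd[ord])), k)
}
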