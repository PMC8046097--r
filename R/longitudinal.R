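#' Baseline-ratio response matrix
#'
#' Reduces the longitudinal design to per-subject responses: the level of
#' each metabolite at a follow-up time divided by the same subject's
#' baseline (month 0) level.  Subjects lacking a baseline sample, or (by
#' default) any required follow-up sample, are excluded and listed in the
#' metadata, mirroring the usual handling of incomplete serum series.
#'
#' @param x a normalized-stage [MetaboSet] whose `colData` has `subject`,
#'   `arm` and `time` columns, with baseline time 0.
#' @param requireComplete exclude subjects missing any time point (default
#'   `TRUE`); if `FALSE` only a baseline is required.
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay
#'   `"ratio"` (metabolites x subject-time responses, follow-up times only),
#'   `colData` columns `subject`, `arm`, `time`, and
#'   `metadata()$excludedSubjects`.
#' @export
computeResponses <- function(x, requireComplete = TRUE) {
    cd <- as.data.frame(SummarizedExperiment::colData(x))
    .stopIfNot(all(c("subject", "arm", "time") %in% colnames(cd)),
               "colData needs subject, arm and time columns")
    .stopIfNot(procStage(x) %in% c("normalized", "filtered"),
               "responses are computed on the normalized (non-log) matrix")
    times <- sort(unique(cd$time))
    .stopIfNot(times[1] == 0, "baseline time 0 is required")
    followUp <- times[-1]
    have <- table(cd$subject, cd$time)
    subjects <- rownames(have)
    complete <- if (requireComplete) rowSums(have > 0) == length(times)
                else have[, "0"] > 0
    excluded <- subjects[!complete]
    subjects <- subjects[complete]
    .stopIfNot(length(subjects) > 0, "no subject has a complete series")
    if (length(excluded))
        message(sprintf("excluding %d subject(s) with incomplete series: %s",
                        length(excluded), paste(excluded, collapse = ", ")))

    m <- intensities(x)
    cols <- list(); meta <- list()
    for (s in subjects) {
        b <- which(cd$subject == s & cd$time == 0)[1]
        for (t in followUp) {
            j <- which(cd$subject == s & cd$time == t)
            if (length(j) == 0) next
            cols[[paste0(s, "_t", t)]] <- m[, j[1]] / m[, b]
            meta[[paste0(s, "_t", t)]] <-
                data.frame(subject = s, arm = cd$arm[b], time = t)
        }
    }
    ratio <- do.call(cbind, cols)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(ratio = ratio),
        colData = do.call(rbind, meta))
    S4Vectors::metadata(se)$excludedSubjects <- excluded
    se
}

#' Dual-criterion selection rule
#'
#' @param vipThreshold select when VIP is strictly above this (default 1).
#' @param pThreshold and the rank-sum p is strictly below this (default
#'   0.05).
#' @return a list rule object.
#' @export
selectionRule <- function(vipThreshold = 1, pThreshold = 0.05) {
    .stopIfNot(vipThreshold >= 0 && pThreshold > 0 && pThreshold <= 1,
               "invalid thresholds")
    list(vipThreshold = vipThreshold, pThreshold = pThreshold)
}

#' @rdname selectionRule
#' @param vip,p vectors of VIP scores and p-values.
#' @param rule a `selectionRule()`.
#' @return `applySelectionRule()`: logical vector, `TRUE` iff
#'   `vip > vipThreshold & p < pThreshold` (conjunction; `NA`-safe).
#' @export
applySelectionRule <- function(vip, p, rule = selectionRule()) {
    sel <- vip > rule$vipThreshold & p < rule$pThreshold
    sel[is.na(sel)] <- FALSE
    sel
}

#' Differentially responding metabolites at one follow-up time
#'
#' At the given follow-up time, each metabolite's treatment-arm response
#' ratios are compared with the placebo-arm ratios by the two-tailed
#' Wilcoxon rank-sum test, and VIP scores are taken from a PLS-DA fitted on
#' the log-ratio matrix (arms as classes).  A metabolite is selected iff
#' VIP > `vipThreshold` AND p < `pThreshold`; BH-adjusted p-values are
#' reported alongside.  Metabolites that are constant across samples at this
#' time are excluded from the PLS fit and flagged.
#'
#' @param responses output of [computeResponses()].
#' @param time follow-up time point (month).
#' @param rule a [selectionRule()].
#' @param nComponents PLS-DA components (default 2).
#' @return a `data.frame` (one row per metabolite): `id`, `time`,
#'   `statistic`, `p`, `padj`, `vip`, `direction` (`"up"` if the treatment
#'   median ratio exceeds placebo), `selected`, `flag`.
#' @export
selectDifferential <- function(responses, time, rule = selectionRule(),
                               nComponents = 2L) {
    cd <- as.data.frame(SummarizedExperiment::colData(responses))
    keep <- cd$time == time
    .stopIfNot(any(keep), "no samples at time %s", format(time))
    arm <- factor(cd$arm[keep])
    .stopIfNot(nlevels(arm) == 2L, "both arms must be present at time %s",
               format(time))
    r <- SummarizedExperiment::assay(responses, "ratio")[, keep, drop = FALSE]
    trt <- arm == "treatment"

    ids <- rownames(r)
    stat <- p <- rep(NA_real_, length(ids))
    direction <- rep(NA_character_, length(ids))
    constant <- apply(r, 1, function(v) sd(v) == 0)
    for (i in which(!constant)) {
        ht <- rankSum(r[i, trt], r[i, !trt])
        stat[i] <- ht$statistic; p[i] <- ht$p
        direction[i] <- if (median(r[i, trt]) >= median(r[i, !trt])) "up" else "down"
    }
    vipScores <- rep(NA_real_, length(ids))
    X <- t(log(r[!constant, , drop = FALSE]))
    fit <- fitPLSDA(X, arm, nComponents = min(nComponents, nrow(X) - 1L,
                                              ncol(X)))
    vipScores[!constant] <- vip(fit)
    data.frame(id = ids, time = time, statistic = stat, p = p,
               padj = adjustP(p), vip = vipScores, direction = direction,
               selected = applySelectionRule(vipScores, p, rule),
               flag = ifelse(constant, "constant", ""),
               stringsAsFactors = FALSE)
}

#' Selection across all follow-up times, with per-time membership
#'
#' Runs [selectDifferential()] at every follow-up time and reports the
#' union of selected metabolites together with the per-time membership
#' matrix (the Venn structure of which metabolites respond at one, two or
#' three follow-up times).
#'
#' @inheritParams selectDifferential
#' @return a list with `tables` (per-time data.frames), `membership`
#'   (logical metabolites x times matrix), `unionIds`, and `timesSelected`
#'   (named count of times each union metabolite was selected).
#' @export
selectDifferentialAllTimes <- function(responses, rule = selectionRule(),
                                       nComponents = 2L) {
    cd <- as.data.frame(SummarizedExperiment::colData(responses))
    times <- sort(unique(cd$time))
    tables <- lapply(times, function(t)
        selectDifferential(responses, t, rule, nComponents))
    names(tables) <- paste0("t", times)
    membership <- do.call(cbind, lapply(tables, function(tb)
        setNames(tb$selected, tb$id)))
    colnames(membership) <- names(tables)
    unionIds <- rownames(membership)[rowSums(membership) > 0]
    list(tables = tables, membership = membership, unionIds = unionIds,
         timesSelected = rowSums(membership)[unionIds])
}

#' Cluster selected metabolites by response pattern (DIANA)
#'
#' Each metabolite is summarized by its mean response profile over
#' arm-by-time cells (2 arms x follow-up times), and divisive hierarchical
#' clustering ([cluster::diana]) is run on the correlation distance
#' `1 - Pearson r` between profiles.  By default the tree is cut at the
#' height that maximizes the number of retained clusters (clusters of at
#' least `minClusterSize` members), preferring the coarser cut on ties, so
#' the cluster count is data-driven; an explicit `cutHeight` overrides this.
#' Clusters smaller than `minClusterSize` are discarded (members become
#' unassigned, `NA`).  Metabolites are processed in id order so the result
#' does not depend on input order.  The divisive coefficient of the tree is
#' reported.
#'
#' @param responses output of [computeResponses()].
#' @param ids metabolites to cluster (e.g. the selection union).
#' @param minClusterSize discard clusters smaller than this (default 10).
#' @param cutHeight optional explicit cut height on the correlation-distance
#'   dendrogram; default: retained-cluster-maximizing height.
#' @return a list with `assignment` (named cluster label or `NA`), `sizes`
#'   (retained cluster sizes), `divisiveCoefficient`, `cutHeight`, `tree`
#'   (the `diana` object) and `profiles` (the matrix clustered).
#' @export
clusterResponses <- function(responses, ids, minClusterSize = 10L,
                             cutHeight = NULL) {
    ids <- sort(unique(ids))
    if (length(ids) < minClusterSize) {
        warning("fewer metabolites than minClusterSize; nothing to cluster")
        return(list(assignment = setNames(rep(NA_integer_, length(ids)), ids),
                    sizes = integer(0), divisiveCoefficient = NA_real_,
                    cutHeight = NA_real_, tree = NULL, profiles = NULL))
    }
    cd <- as.data.frame(SummarizedExperiment::colData(responses))
    r <- SummarizedExperiment::assay(responses, "ratio")[ids, , drop = FALSE]
    cell <- interaction(cd$arm, cd$time, drop = TRUE)
    profiles <- t(apply(r, 1, function(v) tapply(v, cell, mean)))
    d <- as.dist(1 - cor(t(profiles)))
    tree <- cluster::diana(d, diss = TRUE)
    hc <- as.hclust(tree)
    if (is.null(cutHeight)) {
        hts <- sort(unique(hc$height))
        cand <- c((c(0, hts) + c(hts, max(hts) + 1)) / 2)
        retained <- vapply(cand, function(h)
            sum(table(cutree(hc, h = h)) >= minClusterSize), integer(1))
        cutHeight <- max(cand[retained == max(retained)])
    }
    raw <- cutree(hc, h = cutHeight)
    sizes <- table(raw)
    kept <- names(sizes)[sizes >= minClusterSize]
    assignment <- ifelse(raw %in% kept, match(raw, kept), NA_integer_)
    names(assignment) <- ids
    list(assignment = assignment,
         sizes = setNames(as.integer(sizes[kept]), seq_along(kept)),
         divisiveCoefficient = tree$dc, cutHeight = cutHeight, tree = tree,
         profiles = profiles)
}

#' Euclidean distances between arm-by-time mean profiles
#'
#' Averages the log-scale metabolite profile within each arm-by-time cell,
#' computes all pairwise Euclidean distances and orders the cells by
#' average-linkage hierarchical clustering (the heatmap view of how the two
#' arms relate at baseline and during follow-up).
#'
#' @param x a log-stage [MetaboSet] with `subject`, `arm`, `time` columns.
#' @return a list with `dist` (symmetric matrix, zero diagonal), `hclust`
#'   and `order` (cell labels in dendrogram order).
#' @export
groupTimeDistance <- function(x) {
    .stopIfNot(procStage(x) == "log", "expected a log-stage MetaboSet")
    cd <- as.data.frame(SummarizedExperiment::colData(x))
    cell <- interaction(cd$arm, cd$time, drop = TRUE, sep = "_m")
    .stopIfNot(nlevels(cell) >= 2L, "need at least 2 arm-by-time cells")
    empty <- setdiff(levels(cell), unique(as.character(cell)))
    .stopIfNot(length(empty) == 0L, "empty arm-by-time cell(s): %s",
               paste(empty, collapse = ", "))
    m <- intensities(x)
    prof <- sapply(levels(cell), function(cl)
        rowMeans(m[, cell == cl, drop = FALSE]))
    D <- as.matrix(dist(t(prof)))
    hc <- hclust(as.dist(D), method = "average")
    list(dist = D, hclust = hc, order = colnames(D)[hc$order])
}

#' Within-arm paired time-course screen
#'
#' For one arm, compares every pair of time points metabolite-by-metabolite
#' with the paired Wilcoxon signed-rank test on log levels, adjusts by BH
#' within each comparison, and counts metabolites up/down at adjusted
#' p below `alpha` (direction by the median paired difference).
#'
#' @param x a log-stage [MetaboSet] with `subject`, `arm`, `time` columns.
#' @param arm arm to analyze.
#' @param alpha adjusted-p cutoff for the significance counts (default 0.1).
#' @return a list with `table` (per metabolite x comparison: `id`,
#'   `comparison`, `statistic`, `p`, `padj`, `direction`) and `counts`
#'   (per comparison: `n`, `up`, `down`).
#' @export
withinArmTimeCourse <- function(x, arm, alpha = 0.1) {
    .stopIfNot(procStage(x) == "log", "expected a log-stage MetaboSet")
    cd <- as.data.frame(SummarizedExperiment::colData(x))
    cd$col <- seq_len(nrow(cd))
    cd <- cd[cd$arm == arm, ]
    .stopIfNot(nrow(cd) > 0, "no samples in arm '%s'", arm)
    times <- sort(unique(cd$time))
    m <- intensities(x)
    rows <- list(); counts <- list()
    for (i in seq_along(times)[-length(times)]) for (j in (i + 1):length(times)) {
        t1 <- times[i]; t2 <- times[j]
        s1 <- cd[cd$time == t1, ]; s2 <- cd[cd$time == t2, ]
        shared <- intersect(s1$subject, s2$subject)
        cmpName <- sprintf("m%g_vs_m%g", t1, t2)
        if (length(shared) < 2L) {
            message("skipping ", cmpName, ": fewer than 2 complete pairs")
            next
        }
        c1 <- s1$col[match(shared, s1$subject)]
        c2 <- s2$col[match(shared, s2$subject)]
        res <- apply(m, 1, function(v) {
            ht <- suppressWarnings(signedRank(v[c1], v[c2]))
            c(ht$statistic, ht$p, median(v[c2] - v[c1]))
        })
        tab <- data.frame(id = rownames(m), comparison = cmpName,
                          statistic = res[1, ], p = res[2, ],
                          padj = adjustP(res[2, ]),
                          direction = ifelse(res[3, ] >= 0, "up", "down"),
                          stringsAsFactors = FALSE)
        sig <- tab$padj < alpha
        counts[[cmpName]] <- data.frame(
            comparison = cmpName, n = sum(sig),
            up = sum(sig & tab$direction == "up"),
            down = sum(sig & tab$direction == "down"))
        rows[[cmpName]] <- tab
    }
    list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
         counts = do.call(rbind, c(counts, list(make.row.names = FALSE))))
}
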