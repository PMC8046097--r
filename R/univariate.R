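#' Two-tailed Wilcoxon rank-sum test
#'
#' Thin, policy-carrying wrapper around [stats::wilcox.test()]: the exact
#' null distribution is used when both groups have at most 12 observations
#' and there are no ties; otherwise the normal approximation with tie and
#' continuity correction is used.  The branch taken is recorded in the
#' result.
#'
#' @param a,b numeric vectors (each length >= 2).
#' @param exact override the automatic exact/approximate choice.
#' @return a list with `statistic` (W), `p`, `exact` and `method = "ranksum"`.
#' @examples
#' rankSum(c(1, 2), c(3, 4))$p   # 1/3 by exact enumeration
#' @export
rankSum <- function(a, b, exact = NULL) {
    .stopIfNot(length(a) >= 2L && length(b) >= 2L,
               "each group needs at least 2 observations")
    ties <- anyDuplicated(c(a, b)) > 0L
    if (is.null(exact)) exact <- length(a) <= 12L && length(b) <= 12L && !ties
    ht <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = TRUE,
                                       alternative = "two.sided"))
    list(statistic = unname(ht$statistic), p = ht$p.value,
         exact = exact && !ties, method = "ranksum")
}

#' Two-tailed Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped (standard Wilcoxon convention; the count is
#' reported).  Exact when at most 15 non-zero differences without tied
#' absolute values, otherwise normal approximation with corrections.  If all
#' differences are zero, `p = 1` with a warning.
#'
#' @param before,after paired numeric vectors of equal length.
#' @param exact override the automatic choice.
#' @return a list with `statistic` (V), `p`, `exact`, `nZero` and
#'   `method = "signedrank"`.
#' @export
signedRank <- function(before, after, exact = NULL) {
    .stopIfNot(length(before) == length(after), "paired vectors must have equal length")
    d <- after - before
    nZero <- sum(d == 0)
    d <- d[d != 0]
    if (length(d) == 0L) {
        warning("all paired differences are zero; p = 1")
        return(list(statistic = NA_real_, p = 1, exact = TRUE, nZero = nZero,
                    method = "signedrank"))
    }
    .stopIfNot(length(d) >= 2L, "need >= 2 non-zero differences")
    ties <- anyDuplicated(abs(d)) > 0L
    if (is.null(exact)) exact <- length(d) <= 15L && !ties
    ht <- suppressWarnings(wilcox.test(d, exact = exact, correct = TRUE,
                                       alternative = "two.sided"))
    list(statistic = unname(ht$statistic), p = ht$p.value,
         exact = exact && !ties, nZero = nZero, method = "signedrank")
}

#' Multiple-testing adjustment
#'
#' Benjamini-Hochberg step-up (`"fdr_bh"`) or Bonferroni; both are
#' order-preserving and never smaller than the raw p-value.
#'
#' @param p vector of p-values in \[0, 1\].
#' @param method `"fdr_bh"` (default) or `"bonferroni"`.
#' @return adjusted p-values.
#' @export
adjustP <- function(p, method = c("fdr_bh", "bonferroni")) {
    method <- match.arg(method)
    ok <- is.na(p) | (p >= 0 & p <= 1)
    .stopIfNot(all(ok), "p-values outside [0, 1] at position(s): %s",
               paste(which(!ok), collapse = ", "))
    p.adjust(p, method = if (method == "fdr_bh") "BH" else "bonferroni")
}

#' Covariate-adjusted group contrast with raw-scale fold change
#'
#' Fits ordinary least squares `log level ~ group + age + bmi` and reports
#' the two-sided t-test p-value for the group coefficient.  The fold change
#' is computed separately on the raw (normalized, non-log) scale as
#' mean(case) / mean(control), matching how intervention studies report FC
#' alongside adjusted p-values.
#'
#' @param yLog log-scale metabolite levels, one per subject.
#' @param group factor with levels (control, case) or a character vector
#'   containing `"case"`/`"control"`.
#' @param age,bmi covariates.
#' @param yRaw raw-scale levels for the fold change (default `exp(yLog)`).
#' @return a list with `estimate` (group coefficient on the log scale),
#'   `statistic` (t), `p`, `fc` and `method = "lm_group"`.
#' @export
lmGroupContrast <- function(yLog, group, age, bmi, yRaw = exp(yLog)) {
    group <- factor(group, levels = intersect(c("control", "case"),
                                              unique(as.character(group))))
    if (nlevels(group) != 2L) group <- factor(group)
    .stopIfNot(nlevels(group) == 2L, "group must have exactly 2 levels")
    .stopIfNot(all(table(group) >= 3L), "need >= 3 subjects per group")
    .stopIfNot(all(is.finite(age)) && all(is.finite(bmi)),
               "covariates must be finite")
    fit <- lm(yLog ~ group + age + bmi)
    .stopIfNot(fit$rank == 4L, "rank-deficient design (collinear covariates)")
    sm <- summary(fit)$coefficients
    row <- grep("^group", rownames(sm))
    caseLevel <- levels(group)[2L]
    fc <- mean(yRaw[group == caseLevel]) / mean(yRaw[group != caseLevel])
    list(estimate = sm[row, 1], statistic = sm[row, 3], p = sm[row, 4],
         fc = fc, case = caseLevel, method = "lm_group")
}

#' Pearson correlation screen between metabolites and clinical variables
#'
#' Computes Pearson r and the two-sided p-value for every
#' (metabolite, clinical variable) pair, with Benjamini-Hochberg adjustment
#' across the full grid.  Pairs with a zero-variance member are flagged
#' (`r = NA`) rather than failing the batch.
#'
#' @param m metabolites x samples numeric matrix (log scale).
#' @param clinical data.frame of numeric clinical variables, one row per
#'   sample (aligned with columns of `m`).
#' @return a `data.frame` with columns `id`, `variable`, `n`, `r`, `p`,
#'   `padj`, `flag`.
#' @export
clinicalCorrelations <- function(m, clinical) {
    m <- as.matrix(m)
    .stopIfNot(nrow(clinical) == ncol(m),
               "clinical table must have one row per sample")
    grid <- expand.grid(id = rownames(m), variable = colnames(clinical),
                        stringsAsFactors = FALSE)
    res <- lapply(seq_len(nrow(grid)), function(k) {
        x <- m[grid$id[k], ]
        y <- clinical[[grid$variable[k]]]
        ok <- is.finite(x) & is.finite(y)
        if (sum(ok) < 3L || sd(x[ok]) == 0 || sd(y[ok]) == 0)
            return(data.frame(n = sum(ok), r = NA_real_, p = NA_real_,
                              flag = "degenerate"))
        ct <- cor.test(x[ok], y[ok], method = "pearson")
        data.frame(n = sum(ok), r = unname(ct$estimate), p = ct$p.value,
                   flag = "")
    })
    out <- cbind(grid, do.call(rbind, res))
    out$padj <- adjustP(out$p)
    out[order(out$p), ]
}
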