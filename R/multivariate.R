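#' Two-class PLS-DA fitted by sequential NIPALS extraction
#'
#' Partial least squares discriminant analysis for a two-class design.  The
#' class factor is coded as a single centered 0/1 dummy response (PLS1 — for
#' two classes this is equivalent to the two-column indicator coding and
#' makes the VIP definition unambiguous).  Features are mean-centered and,
#' by default, scaled to unit variance.  Components are extracted
#' sequentially: the weight vector is the (normalized) covariance of the
#' deflated X with the response, scores are the projection, and X is
#' deflated by its loading; successive score vectors are mutually
#' orthogonal.  Sign indeterminacy is resolved by forcing the
#' largest-magnitude entry of each weight vector positive, so fits are
#' bit-for-bit reproducible.
#'
#' @param X numeric matrix, samples x features.
#' @param labels two-level factor (or coercible), one per row of `X`, with at
#'   least two samples per class.
#' @param nComponents number of components (default 2; must not exceed
#'   `min(nrow(X) - 1, ncol(X))`).
#' @param scale scale features to unit variance (default `TRUE`); features
#'   with zero variance are rejected.
#' @return a [PlsModel-class] object.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(60), 10, 6, dimnames = list(NULL, paste0("f", 1:6)))
#' X[1:5, 1] <- X[1:5, 1] + 3
#' fit <- fitPLSDA(X, rep(c("a", "b"), each = 5))
#' head(vip(fit))
#' @export
fitPLSDA <- function(X, labels, nComponents = 2L, scale = TRUE) {
    X <- as.matrix(X)
    labels <- factor(labels)
    .stopIfNot(nlevels(labels) == 2L,
               "labels must have exactly 2 classes (got %d)", nlevels(labels))
    .stopIfNot(all(table(labels) >= 2L), "need at least 2 samples per class")
    .stopIfNot(length(labels) == nrow(X), "labels must match rows of X")
    n <- nrow(X); p <- ncol(X)
    .stopIfNot(nComponents >= 1L && nComponents <= min(n - 1L, p),
               "nComponents must be in [1, min(n-1, p)] = [1, %d]",
               min(n - 1L, p))
    if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(p))

    centers <- colMeans(X)
    scales <- if (scale) apply(X, 2, sd) else rep(1, p)
    zero <- colnames(X)[scales == 0]
    .stopIfNot(length(zero) == 0L, "zero-variance feature(s) rejected: %s",
               paste(head(zero, 5), collapse = ", "))
    Xc <- sweep(sweep(X, 2L, centers), 2L, scales, "/")
    y0 <- as.numeric(labels) - 1
    y <- y0 - mean(y0)
    ssYtotal <- sum(y^2)

    W <- P <- matrix(0, p, nComponents,
                     dimnames = list(colnames(X), NULL))
    Tm <- matrix(0, n, nComponents)
    q <- ssY <- numeric(nComponents)
    Xd <- Xc
    for (a in seq_len(nComponents)) {
        w <- drop(crossprod(Xd, y))
        nw <- sqrt(sum(w^2))
        .stopIfNot(nw > 0, "degenerate component %d: X carries no covariance with the response", a)
        w <- w / nw
        if (w[which.max(abs(w))] < 0) w <- -w
        t <- drop(Xd %*% w)
        tt <- sum(t^2)
        pLoad <- drop(crossprod(Xd, t)) / tt
        qa <- sum(y * t) / tt
        Xd <- Xd - tcrossprod(t, pLoad)
        W[, a] <- w; P[, a] <- pLoad; Tm[, a] <- t
        q[a] <- qa; ssY[a] <- qa^2 * tt
    }
    new("PlsModel", weights = W, loadings = P, scores = Tm, yLoadings = q,
        explainedY = ssY / ssYtotal, centers = centers, scales = scales,
        labels = labels, nComponents = as.integer(nComponents))
}

#' @rdname PlsModel-class
#' @export
setClass("PlsModel", representation(
    weights = "matrix", loadings = "matrix", scores = "matrix",
    yLoadings = "numeric", explainedY = "numeric", centers = "numeric",
    scales = "numeric", labels = "factor", nComponents = "integer"))

#' Fitted PLS-DA model
#'
#' Slots hold the X-weights, X-loadings, X-scores, Y-loadings and
#' per-component explained response variance of a [fitPLSDA()] fit, plus the
#' centering/scaling vectors needed to project new samples
#' ([predictScores()]).  `vip()` extracts variable-importance-in-projection
#' scores.
#'
#' @param object a `PlsModel`.
#' @name PlsModel-class
#' @aliases PlsModel
NULL

setMethod("show", "PlsModel", function(object) {
    cat(sprintf("PlsModel: %d samples x %d features, %d component(s)\n",
                nrow(object@scores), nrow(object@weights),
                object@nComponents))
    cat(sprintf("  explained Y variance: %s\n",
                paste(sprintf("%.3f", object@explainedY), collapse = ", ")))
})

#' @describeIn PlsModel-class VIP scores: for feature j,
#'   `VIP_j = sqrt(p * sum_a SS_a * (w_ja / ||w_a||)^2 / sum_a SS_a)` where
#'   `SS_a` is the response variance explained by component a and p the
#'   feature count.  Mean squared VIP over features is identically 1 (checked
#'   on every call).
#' @export
setMethod("vip", "PlsModel", function(object) {
    ss <- object@explainedY
    .stopIfNot(sum(ss) > 0, "model explains zero response variance; VIP undefined")
    W <- object@weights                       # columns already unit-norm
    p <- nrow(W)
    v <- sqrt(p * drop(W^2 %*% ss) / sum(ss))
    stopifnot(abs(mean(v^2) - 1) < 1e-8)      # algebraic identity
    setNames(v, rownames(W))
})

#' Project new samples onto a fitted PLS-DA model
#'
#' @param model a [PlsModel-class].
#' @param newX samples x features matrix with the training feature columns.
#' @return a list with `scores` (component scores) and `yhat` (predicted
#'   response on the centered-dummy scale; values above 0 favour the second
#'   class level).
#' @export
predictScores <- function(model, newX) {
    newX <- as.matrix(newX)
    if (!is.null(colnames(newX)))
        newX <- newX[, rownames(model@weights), drop = FALSE]
    .stopIfNot(ncol(newX) == nrow(model@weights),
               "newX must carry the %d training features", nrow(model@weights))
    Xc <- sweep(sweep(newX, 2L, model@centers), 2L, model@scales, "/")
    n <- nrow(Xc)
    Tm <- matrix(0, n, model@nComponents)
    yhat <- numeric(n)
    Xd <- Xc
    for (a in seq_len(model@nComponents)) {
        t <- drop(Xd %*% model@weights[, a])
        Xd <- Xd - tcrossprod(t, model@loadings[, a])
        Tm[, a] <- t
        yhat <- yhat + t * model@yLoadings[a]
    }
    list(scores = Tm, yhat = yhat)
}

#' Cross-validated classification accuracy of PLS-DA
#'
#' Stratified k-fold cross-validation; a held-out sample is assigned to the
#' second class level when its predicted centered-dummy response exceeds 0.
#' Used to characterize chance-level performance under label permutation.
#'
#' @inheritParams fitPLSDA
#' @param folds number of folds (default 5).
#' @param seed RNG seed for fold assignment.
#' @return mean held-out accuracy.
#' @export
plsdaCV <- function(X, labels, nComponents = 2L, folds = 5L, seed = 1L) {
    labels <- factor(labels)
    set.seed(seed)
    fold <- integer(length(labels))
    for (lv in levels(labels)) {
        idx <- which(labels == lv)
        fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    correct <- 0L
    for (k in seq_len(folds)) {
        hold <- fold == k
        fit <- fitPLSDA(X[!hold, , drop = FALSE], labels[!hold], nComponents)
        pred <- predictScores(fit, X[hold, , drop = FALSE])$yhat
        predClass <- levels(labels)[(pred > 0) + 1L]
        correct <- correct + sum(predClass == as.character(labels[hold]))
    }
    correct / length(labels)
}

#' Principal components analysis via singular value decomposition
#'
#' Columns are mean-centered (optionally unit-scaled); components are ordered
#' by decreasing variance and signs fixed by the largest-magnitude-loading
#' convention.
#'
#' @param X samples x features matrix with at least 2 samples.
#' @param scale scale columns to unit variance (default `FALSE`).
#' @return a list with `scores`, `loadings`, `varExplained` (fractions,
#'   summing to at most 1) and `sdev`.
#' @export
fitPCA <- function(X, scale = FALSE) {
    X <- as.matrix(X)
    .stopIfNot(nrow(X) >= 2L, "need at least 2 samples")
    centers <- colMeans(X)
    Xc <- sweep(X, 2L, centers)
    if (scale) {
        s <- apply(X, 2, sd)
        .stopIfNot(all(s > 0), "zero-variance feature(s); cannot scale")
        Xc <- sweep(Xc, 2L, s, "/")
    }
    totVar <- sum(Xc^2)
    .stopIfNot(totVar > 0, "degenerate input: all samples identical")
    sv <- svd(Xc)
    keep <- sv$d > sv$d[1] * 1e-12
    d <- sv$d[keep]
    loadings <- sv$v[, keep, drop = FALSE]
    flip <- apply(loadings, 2, function(v) sign(v[which.max(abs(v))]))
    loadings <- sweep(loadings, 2L, flip, "*")
    scores <- sweep(sv$u[, keep, drop = FALSE] %*% diag(d, length(d)),
                    2L, flip, "*")
    rownames(loadings) <- colnames(X)
    list(scores = scores, loadings = loadings,
         varExplained = d^2 / totVar,
         sdev = d / sqrt(nrow(X) - 1))
}
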