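# Independent oracles used by the tests.  These are deliberately coded from
# the textbook definitions, not by calling the package internals.

# Exact two-tailed Wilcoxon rank-sum p by full enumeration of rank
# assignments (no ties assumed): p = 2 * min(P(W <= w), P(W >= w)), capped.
enumRankSumP <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  ranks <- rank(pooled)
  wObs <- sum(ranks[seq_len(na)]) - na * (na + 1) / 2
  combs <- utils::combn(length(pooled), na)
  ws <- apply(combs, 2, function(idx) sum(ranks[idx]) - na * (na + 1) / 2)
  min(1, 2 * min(mean(ws <= wObs), mean(ws >= wObs)))
}

# Exact two-tailed signed-rank p by enumeration of all 2^n sign patterns.
enumSignedRankP <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  vObs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- drop(signs %*% r)
  min(1, 2 * min(mean(vs <= vObs), mean(vs >= vObs)))
}

# Classic iterative two-block NIPALS PLS with a two-column indicator
# response: inner power loop to convergence, X deflated by loadings,
# Y deflated by t c'.  Returns scores/weights/loadings per component.
refNipals <- function(X, labels, ncomp, scale = TRUE) {
  labels <- factor(labels)
  Y <- stats::model.matrix(~ labels - 1)
  Y <- sweep(Y, 2, colMeans(Y))
  Xc <- sweep(X, 2, colMeans(X))
  if (scale) Xc <- sweep(Xc, 2, apply(X, 2, stats::sd), "/")
  W <- P <- matrix(0, ncol(X), ncomp)
  Tm <- matrix(0, nrow(X), ncomp)
  for (a in seq_len(ncomp)) {
    u <- Y[, 1]
    tOld <- rep(0, nrow(X))
    for (it in 1:1000) {
      w <- drop(crossprod(Xc, u)); w <- w / sqrt(sum(w^2))
      t <- drop(Xc %*% w)
      cc <- drop(crossprod(Y, t)) / sum(t^2)
      u <- drop(Y %*% cc) / sum(cc^2)
      if (sum((t - tOld)^2) < 1e-24) break
      tOld <- t
    }
    p <- drop(crossprod(Xc, t)) / sum(t^2)
    Xc <- Xc - tcrossprod(t, p)
    Y <- Y - tcrossprod(t, cc)
    W[, a] <- w; P[, a] <- p; Tm[, a] <- t
  }
  list(weights = W, loadings = P, scores = Tm)
}

# Divisive analysis (Macnaughton-Smith splinter procedure): recursively
# split every cluster whose diameter exceeds the cut height h.  Height-based
# cutting is order-free, so the comparison with cluster::diana is immune to
# the merge-ordering ambiguity of tied split heights.
refDianaCut <- function(D, h) {
  D <- as.matrix(D)
  n <- nrow(D)
  clusters <- list(seq_len(n))
  diam <- function(idx) if (length(idx) < 2) 0 else max(D[idx, idx])
  repeat {
    ds <- vapply(clusters, diam, numeric(1))
    if (all(ds <= h)) break
    ci <- which.max(ds)
    idx <- clusters[[ci]]
    avg <- vapply(idx, function(i) mean(D[i, setdiff(idx, i)]), numeric(1))
    B <- idx[which.max(avg)]
    A <- setdiff(idx, B)
    while (length(A) > 1) {
      gain <- vapply(A, function(i)
        mean(D[i, setdiff(A, i)]) - mean(D[i, B]), numeric(1))
      if (max(gain) <= 0) break
      mv <- A[which.max(gain)]
      A <- setdiff(A, mv); B <- c(B, mv)
    }
    clusters[[ci]] <- A
    clusters[[length(clusters) + 1L]] <- B
  }
  part <- integer(n)
  for (i in seq_along(clusters)) part[clusters[[i]]] <- i
  part
}

# Compare cluster::diana topology with the reference at the three coarsest
# well-defined cut heights of an instance.
dianaTopologyMatches <- function(D) {
  hc <- as.hclust(cluster::diana(D, diss = TRUE))
  hts <- sort(unique(hc$height), decreasing = TRUE)
  cuts <- (hts[1:3] + hts[2:4]) / 2
  all(vapply(cuts, function(h)
    samePartition(cutree(hc, h = h), refDianaCut(D, h)), logical(1)))
}

samePartition <- function(p1, p2) {
  tab <- table(p1, p2)
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}

# An age-confounded case set plus control pool for matching tests.
.confoundedPool <- function(seed, nCase = 40, nPool = 200, shift = 1.0) {
  set.seed(seed)
  n <- nCase + nPool
  sd <- data.frame(age = c(rnorm(nCase, 78 + shift, 1.5),
                           rnorm(nPool, 78, 1.5)),
                   height = rnorm(n, 162, 6), weight = rnorm(n, 65, 8),
                   bmi = rnorm(n, 24.4, 3.6),
                   row.names = sprintf("S%03d", 1:n))
  list(sd = sd, cases = rownames(sd)[1:nCase],
       pool = rownames(sd)[-(1:nCase)])
}

# Small MetaboSet builder for hand-crafted fixtures.
makeMset <- function(m, subject = NULL, arm = NULL, time = NULL,
                     stage = "raw", ...) {
  cd <- data.frame(row.names = colnames(m), ...)
  if (!is.null(subject)) cd$subject <- subject
  if (!is.null(arm)) cd$arm <- arm
  if (!is.null(time)) cd$time <- time
  MetaboSet(m, cd, stage = stage)
}

# A baseline-ratio response container with four planted mean-response
# archetypes in the treatment arm (down-then-recover, peak at month 6,
# dip at month 3, monotone diverging); placebo flat at ratio 1.
archetypeResponses <- function(nPer = 12, nSubj = 15, noiseSd = 0.05,
                               seed = 1) {
  set.seed(seed)
  shapes <- list(A = c(0.3, 0.5, 0.9), B = c(1.0, 2.2, 1.0),
                 C = c(0.45, 1.0, 1.05), D = c(1.5, 2.0, 2.7))
  times <- c(3, 6, 12)
  subjects <- c(sprintf("T%02d", 1:nSubj), sprintf("P%02d", 1:nSubj))
  arm <- rep(c("treatment", "placebo"), each = nSubj)
  cols <- as.vector(outer(subjects, times, paste, sep = "_t"))
  cd <- data.frame(subject = rep(subjects, length(times)),
                   arm = rep(arm, length(times)),
                   time = rep(times, each = 2 * nSubj),
                   row.names = cols)
  nm <- nPer * length(shapes)
  ids <- sprintf("A%03d", seq_len(nm))
  truth <- rep(names(shapes), each = nPer)
  ratio <- matrix(NA_real_, nm, length(cols), dimnames = list(ids, cols))
  for (j in seq_along(cols)) {
    tIdx <- match(cd$time[j], times)
    trt <- cd$arm[j] == "treatment"
    mu <- vapply(truth, function(s) if (trt) shapes[[s]][tIdx] else 1,
                 numeric(1))
    ratio[, j] <- mu * exp(rnorm(nm, 0, noiseSd))
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(ratio = ratio), colData = cd)
  list(responses = se, truth = setNames(truth, ids))
}
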