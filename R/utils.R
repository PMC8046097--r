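## Deterministic per-stage seed substreams: one user seed in a pipeline run,
## hashed with the stage name so toggling one stochastic stage does not
## perturb another's draws.  Kept inside 32-bit integer range.
stageSeed <- function(seed, stage) {
    h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
    as.integer((as.numeric(seed) * 1009 + h) %% 2147483647)
}

## Standardized mean difference between two covariate vectors (pooled SD).
smd <- function(a, b) {
    s <- sqrt((stats::var(a) + stats::var(b)) / 2)
    if (s == 0) return(0)
    abs(mean(a) - mean(b)) / s
}

.stopIfNot <- function(cond, fmt, ...) {
    if (!cond) stop(sprintf(fmt, ...), call. = FALSE)
}
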