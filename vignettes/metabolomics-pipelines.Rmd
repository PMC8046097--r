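---
title: "Serum metabolomics pipelines for intervention trials and BMD case-control cohorts"
author: "metaBMD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serum metabolomics pipelines for intervention trials and BMD case-control cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaBMD)
```

# Scope

`metaBMD` implements two linked analyses of untargeted LC-MS serum
metabolomics in elderly women:

1. a **randomized probiotic intervention trial** — two arms sampled at
   months 0, 3, 6 and 12, analyzed through per-subject baseline ratios,
   dual-criterion (VIP and rank-sum p) selection of differentially
   responding metabolites, and divisive clustering of response patterns; and
2. an **extreme-phenotype case-control cohort** — the lowest- and
   highest-tibia-vBMD extremes of a screening population, propensity-matched
   on age, height, weight and BMI, analyzed with covariate-adjusted linear
   contrasts, PLS-DA VIP selection, and a random-forest classifier scored by
   held-out ROC/AUC.

Everything upstream of the peak-intensity matrix (acquisition, peak
identification, platform QC) is out of scope; pathway definitions are
user-supplied input files, never fetched.

# The data container and stage discipline

`MetaboSet` (metabolites x samples) extends `SummarizedExperiment` with a
processing-stage tag and a frozen record of the original missingness
pattern.  The chain `raw -> imputed -> filtered -> normalized -> log` is a
one-way state machine: each stage function checks the tag, so it is
impossible to, say, log-transform before normalizing or filter on
post-imputation "missingness" (after imputation nothing is missing — the
filter must consult the original mask, which is why the mask is stored
at construction and never updated).

# Preprocessing

**Left-censored imputation.**  Missingness in untargeted LC-MS is
concentrated at low abundance (detection-limit censoring), so missing cells
are drawn from a normal distribution shifted below the observed one: within
a scope unit with observed log-intensity mean $\mu$ and SD $\sigma$,
imputed values are $\exp\!\big(N(\mu - 2.5\sigma,\ (0.5\sigma)^2)\big)$.
The width factor 0.5 and down-shift 2.5 are the conventional settings for
this family of imputations and are the package defaults.  Choices we had to
make where the convention is silent:

* *Scope*: "the SD of all measured values" is ambiguous; the default is
  **per sample** (the standard down-shift practice), with
  `per_metabolite` and `global` available and the scope echoed in logs.
* *Scale*: moments are estimated and draws made on the **log** scale, then
  exponentiated.  A down-shifted normal on raw peak areas could produce
  negative intensities; the log-scale version preserves positivity by
  construction.  A clip floor (smallest observed positive intensity
  times $10^{-3}$) guards the residual lower tail.
* Imputation never touches observed cells; the mask records what was drawn.

**Missingness filter.**  Metabolites with **strictly less than 25%**
missing values across all samples are retained; a metabolite missing in
exactly 2 of 8 samples (25%) is dropped.  The fraction is computed on the
pre-imputation mask.

**Total-intensity normalization.**  Assuming equal total intensity per
serum sample (differences reflect sample volume), the correction factor of
sample $i$ is $f_i = T_i / \min_j T_j$ and every cell of sample $i$ is
divided by $f_i$.  Consequences that the tests assert: all post-normalization
totals equal the minimum original total (relative tolerance $10^{-10}$),
all factors are $\ge 1$ with at least one exactly 1, and within-sample
ratios are unchanged.  Natural-log transformation follows; linear models
and PLS-DA always run on the log scale.

# PLS-DA and VIP

The selection engine is a from-scratch sequential (NIPALS-style) partial
least squares discriminant analysis.  For two classes the response is a
single centered 0/1 dummy (PLS1) — equivalent to the two-column indicator
coding but with an unambiguous VIP definition.  Features are mean-centered
and unit-variance scaled (the cited implementation's default; configurable).
Per component $a$: weight $w_a \propto X_a^\top y$ (unit norm), scores
$t_a = X_a w_a$, X-loading $p_a = X_a^\top t_a / t_a^\top t_a$, deflation
$X_{a+1} = X_a - t_a p_a^\top$.  Two components are fitted by default
(the conventional default; the trial analyses do not specify a count).
Sign indeterminacy is resolved by forcing the largest-magnitude weight
entry positive, so fits are bit-for-bit reproducible.

Variable importance in projection:
$$\mathrm{VIP}_j = \sqrt{p \cdot \frac{\sum_a SS_a\,(w_{ja}/\lVert w_a\rVert)^2}{\sum_a SS_a}},$$
with $SS_a$ the response variance explained by component $a$ and $p$ the
feature count.  The algebraic identity $\mathrm{mean}(\mathrm{VIP}^2) = 1$
is asserted on every call.  PCA (for overview score plots) is computed from
the SVD of the centered matrix and cross-checked in the tests against the
eigendecomposition of the covariance matrix.

# Univariate screens

Rank tests are thin wrappers over `stats::wilcox.test` with an explicit
branch policy: exact null distributions when both groups have $\le 12$
observations (rank-sum) or $\le 15$ non-zero differences (signed-rank) and
no ties; otherwise the normal approximation with tie and continuity
corrections.  The thresholds are desk-enumeration scale — the tests verify
the exact branch against full enumeration and the two branches against each
other at the boundary.  Zero differences are dropped (standard Wilcoxon
convention) and counted.  Multiple testing uses Benjamini–Hochberg (default)
or Bonferroni via `p.adjust`.

Case-control contrasts fit OLS `log level ~ group + age + BMI` and report
the two-sided t-test p for the group coefficient; the fold change is
computed separately as mean(case)/mean(control) on the **raw (normalized,
non-log) scale**, mirroring how intervention studies tabulate FC next to
adjusted p-values.

# Longitudinal analysis

**Baseline ratios.**  The longitudinal design is reduced to
$r_{mst} = x_{mst} / x_{ms0}$ — each metabolite's level at follow-up divided
by the same subject's month-0 level.  Subjects missing any required sample
are excluded (and listed), matching the usual handling of incomplete serum
series.  Because the ratio divides out the subject's baseline, stable
between-subject differences cancel, which is what makes the rank-sum
comparison of ratios between arms well calibrated.

**Dual-criterion selection.**  At each follow-up time a metabolite is
selected iff its PLS-DA VIP (arms as classes, fitted on log-ratios for
scale symmetry) exceeds 1 **and** its two-tailed rank-sum p is below 0.05.
BH-adjusted p-values are reported alongside but do not gate (the
intervention-scale analysis this mirrors used raw p).  The per-time tables,
their union, and the membership pattern (selected at one, two or three
follow-up times) are all reported.  A caution the test suite quantifies: with
a raw p<0.05 gate the expected false-positive count is roughly
$0.05 \times$ (number of null metabolites) per time point, and the VIP
criterion adds little extra stringency under the null, so on
1000-metabolite data with few true responders most selected metabolites are
expected to be false positives.  The suite reports sensitivity ~0.99 and
false-discovery proportion ~0.85 at 20 planted responders in 1000 — the
rule is a high-sensitivity screen, not an FDR-controlled discovery
procedure.

**Response-pattern clustering.**  Selected metabolites are summarized by
their mean response profile over arm-by-time cells and clustered with
divisive analysis (`cluster::diana`) on the correlation distance
$1 - r$.  The tree cut was a genuinely open design point: scaling the cut
by $(1-\mathrm{dc})$ (dc = divisive coefficient) collapses for tight,
well-separated clusters (dc $\to$ 1 drives the cut height to 0 and every
profile becomes a singleton).  The default is therefore **data-driven**:
the cut height that maximizes the number of retained clusters (size
$\ge$ 10 by default), preferring the coarser cut on ties; `cutHeight` is an
explicit override and the divisive coefficient is always reported.
Metabolites are processed in id order, so the result is invariant to input
order.

**Overview analyses.**  Arm-by-time mean log profiles feed a Euclidean
distance matrix with average-linkage ordering (heatmap view), and paired
signed-rank screens within each arm count metabolites changing between any
two time points at BH-adjusted p < 0.1, with direction from the median
paired difference.

# Case-control cohort

**Extreme selection and matching.**  The `n` lowest- and highest-vBMD
subjects are drawn from the screening population (ties broken by id,
logged).  The propensity score is a logistic regression of case status on
age, height, weight and BMI; matching is 1:1 **greedy nearest neighbour on
the logit**, without replacement, processing cases in descending propensity
order.  Greedy-on-logit is the classic default of the matching literature;
optimal matching was not needed for the balance levels the tests require.
Standardized mean differences and two-sample t-test p-values are reported
per covariate before and after matching.

**Differential analysis and classification.**  Selection is the same
VIP > 1 AND p < 0.05 conjunction, with p from the covariate-adjusted linear
model; the fold change gates nothing.  The classifier is a 1000-tree random
forest on a stratified 70/30 split; scores are the fraction of trees voting
"case"; ROC and AUC are computed on the held-out 30% only, by explicit
threshold sweep and trapezoid integration (AUC is invariant to monotone
score transforms and cross-checked against the Mann–Whitney identity and
pROC).  Importance is the forest's out-of-bag **permutation** mean decrease
in accuracy — not impurity decrease, which is biased toward
high-cardinality features and is not what "mean decrease in accuracy"
names.  Whether the split should be stratified and where importance should
come from were unspecified; stratified and OOB are the documented defaults.

# Pathway over-representation

One-sided hypergeometric tails (`phyper`) against a user-supplied GMT file,
BH-adjusted across pathways.  The background defaults to the measured,
filter-surviving metabolites mappable to any pathway — a choice the user
can override, since over-representation p-values are extremely sensitive to
the background universe.  Note the direction of the monotonicities: adding
a pathway *member* to the query can only tighten a pathway's p-value, while
padding the query with non-members dilutes it (raises p); both are asserted
in the tests.  The topology impact of a hit set on a pathway reaction graph
is the hit nodes' share of total betweenness centrality, in [0, 1]; in an
edgeless graph (all centralities zero) the hit fraction of nodes is used so
a full hit set still scores 1.

# The synthetic-data generator

Every stage is verifiable without study data because `simulateRCT()` and
`simulateCohort()` generate data with known ground truth that emulate the
study shape:

* log-normal intensities (base level ~ N(13, 1.5) on the natural-log
  scale, i.e. peak areas around $4\times10^5$), per-subject random effects
  (SD 0.5), residual noise (SD 0.3), and per-sample log scale factors
  (SD 0.2) that total-intensity normalization must remove;
* planted arm-by-time effects (`effectLog2`, random sign) on a chosen set
  of responsive metabolites, treatment arm, follow-up times only;
* **left-censored missingness**: a cell is missing with probability
  logistic in its latent (pre-censoring) log intensity, so the imputation
  model's assumption is literally true in simulation.  The study this
  emulates does not report its missingness mechanism; the logistic
  left-censoring model is an assumption of this package, stated as such;
* a screening cohort (default 3028 subjects, age 78 ± 1.7 y,
  BMI 24.4 ± 3.6 — defaults copied from the emulated population's
  characteristics table, overridable) whose tibia vBMD depends on age, BMI
  and a latent bone-status factor.  Planted marker metabolites co-vary with
  standardized vBMD, scaled by the analytic truncated-normal tail mean for
  the configured selection fractions so the realized case-control log2
  difference after extreme selection is approximately `groupEffectLog2`;
  a `confounderStrength` term ties every metabolite to age and BMI, which
  becomes confounding through the selection on vBMD.

The default trial has 34 subjects per arm (one size per arm by
construction; the emulated trial's 32/36 can be had by simulating the
larger design and dropping subjects), 1232 metabolites and 97 responsive.

What the generator deliberately does **not** emulate: batch structure,
instrument drift, adduct/isotope artifacts, correlated metabolite modules
beyond the planted effects, or non-logistic missingness.  Passing tests
therefore demonstrate correctness of the algorithms under the stated
generative model, not robustness to every artifact of real LC-MS data.

# Numerical choices and problem sizes

* Seeds: R's default Mersenne-Twister; every stochastic stage takes an
  explicit seed.  Pipelines derive per-stage substreams by hashing the run
  seed with the stage name, so toggling one stage never perturbs another's
  draws, and a manifest (seed, thresholds, stage counts) makes every run
  reproducible.
* Exact-test enumeration limits (12 / 15), the imputation clip floor, the
  PLS sign convention, id-ordered tie-breaks in clustering and extreme
  selection: all documented above and asserted in tests.
* The test suite runs at deliberately scaled sizes chosen to keep Monte
  Carlo error well inside the asserted tolerances: selection recovery at
  1000 metabolites x 30/arm over 25 seeds, matching balance over 100
  seeded cohorts, permutation-null forests over 50 seeds at 300 subjects,
  imputation moments from $10^5$ draws, divisive-topology agreement on 20
  fifteen-point instances.

# Known limitations

* The dual-criterion selection controls sensitivity, not FDR (see above);
  downstream biological interpretation should treat the selection as a
  screen.
* The DC-based tree cut of the emulated analysis is not a fully specified
  rule; our data-driven cut reproduces planted archetype structure but is
  not guaranteed to reproduce any particular published cluster count.
* Pathway impact approximates topology analysis with betweenness
  centrality only; relative-degree variants are not implemented.
* Reproducing the emulated study's printed metabolite counts requires its
  supplementary dataset, which is not redistributable here; the pipelines
  reproduce the corresponding counts on synthetic reconstructions instead.
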