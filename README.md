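# metaBMD

Serum metabolomics pipelines for two linked study designs in skeletal
health research: a **randomized probiotic intervention trial** (two arms of
elderly women sampled at months 0, 3, 6, 12) and an **extreme-phenotype
case–control cohort** (the lowest- vs highest-tibia-vBMD women of a
screening population).  The package is for analysts who have an untargeted
LC‑MS peak-intensity matrix (metabolites × samples) plus sample metadata
and want the full chain — preprocessing, differential-response selection,
response-pattern clustering, matching, classification, pathway
over-representation — as tested, reproducible R functions, with a
synthetic-data generator so every stage can be verified against known
ground truth.

## Methods at the core

* **Preprocessing**: left-censored imputation — missing cells drawn from
  `exp(N(μ − 2.5σ, (0.5σ)²))` with μ, σ from observed log intensities per
  sample; strict `< 25%` missingness filter on the *original* mask;
  total-intensity normalization `x_ij / (T_i / min_j T_j)`; natural-log
  transform.  The container (`MetaboSet`, a `SummarizedExperiment`
  extension) enforces the stage order `raw → imputed → filtered →
  normalized → log`.
* **PLS-DA + VIP** (from scratch, NIPALS-style, centered-dummy response):
  per feature *j*,

  VIP_j = √( p · Σ_a SS_a (w_ja/‖w_a‖)² / Σ_a SS_a ),  mean(VIP²) ≡ 1.

* **Longitudinal selection**: per-subject baseline ratios
  `x(t)/x(0)`; a metabolite responds differentially at a follow-up time iff
  **VIP > 1 and two-tailed Wilcoxon rank-sum p < 0.05** (treatment vs
  placebo ratios); divisive (DIANA) clustering of mean response profiles on
  correlation distance, minimum cluster size 10.
* **Case–control**: extreme selection on tibia vBMD; logistic propensity
  scores with 1:1 greedy nearest-neighbour matching on the logit (age,
  height, weight, BMI); OLS `log level ~ group + age + BMI` contrasts with
  raw-scale fold changes; 1000-tree random forest on a stratified 70/30
  split, held-out ROC/AUC by threshold sweep + trapezoid, out-of-bag
  permutation importance (mean decrease in accuracy).
* **Enrichment**: one-sided hypergeometric over-representation against
  user-supplied GMT pathways, BH adjustment, betweenness-centrality
  pathway impact in [0, 1].

See `vignettes/metabolomics-pipelines.Rmd` for the full model description,
parameter defaults and design rationale.

## Worked example

Simulate a trial with 15 planted responders among 300 metabolites, run the
chain, and check recovery:

```r
library(metaBMD)
sim <- simulateRCT(simConfig(nMetabolites = 300, nSubjectsPerArm = 20,
                             nResponsive = 15, effectLog2 = 1.5, seed = 7))
sim$mset
#> MetaboSet: 300 metabolites x 160 samples [stage: raw]
#>   missing cells (original): 5222 (10.9%)

nrm  <- preprocess(sim$mset, seed = 7, log = FALSE)
#> missingness filter: retained 261, dropped 39 (threshold < 0.25)
sel  <- selectDifferentialAllTimes(computeResponses(nrm))
head(sel$tables$t6[order(sel$tables$t6$p),
                   c("id", "p", "padj", "vip", "direction", "selected")], 5)
#>     id            p         padj      vip direction selected
#>  M0116 1.917712e-07 4.547390e-05 3.199568      down     TRUE
#>  M0068 3.938805e-07 4.547390e-05 3.879579      down     TRUE
#>  M0050 5.226885e-07 4.547390e-05 3.623817        up     TRUE
#>  M0080 7.947948e-07 5.186036e-05 3.737365      down     TRUE
#>  M0014 2.689769e-06 1.404059e-04 2.558951      up      TRUE
```

All 11 planted responders that survive the missingness filter are in the
selection union (34 metabolites — the VIP ∧ p rule is a high-sensitivity
screen; expect false positives at raw p < 0.05).

The case–control side, from screening population to classifier:

```r
co  <- simulateCohort(cohortConfig(nPopulation = 600, nCases = 60,
                                   nControls = 150, nMetabolites = 300,
                                   nGroupMarkers = 40, groupEffectLog2 = 0.8,
                                   confounderStrength = 0.2, seed = 7))
out <- runCohortPipeline(co$mset,
                         runConfig(seed = 7, nCases = 60, nControls = 150),
                         "cohort_out")
out$match
#> MatchResult: 60 matched pairs
#>  covariate smdPre    pPre smdPost pPost
#>        age 0.5109 0.00134 0.01882 0.918
#>     height 0.0768 0.61426 0.00778 0.966
#>     weight 0.2077 0.17452 0.13392 0.465
#>        bmi 0.2680 0.08107 0.15319 0.403
out$manifest$counts$selected   # 54 metabolites (34 of the 40 planted markers)
out$manifest$auc               # 1 on the held-out validation set
```

Matching removes the planted age confounding (standardized mean difference
0.51 → 0.019); the planted markers drive a perfectly discriminating forest
at this effect size.  `cohort_out/` contains the differential table, ROC
points, top-30 importance, and a `manifest.json` with seed, thresholds and
stage counts; reruns with the same config are byte-identical.

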