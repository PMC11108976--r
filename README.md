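# scovnet — structural covariance networks of amygdala subnuclei

`scovnet` implements a complete two-group structural covariance analysis
of regional gray-matter volumes, built around the amygdala subnuclei.
Structural covariance treats the inter-subject correlation of regional
volumes as an analog of connectivity: if two regions' volumes co-vary
across people, they are taken to be structurally coupled. The package is
aimed at researchers comparing a clinical group against controls on
subject × region volume tables (e.g. FreeSurfer output), without any
image processing.

## What it computes

Given volumes for 105 regions (63 cortical, 24 subcortical, 18 amygdala
subnuclei — nine per hemisphere, optionally aggregated into the
basolateral (BLA), centromedial (CMA) and superficial (SFA) composite
nuclei) plus age, sex and total brain volume (TBV) covariates:

1. **Covariance profiles.** Volumes are residualized per group on
   age + sex + TBV by OLS; each nucleus gets a profile of 87 Pearson
   correlations against the non-amygdala regions.
2. **Correlation comparisons.** Within a group, two nuclei's
   correlations with the same region are *dependent overlapping*
   correlations; they are compared with the Dunn & Clark statistic

   z = (Z(r₁) − Z(r₂)) · √((n − 3) / (2 − 2c)),

   where Z is Fisher's r-to-z transform and c is the covariance term
   induced by the nuclei's intercorrelation. Between groups the
   independent-samples Fisher z is used. Zou confidence intervals for
   r₁ − r₂ accompany both. Each 87-target family is FDR-adjusted
   (Benjamini–Hochberg), then tested against a Bonferroni threshold for
   the number of subnuclei comparisons (within-group: .05/15 composites,
   .05/153 subnuclei; between-group: .05/6, .05/18).
3. **Graph topology.** Association matrices are binarized by rank at
   densities D_min … 0.50 in 2 % steps, where D_min is the smallest grid
   density connecting both groups' graphs. Per node and density: degree,
   betweenness centrality (raw shortest-path counts) and local
   clustering. Scores are integrated over the sweep (trapezoidal AUC,
   the functional-data-analysis summary); nodes more than 2 SD above the
   group mean on integrated degree or betweenness are hubs.
   Hirschberger–Qi–Steuer (HQS) moment-matched random covariance
   matrices (20 by default) provide a null-topology reference, and group
   differences in integrated metrics are tested by label permutation
   (1000 repetitions) with FDR across nodes and Bonferroni across the
   three measures (p ≤ .05/3).
4. **Volume comparisons.** Per nucleus, OLS of volume on
   group + age + sex + TBV with normal-theory 95 % CIs and Bonferroni
   thresholds (.05/6 composites, .05/18 subnuclei).
5. **Synthetic cohorts.** A generator with known ground truth (group
   sizes 71/67 by default, realistic marginal scales, latent correlation
   targets, injected effects) backs every calibration and recovery test.

## Worked example

Generate a synthetic cohort in which, for cases only, the left BLA
constituents share a latent factor with the left superior temporal
gyrus (STG), then ask which within-case nucleus contrasts survive the
layered correction:

```r
library(scovnet)
reg    <- region_registry()
lib    <- scenario_library(reg)
cohort <- generate_cohort(lib$C_corr_diff, seed = 42)
cohort <- aggregate_composites(cohort, reg)

nodes <- c(profile_targets(reg), analysis_nuclei(reg, "three_nuclei"))
assoc <- lapply(c(control = "control", case = "case"), function(g)
  correlation_matrix(residualize(cohort, g, regions = nodes)))
cmp <- run_profile_comparisons(assoc, reg, "three_nuclei")
subset(cmp$within$case, significant,
       c(nucleus1, nucleus2, region, r1, r2, statistic, p_fdr))
#>     nucleus1  nucleus2                  region   r1     r2 statistic    p_fdr
#> 28  left-bla  left-cma ctx-lh-superiortemporal 0.65 0.0576      5.56 2.39e-06
#> 115 left-bla  left-sfa ctx-lh-superiortemporal 0.65 0.1616      4.53 5.05e-04
#> 202 left-bla right-bla ctx-lh-superiortemporal 0.65 0.1538      4.42 8.49e-04
#> 376 left-bla right-sfa ctx-lh-superiortemporal 0.65 0.1588      4.34 1.21e-03
```

The injected contrast — left BLA covaries with the left STG (r ≈ 0.65)
while the left CMA does not (r ≈ 0.06) — is recovered as a Dunn z of
5.56, FDR-adjusted over the 87 targets and below the .05/15 threshold.

The hub machinery, on a cohort where the right basal nucleus is wired to
much of the cortex in cases:

```r
cohort <- generate_cohort(lib$B_hub, seed = 42)
assoc  <- lapply(c(control = "control", case = "case"), function(g)
  correlation_matrix(residualize(cohort, g, regions = measured_regions(reg))))
d_min  <- find_dmin(assoc$control, assoc$case)   # 0.16 here
grid   <- seq(d_min, 0.5, by = 0.02)
scores <- integrate_metric_curves(sweep_metrics(assoc$case, grid))
detect_hubs(scores, "case")
#>   group   region_id      metric  score group_mean group_sd
#> 1  case right-basal      degree  32.07      11.67    4.816
#> 2  case right-basal betweenness 164.55      12.49   17.313
```

The boosted node is designated a hub on both integrated degree and
betweenness; the control group shows no subnucleus hubs.

`run_pipeline()` chains every stage (QC → adjustment → profiles →
comparisons → graphs → HQS reference → permutation inference → volumes)
and writes per-stage TSVs plus a reproducible JSON manifest; the same
analysis is scriptable via the CLI wrapper in `inst/cli/scovnet`
(`simulate`, `qc`, `adjust`, `covary`, `graph`, `infer`, `volumes`,
`run`).

## Vignette

`vignettes/structural-covariance.Rmd` documents the model, the
statistics, every tunable parameter, what the synthetic generator does
and does not emulate, and the design decisions taken where the
methodology left choices open.
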