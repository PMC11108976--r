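---
title: "Structural covariance networks of amygdala subnuclei: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural covariance networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(scovnet)
```

## The model

Structural covariance analysis treats the correlation, across subjects,
of two regions' gray-matter volumes as evidence of structural coupling.
`scovnet` compares such coupling between amygdala subnuclei and the rest
of the brain, and between a case and a control group. The chain is:

volumes → covariate residualization → group-wise Pearson correlation →
(a) profile comparisons, (b) thresholded graph topology, and separately
(c) covariate-adjusted volume models.

All inference is conditional on three assumptions: volumes are linear in
age, sex and total brain volume (TBV) within group; residual dependence
is adequately summarized by Pearson correlation; and subjects are
exchangeable within group.

## Region inventory

The canonical registry holds 105 analysed regions — 63 cortical,
24 subcortical, 18 amygdala subnuclei — plus six derived composites
(BLA = accessory-basal + basal + lateral + paralaminar; CMA = central +
medial; SFA = anterior-amygdaloid-area + cortico-amygdaloid-transition +
cortical, per hemisphere). The authoritative 87-name target list was
never published, so the shipped registry is a **count-faithful
reconstruction** from standard atlas labels: 31
Desikan–Killiany–Tourville cortical labels per hemisphere plus a left
temporal-pole label (an odd cortical count cannot arise from a symmetric
bilateral atlas, so one asymmetric or midline label must have been
present; we fill the count explicitly and say so), and 24 subcortical
labels (nine bilateral gray structures, brainstem, and the five midline
corpus-callosum segmentation labels). Analyses are keyed by region *id*,
so substituting a corrected registry JSON reruns everything unchanged.

## Correlation comparison statistics

Within one group of size $n$, the correlations of two nuclei $j$ and
$k$ with the same target $h$ are dependent and overlapping. With
$Z(r) = \operatorname{artanh}(r)$, the Dunn & Clark statistic is

$$z = \left(Z(r_{jh}) - Z(r_{kh})\right)\sqrt{\frac{n-3}{2-2c}},$$

where $c$ is the correlation between the two sample correlations,
driven by the nuclei's intercorrelation $r_{jk}$:

$$c = \frac{r_{jk}\,(1 - r_{jh}^2 - r_{kh}^2) - \tfrac12 r_{jh} r_{kh}
(1 - r_{jh}^2 - r_{kh}^2 - r_{jk}^2)}{(1 - r_{jh}^2)(1 - r_{kh}^2)}.$$

Between groups the independent-samples statistic
$z = (Z(r_1)-Z(r_2))/\sqrt{1/(n_1-3)+1/(n_2-3)}$ is used. Both are
two-tailed against the standard normal. Zou confidence intervals for
$r_1 - r_2$ are built from the individual Fisher CIs, with $c$ as the
cross-term coefficient in the dependent case. Of the several dependent
overlapping tests in the literature we implement Dunn & Clark's only —
it has the best size/power trade-off among them — and no bootstrap or
Steiger/Hittner variants.

Decisions where the methodology left room:

* **Effective n.** Test formulas use the subject count, not an
  n-minus-covariates correction, matching standard practice when the
  tests are applied to residualized data (the `cocor` convention).
* **Intercorrelation source.** $r_{jk}$ is taken from the *adjusted*
  correlation matrix, consistent with $r_1$ and $r_2$.
* **FDR family size.** The methods convention adjusts each family over
  its 87 targets; a 105 family size is also supported
  (`fdr_family_size`) because the two conventions coexist in published
  tables. Default: 87.
* **Layering.** `significant` means FDR-adjusted $p \le \alpha/m$ with
  $m$ the subnuclei-comparison count (15/6 for composites, 153/18 for
  subnuclei). Anything significant under the layered rule is
  significant under FDR alone.

## Graph construction and topology

An association matrix is binarized by *rank*: the top
$\lfloor d \cdot p(p-1)/2 + 0.5\rfloor$ pairs by signed correlation
become edges (round-half-up, ties broken lexicographically by region
pair — the methodology specifies neither, and determinism is required
for testability; absolute-value ranking is available as an option).
Rank selection makes edge sets nested across densities. The sweep runs
from $D_{\min}$ — the smallest grid density at which both groups'
graphs are one connected component (breadth-first search) — to 0.50 in
0.02 steps.

Per node and density: degree (row sums), betweenness (raw
shortest-path counts, each unordered endpoint pair counted once;
unnormalized because the quantity of interest is "number of shortest
paths crossing the node"), and local clustering
($2T_v / k_v(k_v-1)$, zero below degree 2). Metrics are integrated over
the sweep by trapezoidal AUC — the functional-data-analysis summary —
before any cross-group comparison, so conclusions do not hinge on one
arbitrary threshold. Hubs are nodes whose integrated degree or
betweenness strictly exceeds the group mean by more than two population
SDs; the rule is applied to integrated rather than per-density scores
because hub designations are reported once per analysis, not per
threshold.

## Null models and permutation inference

Hirschberger–Qi–Steuer null matrices match the observed matrix's
moments: with off-diagonal mean $e$ and variance $v$ and diagonal mean
$\bar d$, a $p \times m$ Gaussian matrix with
$m = \max(2, \operatorname{round}((\bar d^2 - e^2)/v))$, entry mean
$\sqrt{e/m}$ and variance $(\bar d - e)/m$ is multiplied by its
transpose — positive semi-definite by construction. How exactly such
nulls entered the original regional inference is not recoverable; here
they serve as a **diagnostic reference** (observed integrated metrics
tabulated against the null mean ± SD over 20 draws), while group
inference uses label permutation. That division of labor is a documented
package choice, not a reconstruction of intent.

The permutation test (default R = 1000) permutes group labels
*before* covariate adjustment, rerunning residualization → correlation →
sweep → AUC inside every permutation, so the null respects
exchangeability including covariate fitting. The density grid is fixed
at the observed $[D_{\min}, 0.5]$ so AUCs are comparable across
permutations; recomputing $D_{\min}$ per permutation would change the
integration range and invalidate the comparison. Two-tailed p-values use
the add-one rule $(\#\{|z^\ast| \ge |z|\} + 1)/(R+1)$, hence never
reach zero; FDR is applied across nodes within metric and a Bonferroni
factor of 3 across the regional measures (printed threshold
$p \le .02$).

## Volume models

Per nucleus, `lm(volume ~ group + age + sex + tbv)` with normal-theory
95 % CIs and two-tailed p-values; Bonferroni thresholds .05/6
(composites) and .05/18 (subnuclei). Education is deliberately not a
default covariate — its regional effect is understood to be mediated
largely by TBV — but any covariate column present in the cohort table
can be added. Volumes enter untransformed even though real subnuclei
volumes are typically non-normal: the reported effect is the group
coefficient in mm³, and the permutation and rank-based alternatives are
out of scope.

## The synthetic world

Because no subject-level data are distributable, `scenario_library()`
defines the cohorts every test runs on: 71 controls and 67 cases;
age ~ Normal(38, 8) truncated above 18 years; sex ~ Bernoulli(0.72)
(0 = female, 1 = male; the observed cohorts were about three-quarters
female); TBV ~ Normal(1.52 × 10⁶, 1.5 × 10⁵) mm³. Amygdala and
subnuclei marginal means/SDs follow the published volume tables (SD =
IQR/1.349); remaining subcortical scales are standard atlas-typical
values and cortical scales are fixed plausible values between 2.5 and
14 cm³ — chosen once, not tuned. Covariate loadings are −0.3 % of the
regional mean per year of age, +1 % for sex, and proportional TBV
scaling. The latent correlation target blends a block structure
(baseline 0.25; within-hemisphere subnuclei 0.55; subnuclei–ipsilateral
amygdala 0.65; subnuclei–hippocampi 0.40; homologous cortical pairs
0.45) with the identity (λ = 0.3) to guarantee positive definiteness.

Injected effects are built so the stated world is exactly the sampled
world: correlation differences enter as rank-one latent factors
($R + ff^\top$, renormalized — positive definite by construction, and
the realized entries are recorded as ground truth), and the hub
scenario rebuilds one subnucleus latent as a weighted sum of 40
cortical latents plus noise, which produces broad moderate coupling
(r ≈ 0.37–0.43) without making the targets a clique — a clique would
absorb the very shortest paths a betweenness hub needs. Volumes are
floored at 1 mm³ (truncations are counted and reported; at the default
scales they are a handful per hundred-thousand draws, concentrated in
the smallest nuclei).

What the generator does **not** emulate: non-linear covariate effects,
site/scanner structure, non-Gaussian volume distributions, missing
data, or clinical covariates such as trauma type. A green recovery test
therefore establishes that the pipeline detects the effects it claims
to detect under its own model assumptions — not that those assumptions
hold in any particular empirical cohort.

## Calibration and numerical choices

* Quartiles in the IQR quality check use linear interpolation
  (`quantile` type 7); the rule was unstated and this is R's default.
* The QC stage only flags (the original workflow inspected outliers
  visually); automated exclusion is intentionally not a default.
* Residualization uses QR least squares; collinear covariates are a
  hard error naming the dependent column.
* Dunn z inputs are checked for positive semi-definiteness of the
  implied 3 × 3 correlation matrix (tolerance −10⁻¹²).
* Type-I behaviour is verified by the acceptance suite: the Dunn z
  rejects at 4–6 % under a trivariate-normal null (5000 reps, n = 70),
  and the full permutation pipeline at 2–9 % (100 seeds, n = 30 + 30,
  R = 200, 16-node AR(1) networks — node count is reduced for runtime
  and does not affect size; an identity-correlation world is avoided
  because rank-thresholding can leave its weakest node isolated at
  every density, which is a property of the world, not a bug in the
  sweep).
* The calibration/permutation scale-downs (R = 200, 16 nodes) apply to
  the test suite only; pipeline defaults remain R = 1000, 20 nulls,
  2 % steps, D_max = 0.5.
* The CLI accepts JSON configuration (no YAML parser is available in
  the supported dependency set). The `covary`, `graph` and `infer`
  subcommands execute the full pipeline (their stages need every
  upstream product anyway); `simulate`, `qc`, `adjust` and `volumes`
  run their stage alone.

## Known limitations

* The registry's cortical/subcortical naming is a reconstruction; the
  subnuclei layer and all counts are exact, but individual
  cortical/subcortical labels may differ from the original list.
* Only Dunn & Clark's dependent-overlapping test is provided.
* No global network measures (efficiency, small-worldness, modularity)
  and no weighted-graph metrics.
* Permutation inference is AUC-based; pointwise per-density results are
  written for inspection but not separately corrected.
* Printed table values from the motivating study are used solely as
  formula fixtures; they are not reproducible without the original
  subject-level data and the package makes no claim to reproduce them.
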