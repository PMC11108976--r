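# Synthetic morphometry cohorts with known ground truth.
#
# The generator emulates the statistical structure the pipeline assumes:
# two groups (71 controls, 67 cases by default), 105 regional volumes with
# realistic marginal scales, linear age/sex/TBV effects, and group-specific
# latent correlation structure among subnuclei, amygdalae, hippocampi and
# cortex. Amygdala marginals follow the published volume tables; remaining
# marginals are fixed plausible values (see the methods vignette).

.subnuclei_marginals <- function() {
  # medians (IQR -> SD via IQR/1.349) of the nine subnuclei per hemisphere
  med <- c(
    "left-accessory-basal" = 261, "left-anterior-amygdaloid-area" = 50,
    "left-basal" = 336, "left-central" = 42, "left-cortical" = 23,
    "left-cortico-amygdaloid-transition" = 178, "left-lateral" = 641,
    "left-medial" = 17, "left-paralaminar" = 50,
    "right-accessory-basal" = 271, "right-anterior-amygdaloid-area" = 54,
    "right-basal" = 368, "right-central" = 48, "right-cortical" = 25,
    "right-cortico-amygdaloid-transition" = 181, "right-lateral" = 655,
    "right-medial" = 19, "right-paralaminar" = 49)
  iqr <- c(37, 8, 176, 10, 6, 26, 108, 7, 8,
           46, 9, 172, 12, 7, 29, 94, 9, 8)
  list(mean = med, sd = stats::setNames(iqr / 1.349, names(med)))
}

.subcortical_marginals <- function() {
  m <- c("Left-Thalamus-Proper" = 7600, "Right-Thalamus-Proper" = 7700,
         "Left-Caudate" = 3650, "Right-Caudate" = 3700,
         "Left-Putamen" = 5350, "Right-Putamen" = 5300,
         "Left-Pallidum" = 1950, "Right-Pallidum" = 1960,
         "Left-Hippocampus" = 4250, "Right-Hippocampus" = 4350,
         "Left-Amygdala" = 1530, "Right-Amygdala" = 1699,
         "Left-Accumbens-area" = 560, "Right-Accumbens-area" = 555,
         "Left-VentralDC" = 4050, "Right-VentralDC" = 4070,
         "Left-Cerebellum-Cortex" = 52000, "Right-Cerebellum-Cortex" = 52500,
         "Brainstem" = 21500,
         "CC_Posterior" = 980, "CC_Mid_Posterior" = 450,
         "CC_Central" = 480, "CC_Mid_Anterior" = 520, "CC_Anterior" = 880)
  s <- 0.11 * m
  s["Left-Amygdala"] <- 202; s["Right-Amygdala"] <- 209
  list(mean = m, sd = s)
}

.default_marginals <- function(registry) {
  sub <- .subnuclei_marginals()
  asg <- .subcortical_marginals()
  cort <- registry_ids(registry, "cortical")
  # deterministic plausible cortical scales, 2.5-14 cm^3
  i <- seq_along(cort)
  cm <- 2500 + 400 * ((i * 7) %% 29)
  cs <- 0.11 * cm
  means <- c(stats::setNames(cm, cort), asg$mean, sub$mean)
  sds <- c(stats::setNames(cs, cort), asg$sd, sub$sd)
  measured <- measured_regions(registry)
  list(mean = means[measured], sd = sds[measured])
}

.base_correlation <- function(registry, shrink = 0.3) {
  regions <- measured_regions(registry)
  p <- length(regions)
  B <- matrix(0.25, p, p, dimnames = list(regions, regions))
  subn <- registry_ids(registry, "amygdala_subnucleus")
  left <- grep("^left-", subn, value = TRUE)
  right <- grep("^right-", subn, value = TRUE)
  B[left, left] <- 0.55
  B[right, right] <- 0.55
  B[left, right] <- 0.45; B[right, left] <- 0.45
  B[left, "Left-Amygdala"] <- B["Left-Amygdala", left] <- 0.65
  B[right, "Right-Amygdala"] <- B["Right-Amygdala", right] <- 0.65
  B[left, "Right-Amygdala"] <- B["Right-Amygdala", left] <- 0.5
  B[right, "Left-Amygdala"] <- B["Left-Amygdala", right] <- 0.5
  hip <- c("Left-Hippocampus", "Right-Hippocampus")
  B[subn, hip] <- 0.4; B[hip, subn] <- 0.4
  lh <- grep("^ctx-lh-", regions, value = TRUE)
  rh <- sub("^ctx-lh-", "ctx-rh-", lh)
  homol <- rh %in% regions
  B[cbind(lh[homol], rh[homol])] <- 0.45
  B[cbind(rh[homol], lh[homol])] <- 0.45
  diag(B) <- 1
  R <- (1 - shrink) * B + shrink * diag(p)
  dimnames(R) <- dimnames(B)
  R
}

.check_pd <- function(R, label) {
  ev <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 0)
    stop("target correlation matrix for ", label,
         " is not positive definite (smallest eigenvalue ",
         signif(ev, 4), ")")
  invisible(ev)
}

#' Construct a cohort scenario
#'
#' A fully specified synthetic world: group sizes, per-region marginal
#' means/SDs, the covariate model (age truncated-normal > 18, sex
#' Bernoulli, TBV normal), per-region covariate loadings, and per-group
#' latent correlation targets.
#'
#' @param name Scenario name.
#' @param registry A `region_registry`.
#' @param n_control,n_case Group sizes (defaults 71 and 67).
#' @param means,sds Named per-region marginal mean/SD (mm^3); defaults are
#'   the package's canonical marginals.
#' @param corr_control,corr_case Positive-definite correlation targets
#'   over the measured regions; default is the shared base structure.
#' @param mean_shift_case Named per-region additive shift (mm^3) applied
#'   to the case group's means (default none).
#' @param age_mean,age_sd,age_min,sex_p,tbv_mean,tbv_sd Covariate model.
#' @param effects List describing injected effects (recorded as ground
#'   truth; effects must already be baked into the targets/means).
#' @return A `cohort_scenario` list.
#' @export
cohort_scenario <- function(name, registry = region_registry(),
                            n_control = 71, n_case = 67,
                            means = NULL, sds = NULL,
                            corr_control = NULL, corr_case = NULL,
                            mean_shift_case = NULL,
                            age_mean = 38, age_sd = 8, age_min = 18,
                            sex_p = 0.72, tbv_mean = 1.52e6,
                            tbv_sd = 1.5e5, effects = list()) {
  marg <- .default_marginals(registry)
  if (is.null(means)) means <- marg$mean
  if (is.null(sds)) sds <- marg$sd
  regions <- names(means)
  stopifnot(identical(regions, names(sds)))
  if (is.null(corr_control)) corr_control <- .base_correlation(registry)
  if (is.null(corr_case)) corr_case <- corr_control
  stopifnot(identical(rownames(corr_control), regions),
            identical(rownames(corr_case), regions))
  .check_pd(corr_control, "control")
  .check_pd(corr_case, "case")
  shift <- stats::setNames(numeric(length(regions)), regions)
  if (!is.null(mean_shift_case))
    shift[names(mean_shift_case)] <- mean_shift_case
  loadings <- cbind(age = -0.003 * means, sex = 0.01 * means,
                    tbv = means / tbv_mean)
  structure(list(name = name, registry = registry,
                 n_control = n_control, n_case = n_case,
                 regions = regions, means = means, sds = sds,
                 mean_shift_case = shift,
                 corr_control = corr_control, corr_case = corr_case,
                 loadings = loadings,
                 age_mean = age_mean, age_sd = age_sd, age_min = age_min,
                 sex_p = sex_p, tbv_mean = tbv_mean, tbv_sd = tbv_sd,
                 effects = effects),
            class = "cohort_scenario")
}

#' @export
print.cohort_scenario <- function(x, ...) {
  cat("Cohort scenario '", x$name, "': ", x$n_control, " controls + ",
      x$n_case, " cases, ", length(x$regions), " regions, ",
      length(x$effects), " injected effect(s)\n", sep = "")
  invisible(x)
}

.rtruncnorm_min <- function(n, mean, sd, lower) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x <= lower))
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

.draw_group <- function(scn, n, corr, prefix) {
  p <- length(scn$regions)
  means <- scn$means
  if (prefix == "cas") means <- means + scn$mean_shift_case
  age <- .rtruncnorm_min(n, scn$age_mean, scn$age_sd, scn$age_min)
  sex <- stats::rbinom(n, 1, scn$sex_p)
  tbv <- .rtruncnorm_min(n, scn$tbv_mean, scn$tbv_sd, 0)
  Z <- matrix(stats::rnorm(n * p), n, p) %*% chol(corr)
  vol <- matrix(means, n, p, byrow = TRUE) +
    outer(age - scn$age_mean, scn$loadings[, "age"]) +
    outer(sex - scn$sex_p, scn$loadings[, "sex"]) +
    outer(tbv - scn$tbv_mean, scn$loadings[, "tbv"]) +
    Z * matrix(scn$sds, n, p, byrow = TRUE)
  n_trunc <- sum(vol < 1)
  vol[vol < 1] <- 1
  colnames(vol) <- scn$regions
  rownames(vol) <- sprintf("%s-%03d", prefix, seq_len(n))
  list(covariates = data.frame(subject_id = rownames(vol),
                               group = if (prefix == "ctl") "control"
                                       else "case",
                               age = age, sex = sex, tbv = tbv,
                               stringsAsFactors = FALSE),
       volumes = vol, n_trunc = n_trunc)
}

#' Generate a synthetic cohort
#'
#' Draws both groups from the scenario's multivariate-normal latent model:
#' per subject, region volume = marginal mean + linear age/sex/TBV effects
#' + SD-scaled latent score with the group's target correlation matrix.
#' Volumes are floored at 1 mm^3 (the truncation count is reported via a
#' message when nonzero). Deterministic for a fixed seed; the true
#' correlation targets, loadings and injected effects are attached as the
#' `ground_truth` attribute.
#'
#' @param scenario A `cohort_scenario`.
#' @param seed Integer seed.
#' @return A `cohort_table` with a `ground_truth` attribute.
#' @export
generate_cohort <- function(scenario, seed) {
  stopifnot(inherits(scenario, "cohort_scenario"))
  .check_pd(scenario$corr_control, "control")
  .check_pd(scenario$corr_case, "case")
  set.seed(seed)
  ctl <- .draw_group(scenario, scenario$n_control, scenario$corr_control,
                     "ctl")
  cas <- .draw_group(scenario, scenario$n_case, scenario$corr_case, "cas")
  if (ctl$n_trunc + cas$n_trunc > 0)
    message("floored ", ctl$n_trunc + cas$n_trunc,
            " volume draw(s) at 1 mm^3")
  cohort <- cohort_table(rbind(ctl$covariates, cas$covariates),
                         rbind(ctl$volumes, cas$volumes))
  attr(cohort, "ground_truth") <- list(
    scenario = scenario$name, seed = seed,
    corr_control = scenario$corr_control, corr_case = scenario$corr_case,
    loadings = scenario$loadings, effects = scenario$effects)
  cohort
}

# Inject a rank-one latent factor into a correlation matrix: R + f f^T,
# renormalized to unit diagonal. PD is preserved by construction, so the
# resulting entries ARE the population targets (recorded in ground truth).
.inject_factor <- function(R, loadings) {
  f <- stats::setNames(numeric(nrow(R)), rownames(R))
  f[names(loadings)] <- loadings
  stats::cov2cor(R + outer(f, f))
}

#' Library of reference scenarios
#'
#' Ships the four validation worlds used throughout the test suite.
#' Group differences are injected through rank-one latent factors
#' (`R + f f^T`, renormalized), which keeps the targets positive definite
#' by construction; the realized population correlations are recorded in
#' each scenario's `effects` entry.
#' \describe{
#'   \item{A_null}{identical groups: every calibration test's fixture.}
#'   \item{B_hub}{in cases, the right basal subnucleus latent is rebuilt
#'     as a weighted sum of 40 cortical region latents plus independent
#'     noise, giving it broad moderate correlations (about 0.37-0.43)
#'     with the whole network while leaving target-target correlations at
#'     baseline: an engineered betweenness/degree hub.}
#'   \item{C_corr_diff}{in cases, the left BLA constituents (loading 1.1)
#'     share a factor with the left superior temporal gyrus (loading
#'     1.4), giving r(BLA_i, STG) about 0.67 while r(CMA_i, STG) stays
#'     near 0.10: a within-group dependent-overlapping contrast.}
#'   \item{D_volume_diff}{a +50 mm^3 case-vs-control shift of the right
#'     basal nucleus mean volume.}
#' }
#'
#' @param registry A `region_registry`.
#' @return Named list of `cohort_scenario` objects.
#' @export
scenario_library <- function(registry = region_registry()) {
  base <- cohort_scenario("A_null", registry)

  cons <- composite_constituents(registry)
  target <- "ctx-lh-superiortemporal"
  f_c <- c(stats::setNames(rep(1.1, 4), cons[["left-bla"]]),
           stats::setNames(1.4, target))
  Rc <- .inject_factor(base$corr_case, f_c)
  scen_c <- cohort_scenario(
    "C_corr_diff", registry, corr_control = base$corr_control,
    corr_case = Rc,
    effects = list(list(kind = "corr_diff", nucleus_hi = "left-bla",
                        nucleus_lo = "left-cma", region = target,
                        r_hi = unname(Rc[cons[["left-bla"]][1], target]),
                        r_lo = unname(Rc[cons[["left-cma"]][1], target]))))

  boosted <- registry_ids(registry, "cortical")[
    round(seq(1, 62, length.out = 40))]
  hub <- "right-basal"
  Rb <- base$corr_case
  # hub latent := w * sum(boosted latents) + noise; w chosen so the sum
  # carries 0.95^2 of the hub's unit variance
  w <- 0.95 / sqrt(sum(Rb[boosted, boosted]))
  Rb[hub, ] <- w * colSums(Rb[boosted, ])
  Rb[, hub] <- Rb[hub, ]
  Rb[hub, hub] <- 1
  scen_b <- cohort_scenario(
    "B_hub", registry, corr_control = base$corr_control, corr_case = Rb,
    effects = list(list(kind = "hub_boost", region = hub,
                        targets = boosted,
                        r = unname(Rb[hub, boosted[1]]))))

  scen_d <- cohort_scenario(
    "D_volume_diff", registry,
    mean_shift_case = c("right-basal" = 50),
    effects = list(list(kind = "volume_diff", region = "right-basal",
                        magnitude = 50)))
  list(A_null = base, B_hub = scen_b, C_corr_diff = scen_c,
       D_volume_diff = scen_d)
}
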