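# Comparison of Pearson correlations: Fisher z for independent groups,
# Dunn & Clark z for dependent overlapping correlations (two correlations
# sharing one variable, measured in the same sample), Zou confidence
# intervals for the difference, and the layered FDR + Bonferroni scheme.

#' Fisher r-to-z transform
#'
#' `z = 0.5 * log((1 + r) / (1 - r))` = `atanh(r)`; odd and strictly
#' increasing on (-1, 1).
#'
#' @param r Correlation(s) with `|r| < 1`.
#' @return Transformed value(s).
#' @export
fisher_rz <- function(r) {
  if (any(abs(r) >= 1)) stop("fisher_rz requires |r| < 1")
  atanh(r)
}

# per-correlation Fisher CI bounds, vectorized
.fisher_ci <- function(r, n, alpha) {
  half <- stats::qnorm(1 - alpha / 2) / sqrt(n - 3)
  list(lo = tanh(atanh(r) - half), hi = tanh(atanh(r) + half))
}

# vectorized engine for the independent (between-group) comparison
.indep_engine <- function(r1, n1, r2, n2, alpha) {
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  p <- 2 * stats::pnorm(-abs(z))
  c1 <- .fisher_ci(r1, n1, alpha)
  c2 <- .fisher_ci(r2, n2, alpha)
  d <- r1 - r2
  list(statistic = z, p = p,
       ci_low  = d - sqrt((r1 - c1$lo)^2 + (c2$hi - r2)^2),
       ci_high = d + sqrt((c1$hi - r1)^2 + (r2 - c2$lo)^2))
}

# Correlation between the two sample correlations r_jk and r_jh induced by
# the intercorrelation r_kh; the Dunn & Clark covariance term.
.dunn_c <- function(r_jk, r_jh, r_kh) {
  num <- r_kh * (1 - r_jk^2 - r_jh^2) -
    0.5 * r_jk * r_jh * (1 - r_jk^2 - r_jh^2 - r_kh^2)
  num / ((1 - r_jk^2) * (1 - r_jh^2))
}

# vectorized engine for the dependent overlapping comparison
.dunn_engine <- function(r_jk, r_jh, r_kh, n, alpha) {
  cc <- .dunn_c(r_jk, r_jh, r_kh)
  z <- (atanh(r_jk) - atanh(r_jh)) * sqrt((n - 3) / (2 - 2 * cc))
  p <- 2 * stats::pnorm(-abs(z))
  c1 <- .fisher_ci(r_jk, n, alpha)
  c2 <- .fisher_ci(r_jh, n, alpha)
  d <- r_jk - r_jh
  lo_rad <- (r_jk - c1$lo)^2 + (c2$hi - r_jh)^2 -
    2 * cc * (r_jk - c1$lo) * (c2$hi - r_jh)
  hi_rad <- (c1$hi - r_jk)^2 + (r_jh - c2$lo)^2 -
    2 * cc * (c1$hi - r_jk) * (r_jh - c2$lo)
  list(statistic = z, p = p, c = cc,
       ci_low  = d - sqrt(pmax(lo_rad, 0)),
       ci_high = d + sqrt(pmax(hi_rad, 0)))
}

#' Compare two independent correlations (between groups)
#'
#' The same region pair's correlation in two independent samples, compared
#' via Fisher's z: `z = (Z(r1) - Z(r2)) / sqrt(1/(n1-3) + 1/(n2-3))` with a
#' two-tailed normal p-value, plus Zou's confidence interval for `r1 - r2`.
#'
#' @param r1,r2 Correlations (`|r| < 1`) in group 1 and group 2.
#' @param n1,n2 Group sizes (>= 4).
#' @param alpha Two-sided level for the CI (default 0.05).
#' @param labels Optional character vector naming the comparison.
#' @return A `corr_comparison` list: kind, r1, r2, n1, n2, statistic,
#'   p_raw, ci_low, ci_high, labels.
#' @export
independent_groups_test <- function(r1, n1, r2, n2, alpha = 0.05,
                                    labels = NULL) {
  if (n1 <= 3 || n2 <= 3) stop("need n > 3 in both groups")
  if (abs(r1) >= 1 || abs(r2) >= 1) stop("|r| must be < 1")
  e <- .indep_engine(r1, n1, r2, n2, alpha)
  structure(list(kind = "independent", r1 = r1, r2 = r2, r12 = NULL,
                 n1 = n1, n2 = n2, statistic = e$statistic, p_raw = e$p,
                 ci_low = e$ci_low, ci_high = e$ci_high, alpha = alpha,
                 labels = labels),
            class = "corr_comparison")
}

#' Compare two dependent overlapping correlations (Dunn & Clark z)
#'
#' Within one sample of size `n`, compares `r_jk = r(j, k)` against
#' `r_jh = r(j, h)` (shared variable `j`), accounting for the
#' intercorrelation `r_kh` of the two non-shared variables through the
#' covariance term `c` of the Fisher-transformed sample correlations:
#' `z = (Z(r_jk) - Z(r_jh)) * sqrt((n - 3) / (2 - 2c))`. Zou's interval
#' for `r_jk - r_jh` uses the same `c` as cross-term coefficient.
#'
#' @param r_jk,r_jh The two overlapping correlations.
#' @param r_kh Intercorrelation of the non-shared variables.
#' @param n Sample size (>= 4).
#' @param alpha Two-sided level for the CI.
#' @param labels Optional character vector naming the comparison.
#' @return A `corr_comparison` list (dependent kind, with `r12 = r_kh`).
#' @export
dunn_dependent_overlapping_test <- function(r_jk, r_jh, r_kh, n,
                                            alpha = 0.05, labels = NULL) {
  if (n < 4) stop("need n >= 4")
  if (any(abs(c(r_jk, r_jh, r_kh)) >= 1)) stop("|r| must be < 1")
  R <- matrix(c(1, r_jk, r_jh, r_jk, 1, r_kh, r_jh, r_kh, 1), 3, 3)
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-12)
    stop("correlation triple (r_jk, r_jh, r_kh) is not positive ",
         "semi-definite")
  e <- .dunn_engine(r_jk, r_jh, r_kh, n, alpha)
  if (e$c >= 1) stop("degenerate comparison: c >= 1")
  structure(list(kind = "dependent_overlapping", r1 = r_jk, r2 = r_jh,
                 r12 = r_kh, n1 = n, n2 = NULL, statistic = e$statistic,
                 p_raw = e$p, ci_low = e$ci_low, ci_high = e$ci_high,
                 alpha = alpha, labels = labels),
            class = "corr_comparison")
}

#' @export
print.corr_comparison <- function(x, ...) {
  cat(sprintf("%s comparison: r1 = %.3f vs r2 = %.3f, z = %.3f, p = %.2g\n",
              x$kind, x$r1, x$r2, x$statistic, x$p_raw))
  cat(sprintf("  %.0f%% Zou CI for r1 - r2: [%.3f, %.3f]\n",
              100 * (1 - x$alpha), x$ci_low, x$ci_high))
  invisible(x)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: sorted descending, `p_adj(i) = min(p_adj(i+1),
#' m * p(i) / rank(i))`, capped at 1. `m` defaults to the vector length but
#' may be set larger to adjust against a nominal family size.
#'
#' @param p Raw p-values in `[0, 1]`.
#' @param m Family size (>= `length(p)`).
#' @return Adjusted p-values in input order.
#' @export
bh_fdr <- function(p, m = length(p)) {
  if (!length(p)) stop("empty p-value vector")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  if (m < length(p)) stop("family size m smaller than number of tests")
  k <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(m / (k:1) * p[o]))[ro]
  adj
}

#' Bonferroni layer for subnuclei comparisons
#'
#' Number of subnuclei comparisons, and the corresponding significance
#' threshold, for each analysis/family combination: within-group compares
#' all unordered nucleus pairs (C(6,2) = 15 for three composite nuclei per
#' hemisphere pair, C(18,2) = 153 for nine), between-group compares each
#' nucleus across groups (6, resp. 18).
#'
#' @param analysis `"three_nuclei"` or `"nine_nuclei"`.
#' @param family `"within_group"` or `"between_group"`.
#' @param alpha Base level (default 0.05).
#' @return List with `divisor`, exact `alpha_bonf = alpha / divisor`, and
#'   `alpha_printed` (one significant digit, the convention used when the
#'   threshold is quoted, e.g. .003 for .05/15).
#' @export
decide_alpha <- function(analysis = c("three_nuclei", "nine_nuclei"),
                         family = c("within_group", "between_group"),
                         alpha = 0.05) {
  analysis <- match.arg(analysis)
  family <- match.arg(family)
  k <- if (analysis == "three_nuclei") 6L else 18L
  divisor <- if (family == "within_group") k * (k - 1L) / 2L else k
  list(divisor = as.integer(divisor), alpha_bonf = alpha / divisor,
       alpha_printed = signif(alpha / divisor, 1))
}

.stack_family <- function(lst) {
  df <- do.call(rbind, lst)
  rownames(df) <- NULL
  df
}

#' Run all covariance-profile comparisons
#'
#' For each nucleus (six composites or 18 subnuclei) a profile of adjusted
#' correlations against the target regions is drawn from each group's
#' association matrix. Within each group, every unordered nucleus pair is
#' compared target-by-target with the Dunn & Clark z (intercorrelation =
#' the two nuclei's adjusted correlation); between groups, each nucleus's
#' profile is compared target-by-target with Fisher's z. Every family (one
#' nucleus pair, or one nucleus between groups) is FDR-adjusted over the
#' targets against family size `fdr_family_size`, then tested against the
#' Bonferroni threshold from [decide_alpha()].
#'
#' @param assoc_by_group Named list `list(control = , case = )` of
#'   `association_matrix` objects with identical region ordering.
#' @param registry A `region_registry`.
#' @param analysis `"three_nuclei"` or `"nine_nuclei"`.
#' @param fdr_family_size Nominal FDR family size per family: 87 (methods
#'   convention, default) or 105.
#' @param alpha Base significance level.
#' @return A `profile_comparisons` list: `within` (named list per group of
#'   one stacked data frame, one row per pair x target), `between` (one
#'   data frame, one row per nucleus x target), and the `alpha` bookkeeping.
#' @export
run_profile_comparisons <- function(assoc_by_group,
                                    registry = region_registry(),
                                    analysis = c("three_nuclei",
                                                 "nine_nuclei"),
                                    fdr_family_size = 87, alpha = 0.05) {
  analysis <- match.arg(analysis)
  stopifnot(all(c("control", "case") %in% names(assoc_by_group)))
  a1 <- assoc_by_group$control; a2 <- assoc_by_group$case
  if (!identical(a1$region_ids, a2$region_ids))
    stop("association matrices have mismatched region sets")
  if (a1$n < 10 || a2$n < 10)
    stop("inferential comparisons need n >= 10 per group")
  nuclei <- analysis_nuclei(registry, analysis)
  targets <- intersect(profile_targets(registry), a1$region_ids)
  miss <- setdiff(nuclei, a1$region_ids)
  if (length(miss))
    stop("nuclei absent from association matrices: ",
         paste(miss, collapse = ", "))
  if (fdr_family_size < length(targets))
    stop("fdr_family_size smaller than the number of targets")
  aw <- decide_alpha(analysis, "within_group", alpha)
  ab <- decide_alpha(analysis, "between_group", alpha)

  pairs <- utils::combn(nuclei, 2)
  within <- list()
  for (g in c("control", "case")) {
    am <- assoc_by_group[[g]]
    fams <- vector("list", ncol(pairs))
    for (i in seq_len(ncol(pairs))) {
      n1 <- pairs[1, i]; n2 <- pairs[2, i]
      r1 <- am$r[n1, targets]; r2 <- am$r[n2, targets]
      e <- .dunn_engine(r1, r2, am$r[n1, n2], am$n, alpha)
      p_fdr <- bh_fdr(e$p, m = fdr_family_size)
      fams[[i]] <- data.frame(
        nucleus1 = n1, nucleus2 = n2, region = targets,
        r1 = unname(r1), r2 = unname(r2), r12 = am$r[n1, n2],
        statistic = unname(e$statistic), p_raw = unname(e$p),
        p_fdr = p_fdr, ci_low = unname(e$ci_low),
        ci_high = unname(e$ci_high),
        significant = p_fdr <= aw$alpha_bonf,
        stringsAsFactors = FALSE, row.names = NULL)
    }
    within[[g]] <- .stack_family(fams)
  }

  fams <- vector("list", length(nuclei))
  for (i in seq_along(nuclei)) {
    nu <- nuclei[i]
    r1 <- a1$r[nu, targets]; r2 <- a2$r[nu, targets]
    e <- .indep_engine(r1, a1$n, r2, a2$n, alpha)
    p_fdr <- bh_fdr(e$p, m = fdr_family_size)
    fams[[i]] <- data.frame(
      nucleus = nu, region = targets,
      r_control = unname(r1), r_case = unname(r2),
      statistic = unname(e$statistic), p_raw = unname(e$p),
      p_fdr = p_fdr, ci_low = unname(e$ci_low),
      ci_high = unname(e$ci_high),
      significant = p_fdr <= ab$alpha_bonf,
      stringsAsFactors = FALSE, row.names = NULL)
  }
  structure(list(within = within, between = .stack_family(fams),
                 analysis = analysis, targets = targets,
                 fdr_family_size = fdr_family_size,
                 alpha_within = aw, alpha_between = ab),
            class = "profile_comparisons")
}

#' @export
print.profile_comparisons <- function(x, ...) {
  cat("Profile comparisons (", x$analysis, "): ",
      length(unique(paste(x$within$control$nucleus1,
                          x$within$control$nucleus2))),
      " within-group families x ", length(x$targets), " targets; ",
      length(unique(x$between$nucleus)), " between-group families\n",
      sep = "")
  cat("  thresholds: within p <= ", signif(x$alpha_within$alpha_bonf, 3),
      ", between p <= ", signif(x$alpha_between$alpha_bonf, 3), "\n",
      sep = "")
  invisible(x)
}

#' Write comparison tables as TSV
#'
#' @param comparisons A `profile_comparisons` object.
#' @param dir Output directory.
#' @return Character vector of written paths, invisibly.
#' @export
write_comparisons <- function(comparisons, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (g in names(comparisons$within)) {
    p <- file.path(dir, paste0("within_", g, ".tsv"))
    utils::write.table(comparisons$within[[g]], p, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "between_groups.tsv")
  utils::write.table(comparisons$between, p, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(c(paths, p))
}
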