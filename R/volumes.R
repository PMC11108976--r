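# Covariate-adjusted between-group volume comparisons.

#' Compare nucleus volumes between groups
#'
#' Per region, ordinary least squares of volume on intercept + group +
#' age + sex + total brain volume. Reports the case-versus-control group
#' coefficient (mm^3), its normal-theory 95% confidence interval, the
#' two-tailed p-value, and the Bonferroni threshold for the analysis
#' (six tests for three bilateral nuclei, 18 for nine).
#'
#' @param cohort A `cohort_table` (pass through [aggregate_composites()]
#'   first for the three-nuclei analysis).
#' @param analysis `"three_nuclei"` or `"nine_nuclei"`; decides both the
#'   region set and the Bonferroni divisor.
#' @param registry A `region_registry`.
#' @param covariates Adjustment covariates (default age, sex, tbv;
#'   education is deliberately not included by default).
#' @param alpha Base significance level.
#' @return A `volume_comparisons` data frame: `region_id`, `beta_group`,
#'   `ci_low`, `ci_high`, `p`, `alpha_bonf`, `significant`, plus
#'   descriptive group medians and IQRs.
#' @export
compare_volumes <- function(cohort,
                            analysis = c("three_nuclei", "nine_nuclei"),
                            registry = region_registry(),
                            covariates = c("age", "sex", "tbv"),
                            alpha = 0.05) {
  analysis <- match.arg(analysis)
  regions <- analysis_nuclei(registry, analysis)
  miss <- setdiff(regions, colnames(cohort$volumes))
  if (length(miss))
    stop("cohort lacks region(s): ", paste(miss, collapse = ", "),
         if (analysis == "three_nuclei")
           " (run aggregate_composites() first)" else "")
  sizes <- group_sizes(cohort)
  if (any(sizes < length(covariates) + 2))
    stop("each group needs n >= covariates + 2")
  dat <- cbind(cohort$covariates,
               as.data.frame(cohort$volumes[, regions, drop = FALSE]))
  fml_rhs <- paste(c("group", covariates), collapse = " + ")
  rows <- lapply(regions, function(rg) {
    fit <- stats::lm(stats::reformulate(c("group", covariates),
                                        response = sprintf("`%s`", rg)),
                     data = dat)
    if (any(is.na(stats::coef(fit))))
      stop("singular design for region ", rg,
           " (collinear covariates?)")
    sm <- summary(fit)$coefficients["groupcase", ]
    half <- stats::qnorm(1 - alpha / 2) * sm["Std. Error"]
    ctl <- cohort$volumes[cohort$covariates$group == "control", rg]
    cas <- cohort$volumes[cohort$covariates$group == "case", rg]
    data.frame(region_id = rg,
               control_median = stats::median(ctl),
               control_iqr = stats::IQR(ctl),
               case_median = stats::median(cas),
               case_iqr = stats::IQR(cas),
               beta_group = unname(sm["Estimate"]),
               ci_low = unname(sm["Estimate"] - half),
               ci_high = unname(sm["Estimate"] + half),
               p = unname(sm["Pr(>|t|)"]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  divisor <- if (analysis == "three_nuclei") 6L else 18L
  out$alpha_bonf <- alpha / divisor
  out$significant <- out$p <= out$alpha_bonf
  rownames(out) <- NULL
  attr(out, "analysis") <- analysis
  attr(out, "formula") <- paste("volume ~", fml_rhs)
  class(out) <- c("volume_comparisons", "data.frame")
  out
}

#' Write volume comparisons as TSV
#' @param comparisons A `volume_comparisons` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_volume_comparisons <- function(comparisons, path) {
  utils::write.table(comparisons, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
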