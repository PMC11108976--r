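# Covariate adjustment and group-wise association structure.

#' Residualize regional volumes on covariates
#'
#' Per region, residuals of an ordinary least-squares fit of volume on
#' intercept + the requested covariates, computed within one group. All
#' downstream correlations are taken on these residuals, which is
#' equivalent to partialling the covariates out of the raw correlations.
#'
#' @param cohort A `cohort_table`.
#' @param group `"control"` or `"case"`.
#' @param regions Ordered region ids (default: all volume columns).
#' @param covariates Covariate column names (default age, sex, tbv).
#' @return An `adjusted_matrix`: list with `group`, `subject_ids`,
#'   `region_ids`, `covariates`, and the subjects x regions `residuals`.
#' @export
residualize <- function(cohort, group,
                        regions = colnames(cohort$volumes),
                        covariates = c("age", "sex", "tbv")) {
  stopifnot(group %in% c("control", "case"))
  idx <- cohort$covariates$group == group
  n <- sum(idx)
  if (n < length(covariates) + 2)
    stop("group '", group, "' has n = ", n, " < covariates + 2")
  miss <- setdiff(regions, colnames(cohort$volumes))
  if (length(miss)) stop("unknown region(s): ", paste(miss, collapse = ", "))
  X <- cbind(`(Intercept)` = 1,
             as.matrix(cohort$covariates[idx, covariates, drop = FALSE]))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("collinear covariate(s): ", paste(dropped, collapse = ", "))
  }
  Y <- cohort$volumes[idx, regions, drop = FALSE]
  res <- qr.resid(qrX, Y)
  dimnames(res) <- dimnames(Y)
  structure(list(group = group, subject_ids = rownames(Y),
                 region_ids = regions, covariates = covariates,
                 residuals = res),
            class = "adjusted_matrix")
}

#' Pearson association matrix of adjusted volumes
#'
#' @param adj An `adjusted_matrix`.
#' @return An `association_matrix`: list with `group`, `region_ids`,
#'   correlation matrix `r` (symmetric, unit diagonal) and `n`.
#' @export
correlation_matrix <- function(adj) {
  stopifnot(inherits(adj, "adjusted_matrix"))
  sds <- apply(adj$residuals, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance region(s): ",
         paste(adj$region_ids[sds == 0], collapse = ", "))
  r <- stats::cor(adj$residuals)
  r[r > 1] <- 1; r[r < -1] <- -1
  diag(r) <- 1
  structure(list(group = adj$group, region_ids = adj$region_ids, r = r,
                 n = nrow(adj$residuals)),
            class = "association_matrix")
}

#' @export
print.association_matrix <- function(x, ...) {
  cat("Association matrix (", x$group, "): ", length(x$region_ids), " x ",
      length(x$region_ids), ", n = ", x$n, "\n", sep = "")
  invisible(x)
}

#' Covariance profile of one nucleus
#'
#' The ordered vector of adjusted correlations between a nucleus and each
#' target region (87 targets in the canonical registry). Targets must not
#' include the nucleus itself nor any amygdala subnucleus or composite.
#'
#' @param assoc An `association_matrix`.
#' @param nucleus Nucleus region id.
#' @param targets Ordered target region ids.
#' @return Named numeric vector of correlations, one per target.
#' @export
covariance_profile <- function(assoc, nucleus, targets) {
  stopifnot(inherits(assoc, "association_matrix"))
  if (nucleus %in% targets)
    stop("nucleus '", nucleus, "' listed among targets")
  miss <- setdiff(c(nucleus, targets), assoc$region_ids)
  if (length(miss))
    stop("not in association matrix: ", paste(miss, collapse = ", "))
  assoc$r[nucleus, targets]
}

#' Export an association matrix
#'
#' Writes a TSV matrix with region-id header row/column and a JSON sidecar
#' (`<path>.meta.json`) recording group, n and adjustment covariates.
#'
#' @param assoc An `association_matrix`.
#' @param path Output TSV path.
#' @param covariates Covariates recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_association_matrix <- function(assoc, path,
                                     covariates = c("age", "sex", "tbv")) {
  df <- data.frame(region_id = assoc$region_ids, assoc$r,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(group = assoc$group, n = assoc$n,
                            covariates = covariates),
                       paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
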