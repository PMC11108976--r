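# Null covariance models, density-sweep integration, permutation inference.

#' Specification for a Hirschberger-Qi-Steuer null covariance matrix
#'
#' Records the target moments of the matrix to be generated: mean `e` and
#' variance `v` of the off-diagonal entries, mean `dbar` of the diagonal,
#' node count `p`, and the implied latent dimension
#' `m = max(2, round((dbar^2 - e^2) / v))`.
#'
#' @param e Target off-diagonal mean (>= 0).
#' @param v Target off-diagonal variance (> 0).
#' @param dbar Target diagonal mean (> `e`).
#' @param p Number of nodes.
#' @return An `hqs_spec` list with fields `e`, `v`, `dbar`, `p`, `m`.
#' @export
hqs_spec <- function(e, v, dbar, p) {
  if (v <= 0) stop("v must be positive")
  if (e < 0) stop("e must be non-negative")
  if (dbar <= e) stop("need dbar > e (else latent variance <= 0)")
  m <- max(2, round((dbar^2 - e^2) / v))
  structure(list(e = e, v = v, dbar = dbar, p = as.integer(p),
                 m = as.integer(m)),
            class = "hqs_spec")
}

#' Estimate an HQS specification from an observed matrix
#'
#' @param x An `association_matrix` or a square symmetric matrix.
#' @return An `hqs_spec` matched to the observed diagonal/off-diagonal
#'   moments.
#' @export
estimate_hqs_spec <- function(x) {
  r <- if (inherits(x, "association_matrix")) x$r else as.matrix(x)
  p <- nrow(r)
  if (p < 3) stop("need p >= 3")
  off <- r[upper.tri(r)]
  v <- stats::var(off)
  if (v == 0) stop("degenerate input: off-diagonal variance is zero")
  hqs_spec(e = mean(off), v = v, dbar = mean(diag(r)), p = p)
}

#' Generate an HQS null covariance matrix
#'
#' Draws a `p x m` matrix of independent normals with mean `sqrt(e/m)` and
#' SD `sqrt((dbar - e)/m)` and returns its outer product with its
#' transpose: a random positive semi-definite matrix whose expected
#' off-diagonal mean is `e`, off-diagonal variance approximately `v`, and
#' diagonal mean `dbar`.
#'
#' @param spec An `hqs_spec`.
#' @param seed Integer seed.
#' @param as_correlation Convert to correlation form (`stats::cov2cor`)?
#' @return A `p x p` covariance (or correlation) matrix.
#' @export
hqs_null_covariance <- function(spec, seed, as_correlation = FALSE) {
  stopifnot(inherits(spec, "hqs_spec"))
  set.seed(seed)
  mu <- sqrt(spec$e / spec$m)
  sigma <- sqrt((spec$dbar - spec$e) / spec$m)
  X <- matrix(stats::rnorm(spec$p * spec$m, mean = mu, sd = sigma),
              spec$p, spec$m)
  S <- tcrossprod(X)
  if (as_correlation) S <- stats::cov2cor(S)
  S
}

#' Area under a metric-versus-density curve
#'
#' Trapezoidal integral of a regional network metric over the density
#' sweep: the functional-data-analysis summary used for hub designation
#' and permutation inference.
#'
#' @param curve Metric values, one per density.
#' @param densities Strictly increasing density grid (>= 2 points).
#' @return The integral (a scalar).
#' @export
fda_auc <- function(curve, densities) {
  if (length(curve) != length(densities))
    stop("curve and density grid lengths differ")
  if (length(densities) < 2 || any(diff(densities) <= 0))
    stop("need a strictly increasing grid of >= 2 densities")
  sum(diff(densities) * (utils::head(curve, -1) + utils::tail(curve, -1)) / 2)
}

# residual correlation matrix for an arbitrary group indexing (fast path
# used inside the permutation loop; mirrors residualize + correlation_matrix)
.residual_cor <- function(volumes, covariates, idx, regions) {
  X <- cbind(1, as.matrix(covariates[idx, , drop = FALSE]))
  res <- qr.resid(qr(X), volumes[idx, regions, drop = FALSE])
  stats::cor(res)
}

.assoc_from_r <- function(r, regions, group, n) {
  structure(list(group = group, region_ids = regions, r = r, n = n),
            class = "association_matrix")
}

# per-group integrated metric scores on a fixed density grid; returns a
# nodes x 3 matrix. Fast path equivalent to
# integrate_metric_curves(sweep_metrics(assoc, grid)): one edge ranking is
# reused across the nested densities and no per-density tables are built.
.integrated_scores <- function(assoc, grid) {
  r <- assoc$r
  p <- nrow(r)
  ij <- which(upper.tri(r), arr.ind = TRUE)
  val <- r[ij]
  ord <- order(-val, ij[, 1], ij[, 2])
  ij <- ij[ord, , drop = FALSE]
  n_pairs <- p * (p - 1) / 2
  nd <- length(grid)
  deg <- btw <- clu <- matrix(0, p, nd)
  for (k in seq_len(nd)) {
    m <- floor(grid[k] * n_pairs + 0.5)
    g <- igraph::graph_from_edgelist(ij[seq_len(m), , drop = FALSE],
                                     directed = FALSE)
    if (igraph::vcount(g) < p)
      g <- igraph::add_vertices(g, p - igraph::vcount(g))
    dg <- igraph::degree(g)
    deg[, k] <- dg
    btw[, k] <- igraph::betweenness(g, directed = FALSE)
    cl <- igraph::transitivity(g, type = "local", isolates = "zero")
    cl[dg < 2] <- 0
    clu[, k] <- cl
  }
  w <- diff(grid) / 2
  trap <- function(M) as.vector((M[, -nd, drop = FALSE] +
                                   M[, -1, drop = FALSE]) %*% w)
  out <- cbind(degree = trap(deg), betweenness = trap(btw),
               clustering = trap(clu))
  rownames(out) <- assoc$region_ids
  out
}

#' Permutation test of density-integrated regional metrics
#'
#' Compares case minus control differences of the density-integrated
#' (AUC) degree, betweenness and clustering per node against a null built
#' by permuting group labels. Each permutation reruns the whole chain --
#' covariate residualization within the permuted groups, correlation
#' matrices, the density sweep and the AUC -- so covariate adjustment is
#' inside the exchangeability null. The density grid is fixed at the
#' observed `[D_min, d_max]` so AUCs are comparable across permutations.
#'
#' @param cohort A `cohort_table` (both groups present, n >= 10 each).
#' @param regions Node set for the graphs (e.g. 87 targets + nuclei).
#' @param covariates Adjustment covariates.
#' @param step,d_max Density grid parameters (defaults 0.02 and 0.5).
#' @param R Number of permutations (>= 100; default 1000).
#' @param seed Integer seed; identical seed + input gives identical output.
#' @param alpha Base level; Bonferroni across the three regional measures
#'   gives the reported threshold `alpha / 3`.
#' @return A `permutation_result` data frame: per node x metric the two
#'   group AUCs, observed difference, permutation `p_raw`
#'   (`(#{|null| >= |obs|} + 1) / (R + 1)`), BH-FDR `p_fdr` across nodes
#'   within metric, and the significance flag at `alpha / 3`. The density
#'   grid, `R`, seed and thresholds are attached as attributes.
#' @export
permutation_group_test <- function(cohort, regions,
                                   covariates = c("age", "sex", "tbv"),
                                   step = 0.02, d_max = 0.5, R = 1000,
                                   seed = 1, alpha = 0.05) {
  if (R < 100) stop("need R >= 100 permutations")
  sizes <- group_sizes(cohort)
  if (any(sizes < 10)) stop("inferential comparisons need n >= 10 per group")
  set.seed(seed)
  covs <- cohort$covariates[, covariates, drop = FALSE]
  labels <- cohort$covariates$group
  obs <- lapply(c(control = "control", case = "case"), function(g)
    .assoc_from_r(.residual_cor(cohort$volumes, covs, labels == g, regions),
                  regions, g, sum(labels == g)))
  d_min <- find_dmin(obs$control, obs$case, step = step, d_max = d_max)
  grid <- seq(d_min, d_max + 1e-12, by = step)
  sc_ctl <- .integrated_scores(obs$control, grid)
  sc_cas <- .integrated_scores(obs$case, grid)
  obs_diff <- sc_cas - sc_ctl

  null_exceed <- matrix(0L, nrow(obs_diff), ncol(obs_diff))
  n_all <- length(labels)
  n_cas <- sizes[["case"]]
  for (rep in seq_len(R)) {
    perm <- sample.int(n_all)
    is_case <- seq_len(n_all) %in% perm[seq_len(n_cas)]
    rc <- .assoc_from_r(.residual_cor(cohort$volumes, covs, !is_case,
                                      regions), regions, "control",
                        n_all - n_cas)
    ra <- .assoc_from_r(.residual_cor(cohort$volumes, covs, is_case,
                                      regions), regions, "case", n_cas)
    nd <- .integrated_scores(ra, grid) - .integrated_scores(rc, grid)
    null_exceed <- null_exceed + (abs(nd) >= abs(obs_diff))
  }
  p_raw <- (null_exceed + 1) / (R + 1)
  out <- data.frame(
    region_id = rep(rownames(obs_diff), 3),
    metric = rep(colnames(obs_diff), each = nrow(obs_diff)),
    auc_control = as.vector(sc_ctl), auc_case = as.vector(sc_cas),
    observed_diff = as.vector(obs_diff), p_raw = as.vector(p_raw),
    stringsAsFactors = FALSE)
  out$p_fdr <- stats::ave(out$p_raw, out$metric, FUN = bh_fdr)
  alpha_bonf <- alpha / 3
  out$significant <- out$p_fdr <= alpha_bonf
  attr(out, "densities") <- grid
  attr(out, "R") <- R
  attr(out, "seed") <- seed
  attr(out, "alpha_bonf") <- alpha_bonf
  attr(out, "alpha_printed") <- signif(alpha_bonf, 1)
  class(out) <- c("permutation_result", "data.frame")
  out
}

#' Null-network diagnostic against HQS matrices
#'
#' Generates `n_null` HQS correlation matrices matched to each observed
#' association matrix, runs them through the same density sweep, and
#' tabulates the observed density-integrated metric per node against the
#' null mean and SD. A sanity reference (observed topology should diverge
#' from moment-matched random covariance), not a group-inference step.
#'
#' @param assoc An `association_matrix`.
#' @param densities Density grid used for the observed sweep.
#' @param n_null Number of null matrices (default 20).
#' @param seed Integer seed.
#' @return Data frame: `region_id`, `metric`, `observed`, `null_mean`,
#'   `null_sd`.
#' @export
hqs_null_reference <- function(assoc, densities, n_null = 20, seed = 1) {
  spec <- estimate_hqs_spec(assoc)
  obs <- .integrated_scores(assoc, densities)
  acc <- array(NA_real_, c(nrow(obs), ncol(obs), n_null))
  for (k in seq_len(n_null)) {
    S <- hqs_null_covariance(spec, seed = seed + k - 1,
                             as_correlation = TRUE)
    dimnames(S) <- list(assoc$region_ids, assoc$region_ids)
    null_assoc <- .assoc_from_r(S, assoc$region_ids, assoc$group, assoc$n)
    acc[, , k] <- .integrated_scores(null_assoc, densities)
  }
  data.frame(
    region_id = rep(rownames(obs), ncol(obs)),
    metric = rep(colnames(obs), each = nrow(obs)),
    observed = as.vector(obs),
    null_mean = as.vector(apply(acc, c(1, 2), mean)),
    null_sd = as.vector(apply(acc, c(1, 2), stats::sd)),
    stringsAsFactors = FALSE)
}
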