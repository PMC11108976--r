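# Independent oracles and fixture builders shared across the suite.
# Oracles deliberately re-derive quantities by a different route than the
# package (literal path enumeration, triple loops, precision matrices).

the_registry <- region_registry()

# ---- graph oracles (p <= 12) ------------------------------------------

.bfs_dist_oracle <- function(adj, s) {
  p <- nrow(adj)
  d <- rep(Inf, p); d[s] <- 0
  frontier <- s
  while (length(frontier)) {
    nxt <- integer()
    for (v in frontier) {
      nb <- which(adj[v, ] > 0 & is.infinite(d))
      d[nb] <- d[v] + 1
      nxt <- c(nxt, nb)
    }
    frontier <- unique(nxt)
  }
  d
}

# all shortest s->t paths by backward recursion on BFS distances
.enum_shortest_paths <- function(adj, d, t) {
  if (d[t] == 0) return(list(t))
  preds <- which(adj[t, ] > 0 & d == d[t] - 1)
  out <- list()
  for (u in preds)
    for (pth in .enum_shortest_paths(adj, d, u))
      out[[length(out) + 1]] <- c(pth, t)
  out
}

oracle_betweenness <- function(adj) {
  p <- nrow(adj)
  btw <- numeric(p)
  for (s in seq_len(p - 1)) {
    d <- .bfs_dist_oracle(adj, s)
    for (t in seq(s + 1, p)) {
      if (!is.finite(d[t])) next
      paths <- .enum_shortest_paths(adj, d, t)
      pass <- numeric(p)
      for (pth in paths) {
        inner <- setdiff(pth, c(s, t))
        pass[inner] <- pass[inner] + 1
      }
      btw <- btw + pass / length(paths)
    }
  }
  btw
}

oracle_clustering <- function(adj) {
  p <- nrow(adj)
  sapply(seq_len(p), function(v) {
    nb <- which(adj[v, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    tri <- 0
    for (i in seq_len(k - 1)) for (j in seq(i + 1, k))
      tri <- tri + adj[nb[i], nb[j]]
    2 * tri / (k * (k - 1))
  })
}

random_adjacency <- function(p, prob) {
  adj <- matrix(0L, p, p)
  up <- which(upper.tri(adj))
  on <- up[stats::runif(length(up)) < prob]
  adj[on] <- 1L
  adj + t(adj)
}

graph_from_adj_fixture <- function(adj, density = 0.3) {
  ids <- sprintf("n%02d", seq_len(nrow(adj)))
  dimnames(adj) <- list(ids, ids)
  structure(list(region_ids = ids, adjacency = adj, density = density),
            class = "binary_graph")
}

# association matrix straight from a value matrix
assoc_fixture <- function(r, n = 50, group = "control") {
  ids <- rownames(r)
  if (is.null(ids)) {
    ids <- sprintf("n%02d", seq_len(nrow(r)))
    dimnames(r) <- list(ids, ids)
  }
  structure(list(group = group, region_ids = ids, r = r, n = n),
            class = "association_matrix")
}

# ---- statistics oracles -----------------------------------------------

# scalar re-transcriptions, kept separate from the package's vectorized
# engines on purpose
oracle_indep_z <- function(r1, n1, r2, n2) {
  (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
}

oracle_dunn_z <- function(r_jk, r_jh, r_kh, n) {
  cnum <- r_kh * (1 - r_jk^2 - r_jh^2) -
    0.5 * r_jk * r_jh * (1 - r_jk^2 - r_jh^2 - r_kh^2)
  cc <- cnum / ((1 - r_jk^2) * (1 - r_jh^2))
  (atanh(r_jk) - atanh(r_jh)) * sqrt((n - 3) / (2 - 2 * cc))
}

# partial correlation of x, y given covariate matrix Z via the precision
# matrix of cbind(x, y, Z)
oracle_partial_cor <- function(x, y, Z) {
  P <- solve(stats::cov(cbind(x, y, Z)))
  -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
}

# ---- cohort fixtures --------------------------------------------------

# small cohort over an arbitrary region subset with identity latent
# correlation (unless given) and default covariate effects
small_cohort <- function(n_control = 30, n_case = 30, p = 10, seed = 1,
                         corr = NULL, registry = the_registry) {
  regions <- measured_regions(registry)[seq_len(p)]
  marg <- scovnet:::.default_marginals(registry)
  if (is.null(corr)) {
    corr <- diag(p)
    dimnames(corr) <- list(regions, regions)
  }
  scn <- cohort_scenario("test", registry, n_control = n_control,
                         n_case = n_case, means = marg$mean[regions],
                         sds = marg$sd[regions], corr_control = corr,
                         corr_case = corr)
  suppressMessages(generate_cohort(scn, seed = seed))
}

# hand-built two-group cohort from explicit volumes
manual_cohort <- function(volumes, groups, age = NULL, sex = NULL,
                          tbv = NULL) {
  n <- nrow(volumes)
  if (is.null(rownames(volumes)))
    rownames(volumes) <- sprintf("s%03d", seq_len(n))
  covs <- data.frame(
    subject_id = rownames(volumes), group = groups,
    age = if (is.null(age)) rep(40, n) else age,
    sex = if (is.null(sex)) rep(0:1, length.out = n) else sex,
    tbv = if (is.null(tbv)) rep(1.5e6, n) else tbv,
    stringsAsFactors = FALSE)
  cohort_table(covs, volumes)
}
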