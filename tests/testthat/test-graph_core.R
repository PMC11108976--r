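test_that("binarize_at_density keeps the top-ranked pairs", {
  set.seed(21)
  p <- 5
  r <- matrix(0, p, p)
  r[upper.tri(r)] <- seq(0.1, 1, length.out = 10)
  r <- r + t(r); diag(r) <- 1
  a <- assoc_fixture(r)
  g <- binarize_at_density(a, 0.2)  # floor(0.2*10+0.5) = 2 edges
  expect_equal(sum(g$adjacency) / 2, 2)
  kept <- which(upper.tri(r) & g$adjacency == 1)
  expect_setequal(r[kept], sort(r[upper.tri(r)], decreasing = TRUE)[1:2])

  # round-half-up rule: p = 10, density 0.5 -> floor(22.5 + .5) = 23
  r10 <- matrix(stats::runif(100), 10, 10)
  r10 <- (r10 + t(r10)) / 2; diag(r10) <- 1
  g10 <- binarize_at_density(assoc_fixture(r10), 0.5)
  expect_equal(sum(g10$adjacency) / 2, 23)

  # all-tie case: deterministic lexicographic selection
  rt <- matrix(0.4, 6, 6); diag(rt) <- 1
  gt1 <- binarize_at_density(assoc_fixture(rt), 0.3)
  gt2 <- binarize_at_density(assoc_fixture(rt), 0.3)
  expect_identical(gt1$adjacency, gt2$adjacency)
  expect_equal(sum(gt1$adjacency) / 2, floor(0.3 * 15 + 0.5))
  # ties resolved toward lexicographically first pairs
  expect_equal(gt1$adjacency[1, 2], 1L)

  expect_error(binarize_at_density(assoc_fixture(rt), 0.6), "density")
  expect_error(binarize_at_density(assoc_fixture(rt), 0.01), "zero edges")
})

test_that("edge sets are nested across densities", {
  set.seed(22)
  r <- stats::cov2cor(crossprod(matrix(stats::rnorm(400), 20)))
  a <- assoc_fixture(r)
  prev <- binarize_at_density(a, 0.1)$adjacency
  for (d in seq(0.2, 0.5, by = 0.1)) {
    cur <- binarize_at_density(a, d)$adjacency
    expect_true(all(cur[prev == 1] == 1))
    prev <- cur
  }
})

test_that("find_dmin returns the first grid density connecting both", {
  # hub-and-spoke values: top edges already a spanning star at the first
  # grid point (p = 20: floor(0.1 * 190 + .5) = 19 edges = the 19 spokes)
  p <- 20
  r <- matrix(0.01, p, p)
  r[1, ] <- r[, 1] <- 0.9
  diag(r) <- 1
  a <- assoc_fixture(r)
  expect_equal(find_dmin(a, a, step = 0.1), 0.1)

  # a pendant node whose best edge's rank worsens raises d_min
  base <- matrix(0.01, 6, 6)
  base[1, 2:5] <- base[2:5, 1] <- 0.9           # star over nodes 1..5
  mids <- c(0.20, 0.22, 0.24, 0.26, 0.28, 0.30) # distinct mid-ranked pairs
  k <- 1
  for (i in 2:4) for (j in (i + 1):5) {
    base[i, j] <- base[j, i] <- mids[k]; k <- k + 1
  }
  diag(base) <- 1
  dmins <- sapply(c(0.6, 0.27, 0.25), function(w) {
    r2 <- base
    r2[1, 6] <- r2[6, 1] <- w
    find_dmin(assoc_fixture(r2), assoc_fixture(r2), step = 0.02)
  })
  expect_equal(dmins, c(0.30, 0.44, 0.50))

  # isolated node beyond d_max: error reports the maximum tried
  r3 <- matrix(0.8, 6, 6); diag(r3) <- 1
  r3[6, -6] <- r3[-6, 6] <- 0.01
  expect_error(find_dmin(assoc_fixture(r3), assoc_fixture(r3),
                         step = 0.1, d_max = 0.4), "0.4")
})

test_that("nodal_metrics agrees with hand-computed fixtures", {
  # complete graph K6
  k6 <- matrix(1L, 6, 6); diag(k6) <- 0L
  m <- nodal_metrics(graph_from_adj_fixture(k6))
  expect_equal(m$degree, rep(5L, 6))
  expect_equal(m$betweenness, rep(0, 6))
  expect_equal(m$clustering, rep(1, 6))

  # path a-b-c-d-e: betweenness(c) = 4, ends 0
  pth <- matrix(0L, 5, 5)
  for (i in 1:4) pth[i, i + 1] <- pth[i + 1, i] <- 1L
  m <- nodal_metrics(graph_from_adj_fixture(pth))
  expect_equal(m$betweenness, c(0, 3, 4, 3, 0))
  expect_equal(m$clustering, rep(0, 5))

  # star with 6 leaves: center betweenness C(6,2) = 15
  st <- matrix(0L, 7, 7)
  st[1, 2:7] <- st[2:7, 1] <- 1L
  m <- nodal_metrics(graph_from_adj_fixture(st))
  expect_equal(m$betweenness[1], 15)
  expect_equal(m$betweenness[-1], rep(0, 6))
  expect_equal(m$degree[1], 6L)
})

test_that("nodal_metrics matches the brute-force path-enumeration oracle", {
  set.seed(23)
  for (i in 1:30) {
    p <- sample(4:12, 1)
    adj <- random_adjacency(p, stats::runif(1, 0.25, 0.7))
    m <- nodal_metrics(graph_from_adj_fixture(adj))
    expect_equal(m$betweenness, oracle_betweenness(adj),
                 tolerance = 1e-10)
    expect_equal(m$clustering, oracle_clustering(adj), tolerance = 1e-12)
    expect_equal(m$degree, as.integer(rowSums(adj)))
    expect_equal(sum(m$degree), sum(adj))
  }
})

test_that("detect_hubs applies the strict mean + 2 SD rule", {
  sc <- data.frame(region_id = sprintf("n%d", 1:5),
                   metric = "betweenness",
                   score = c(0, 0, 0, 0, 5))
  # a single nonzero among n scores sits at z = sqrt(n - 1) population
  # SDs: exactly 2 for n = 5, so the strict rule must NOT flag it
  hb <- detect_hubs(sc, "control")
  expect_equal(nrow(hb), 0L)
  # with n = 10 the lone outlier sits at 3 SD and is flagged
  sc10 <- data.frame(region_id = sprintf("n%d", 1:10),
                     metric = "degree", score = c(rep(0, 9), 5))
  hb <- detect_hubs(sc10, "control")
  expect_equal(hb$region_id, "n10")
  expect_equal(hb$group_mean, 0.5)

  sc$score <- rep(2, 5)
  expect_warning(hb0 <- detect_hubs(sc, "case"), "zero SD")
  expect_equal(nrow(hb0), 0L)

  # star fixture: integrated betweenness flags the center only
  st <- matrix(0L, 7, 7); st[1, 2:7] <- st[2:7, 1] <- 1L
  ids <- sprintf("n%02d", 1:7)
  sc2 <- data.frame(region_id = ids, metric = "betweenness",
                    score = c(15, rep(0, 6)) * 0.3)
  hb2 <- detect_hubs(sc2, "control")
  expect_equal(hb2$region_id, "n01")
})

test_that("integrated curves equal per-density AUC composition", {
  set.seed(24)
  r <- stats::cov2cor(crossprod(matrix(stats::rnorm(15 * 30), 30)))
  a <- assoc_fixture(r)
  grid <- seq(0.2, 0.5, by = 0.02)
  sw <- sweep_metrics(a, grid)
  sc <- integrate_metric_curves(sw)
  # manual AUC for one node and metric
  one <- sw[sw$region_id == a$region_ids[3], ]
  expect_equal(sc$score[sc$region_id == a$region_ids[3] &
                          sc$metric == "degree"],
               fda_auc(one$degree, one$density))
  # internal fast path is identical
  fast <- scovnet:::.integrated_scores(a, grid)
  expect_equal(as.vector(fast),
               sc$score[order(match(sc$metric,
                                    c("degree", "betweenness",
                                      "clustering")),
                              match(sc$region_id, a$region_ids))],
               tolerance = 1e-12)
})
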