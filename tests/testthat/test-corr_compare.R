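test_that("fisher_rz is the odd, increasing arctanh transform", {
  expect_equal(fisher_rz(0), 0)
  expect_equal(fisher_rz(0.5), 0.5493061443340548, tolerance = 1e-15)
  r <- seq(0.1, 0.9, by = 0.1)
  expect_equal(fisher_rz(-r), -fisher_rz(r))
  expect_true(all(diff(fisher_rz(seq(-0.99, 0.99, by = 0.01))) > 0))
  expect_error(fisher_rz(1), "< 1")
})

test_that("independent_groups_test matches the closed form", {
  # equal correlations: exact null
  eq <- independent_groups_test(0.4, 30, 0.4, 50)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_raw, 1)
  expect_lt(eq$ci_low, 0); expect_gt(eq$ci_high, 0)

  # fixture at published scale: r = .81 vs .40 with n = 71/67
  cmp <- independent_groups_test(0.81, 71, 0.40, 67)
  expect_equal(cmp$statistic, oracle_indep_z(0.81, 71, 0.40, 67),
               tolerance = 1e-12)
  expect_equal(cmp$statistic, 4.038755405576, tolerance = 1e-9)
  expect_lt(cmp$p_raw, 1e-4)

  # grid agreement with the scalar oracle
  for (r1 in c(-0.6, 0, 0.35, 0.8))
    for (r2 in c(-0.2, 0.5))
      expect_equal(independent_groups_test(r1, 40, r2, 55)$statistic,
                   oracle_indep_z(r1, 40, r2, 55), tolerance = 1e-12)

  # degenerate n
  expect_error(independent_groups_test(0.5, 3, 0.2, 30), "n > 3")
})

test_that("Zou CI endpoints collapse to single-group Fisher CI limits", {
  # when r2's CI has zero width (n2 -> huge), the difference CI approaches
  # r1's own Fisher CI shifted by r2
  r1 <- 0.6; r2 <- 0.3
  cmp <- independent_groups_test(r1, 45, r2, 4e7)
  half <- stats::qnorm(0.975) / sqrt(45 - 3)
  l1 <- tanh(atanh(r1) - half); u1 <- tanh(atanh(r1) + half)
  expect_equal(cmp$ci_low, l1 - r2, tolerance = 1e-3)
  expect_equal(cmp$ci_high, u1 - r2, tolerance = 1e-3)
})

test_that("dunn_dependent_overlapping_test matches the closed form", {
  eq <- dunn_dependent_overlapping_test(0.5, 0.5, 0.3, 40)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_raw, 1)

  # fixture at published scale: r1 = .77 vs r2 = .37 at n = 67; the
  # intercorrelation 0.50 is a constructed fixture value
  cmp <- dunn_dependent_overlapping_test(0.77, 0.37, 0.50, 67)
  expect_equal(cmp$statistic, oracle_dunn_z(0.77, 0.37, 0.50, 67),
               tolerance = 1e-12)
  expect_equal(cmp$statistic, 4.526279592436, tolerance = 1e-9)

  for (rkh in c(-0.2, 0.1, 0.45))
    expect_equal(
      dunn_dependent_overlapping_test(0.6, 0.2, rkh, 80)$statistic,
      oracle_dunn_z(0.6, 0.2, rkh, 80), tolerance = 1e-12)

  # p is an even function of the transformed difference
  a <- dunn_dependent_overlapping_test(0.7, 0.2, 0.3, 50)
  b <- dunn_dependent_overlapping_test(0.2, 0.7, 0.3, 50)
  expect_equal(a$p_raw, b$p_raw)
  expect_equal(a$statistic, -b$statistic)

  expect_error(dunn_dependent_overlapping_test(0.9, -0.9, 0.9, 50),
               "positive")
})

test_that("Zou CI excludes zero iff the two-tailed test rejects", {
  grid_r <- seq(-0.7, 0.7, by = 0.2)
  mismatches <- 0L; total <- 0L
  for (r1 in grid_r) for (r2 in grid_r) {
    cmp <- independent_groups_test(r1, 40, r2, 60)
    rej <- cmp$p_raw <= 0.05
    excl <- cmp$ci_low > 0 || cmp$ci_high < 0
    total <- total + 1L
    # known near-boundary discrepancies are tolerated only when p ~ alpha
    if (rej != excl && abs(cmp$p_raw - 0.05) > 1e-3) {
      mismatches <- mismatches + 1L
    }
  }
  expect_equal(mismatches, 0L)

  for (r1 in grid_r) for (r2 in grid_r) {
    R3 <- matrix(c(1, r1, r2, r1, 1, 0.25, r2, 0.25, 1), 3, 3)
    if (min(eigen(R3, symmetric = TRUE,
                  only.values = TRUE)$values) < 1e-6) next
    cmp <- dunn_dependent_overlapping_test(r1, r2, 0.25, 45)
    rej <- cmp$p_raw <= 0.05
    excl <- cmp$ci_low > 0 || cmp$ci_high < 0
    if (rej != excl && abs(cmp$p_raw - 0.05) > 1e-3)
      mismatches <- mismatches + 1L
  }
  expect_equal(mismatches, 0L)
})

test_that("bh_fdr implements the step-up rule", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(0.2), 0.2)
  # order preservation and monotonicity against the reference routine
  set.seed(8)
  for (k in c(3, 10, 87)) {
    p <- stats::runif(k)
    expect_equal(bh_fdr(p), stats::p.adjust(p, "BH"))
    expect_true(all(bh_fdr(p) >= p))
  }
  # nominal family larger than the number of tests
  p <- c(0.001, 0.04)
  expect_equal(bh_fdr(p, m = 4), stats::p.adjust(c(p, 1, 1), "BH")[1:2])
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_fdr(numeric()), "empty")
})

test_that("decide_alpha reproduces the comparison-count thresholds", {
  w3 <- decide_alpha("three_nuclei", "within_group")
  expect_equal(w3$divisor, 15L)
  expect_equal(w3$alpha_bonf, 0.05 / 15)
  expect_equal(w3$alpha_printed, 0.003)
  b3 <- decide_alpha("three_nuclei", "between_group")
  expect_equal(b3$divisor, 6L)
  expect_equal(b3$alpha_printed, 0.008)
  w9 <- decide_alpha("nine_nuclei", "within_group")
  expect_equal(w9$divisor, 153L)
  expect_equal(w9$alpha_printed, 3e-04)
  b9 <- decide_alpha("nine_nuclei", "between_group")
  expect_equal(b9$divisor, 18L)
  expect_equal(b9$alpha_printed, 0.003)
})

test_that("run_profile_comparisons emits the right family structure", {
  co <- small_cohort(p = 105, n_control = 25, n_case = 25, seed = 12)
  co <- aggregate_composites(co, the_registry)
  nodes <- c(profile_targets(the_registry),
             analysis_nuclei(the_registry, "three_nuclei"))
  a <- lapply(c(control = "control", case = "case"), function(g)
    correlation_matrix(residualize(co, g, regions = nodes)))
  cmp <- run_profile_comparisons(a, the_registry, "three_nuclei")
  expect_equal(nrow(cmp$within$control), 15 * 87)
  expect_equal(nrow(cmp$within$case), 15 * 87)
  expect_equal(nrow(cmp$between), 6 * 87)
  expect_equal(length(unique(paste(cmp$within$case$nucleus1,
                                   cmp$within$case$nucleus2))), 15)
  # FDR is per family: each family's adjusted p respects monotonicity
  expect_true(all(cmp$between$p_fdr >= cmp$between$p_raw))

  # identical matrices: between-group z identically 0, nothing significant
  mirror <- a$control
  mirror$group <- "case"
  cmp0 <- run_profile_comparisons(list(control = a$control, case = mirror),
                                  the_registry, "three_nuclei")
  expect_true(all(cmp0$between$statistic == 0))
  expect_false(any(cmp0$between$significant))

  b <- a
  b$case$region_ids <- rev(b$case$region_ids)
  expect_error(run_profile_comparisons(b, the_registry), "mismatched")
})
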