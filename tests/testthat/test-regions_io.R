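test_that("canonical registry satisfies the count and grouping contract", {
  reg <- the_registry
  counts <- table(reg$region_class)
  expect_equal(unname(counts[c("cortical", "subcortical",
                               "amygdala_subnucleus")]),
               c(63L, 24L, 18L), ignore_attr = TRUE)
  expect_length(measured_regions(reg), 105)
  expect_length(profile_targets(reg), 87)
  expect_false(anyDuplicated(reg$region_id) > 0)

  subn <- reg[reg$region_class == "amygdala_subnucleus", ]
  expect_equal(sum(subn$hemisphere == "left"), 9)
  expect_equal(sum(subn$hemisphere == "right"), 9)

  cons <- composite_constituents(reg)
  expect_setequal(cons[["left-bla"]],
                  paste0("left-", c("accessory-basal", "basal", "lateral",
                                    "paralaminar")))
  expect_setequal(cons[["right-cma"]],
                  paste0("right-", c("central", "medial")))
  expect_setequal(cons[["left-sfa"]],
                  paste0("left-", c("anterior-amygdaloid-area",
                                    "cortico-amygdaloid-transition",
                                    "cortical")))
  expect_length(unlist(cons), 18)
})

test_that("registry JSON round-trips and ships in extdata", {
  path <- withr::local_tempfile(fileext = ".json")
  write_registry_json(the_registry, path)
  back <- read_registry_json(path)
  expect_equal(as.data.frame(back), as.data.frame(the_registry))
  shipped <- system.file("extdata", "region_registry_v1.json",
                         package = "scovnet")
  expect_true(nzchar(shipped))
  expect_equal(nrow(read_registry_json(shipped)), nrow(the_registry))
})

test_that("load_cohort validates, resolves headers, reports extras", {
  co <- small_cohort(n_control = 71, n_case = 67, p = 105, seed = 4)
  expect_equal(group_sizes(co), c(control = 71L, case = 67L))

  dir <- withr::local_tempdir()
  paths <- write_cohort(co, dir)
  back <- load_cohort(paths["volumes"], paths["covariates"], the_registry)
  expect_equal(back$volumes, co$volumes)
  expect_equal(back$covariates$age, co$covariates$age)

  # header resolution is case/separator-insensitive
  vols <- utils::read.csv(paths["volumes"], check.names = FALSE)
  names(vols)[2] <- toupper(gsub("-", "_", names(vols)[2]))
  utils::write.csv(vols, paths["volumes"], row.names = FALSE, quote = FALSE)
  back2 <- load_cohort(paths["volumes"], paths["covariates"], the_registry)
  expect_equal(back2$volumes, co$volumes)

  # missing region column is an error naming the id
  vols <- utils::read.csv(paths["volumes"], check.names = FALSE)
  vols[["left-basal"]] <- NULL
  utils::write.csv(vols, paths["volumes"], row.names = FALSE, quote = FALSE)
  expect_error(load_cohort(paths["volumes"], paths["covariates"],
                           the_registry),
               "left-basal")

  # extra columns are reported and ignored
  paths <- write_cohort(co, dir)
  vols <- utils::read.csv(paths["volumes"], check.names = FALSE)
  vols$not_a_region <- 1
  utils::write.csv(vols, paths["volumes"], row.names = FALSE, quote = FALSE)
  expect_message(load_cohort(paths["volumes"], paths["covariates"],
                             the_registry),
                 "unrecognized")
})

test_that("cohort_table rejects malformed input", {
  vols <- matrix(100, 4, 2,
                 dimnames = list(paste0("s", 1:4), c("a", "b")))
  covs <- data.frame(subject_id = paste0("s", 1:4),
                     group = c("control", "control", "case", "case"),
                     age = 40, sex = 0:1, tbv = 1.5e6)
  expect_s3_class(cohort_table(covs, vols), "cohort_table")
  covs_dup <- covs; covs_dup$subject_id[2] <- "s1"
  expect_error(cohort_table(covs_dup, vols), "duplicate")
  vols_neg <- vols; vols_neg[1, 1] <- -5
  expect_error(cohort_table(covs, vols_neg), "positive")
  expect_error(cohort_table(covs[-1, ], vols), "differ")
})

test_that("iqr_qc flags exactly the out-of-fence values", {
  # group of five with one gross outlier: Q1 = 2, Q3 = 4, fences [-1, 7]
  vols <- cbind(r1 = c(1, 2, 3, 4, 100, 10, 11, 12, 13),
                r2 = rep(50, 9))
  groups <- c(rep("control", 5), rep("case", 4))
  co <- manual_cohort(vols, groups)
  rep <- iqr_qc(co, c("r1", "r2"))
  expect_equal(nrow(rep), 1L)
  expect_equal(rep$region_id, "r1")
  expect_equal(rep$value, 100)
  expect_equal(rep$lower_fence, -1)
  expect_equal(rep$upper_fence, 7)
  # all-equal region produces no flags; cohort is not mutated
  before <- co$volumes
  expect_equal(nrow(iqr_qc(co, "r2")), 0L)
  expect_identical(co$volumes, before)
  expect_error(iqr_qc(co, character()), "empty")
})

test_that("aggregate_composites sums constituents and is idempotent", {
  co <- small_cohort(p = 105, n_control = 12, n_case = 12, seed = 2)
  agg <- aggregate_composites(co, the_registry)
  cons <- composite_constituents(the_registry)
  for (comp in names(cons))
    expect_equal(agg$volumes[, comp],
                 rowSums(co$volumes[, cons[[comp]]]))
  agg2 <- aggregate_composites(agg, the_registry)
  expect_equal(agg2$volumes[, colnames(agg$volumes)], agg$volumes)

  broken <- co
  broken$volumes <- broken$volumes[, colnames(broken$volumes) !=
                                     "left-basal"]
  expect_error(aggregate_composites(broken, the_registry), "left-basal")
})
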