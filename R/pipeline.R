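# End-to-end orchestration: QC -> adjustment -> profiles -> comparisons ->
# graphs -> inference -> volumes, with a JSON run manifest.

#' Build a validated run configuration
#'
#' @param analysis `"three_nuclei"` or `"nine_nuclei"`.
#' @param covariates Adjustment covariates.
#' @param fdr_family_size FDR family size per comparison family (87 or 105).
#' @param density_step,d_max Density sweep grid (defaults 0.02, 0.5).
#' @param R Permutation repetitions (default 1000).
#' @param n_null HQS null matrices (default 20).
#' @param seed Integer seed for every stochastic stage.
#' @param alpha Base significance level.
#' @param out_dir Output directory.
#' @return A `run_config` list including a `hash` of its own contents.
#' @export
run_config <- function(analysis = c("three_nuclei", "nine_nuclei"),
                       covariates = c("age", "sex", "tbv"),
                       fdr_family_size = 87, density_step = 0.02,
                       d_max = 0.5, R = 1000, n_null = 20, seed = 1,
                       alpha = 0.05, out_dir = "results") {
  analysis <- match.arg(analysis)
  if (!fdr_family_size %in% c(87, 105))
    stop("fdr_family_size must be 87 or 105")
  if (density_step <= 0 || density_step > 0.1)
    stop("density_step must lie in (0, 0.1]")
  if (d_max <= density_step || d_max > 0.5)
    stop("d_max must lie in (density_step, 0.5]")
  if (R < 100) stop("R must be >= 100")
  if (n_null < 1) stop("n_null must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  cfg <- list(analysis = analysis, covariates = covariates,
              fdr_family_size = fdr_family_size,
              density_step = density_step, d_max = d_max, R = R,
              n_null = n_null, seed = as.integer(seed), alpha = alpha,
              out_dir = out_dir)
  cfg$hash <- .json_md5(cfg)
  class(cfg) <- "run_config"
  cfg
}

.json_md5 <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), tf)
  unname(tools::md5sum(tf))
}

#' Read a JSON run configuration file
#'
#' Accepts a JSON object with any subset of [run_config()]'s fields.
#'
#' @param path Path to the JSON config.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- setdiff(names(formals(run_config)), "...")
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config field(s): ", paste(bad, collapse = ", "))
  do.call(run_config, raw)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes QC, composite aggregation, group-wise residualization,
#' association matrices, profile comparisons, the density-sweep graph
#' analysis with HQS reference and permutation inference, and the volume
#' comparisons; every stage's table is written under `config$out_dir`
#' together with a JSON manifest (seed, config, file checksums). A rerun
#' with identical inputs and seed is bit-identical.
#'
#' @param cohort A `cohort_table`, or `NULL` to load from paths.
#' @param config A `run_config`.
#' @param volumes_path,covariates_path Input tables (used when `cohort`
#'   is `NULL`).
#' @param registry A `region_registry`.
#' @return Invisibly, the result bundle: cohort, qc, association matrices,
#'   comparisons, d_min, integrated metrics, hubs, HQS reference,
#'   permutation result, volume comparisons, manifest path.
#' @export
run_pipeline <- function(cohort = NULL, config = run_config(),
                         volumes_path = NULL, covariates_path = NULL,
                         registry = region_registry()) {
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  if (is.null(cohort))
    cohort <- .stage("load", load_cohort(volumes_path, covariates_path,
                                         registry))
  qc <- .stage("qc", {
    rep <- iqr_qc(cohort,
                  regions = registry_ids(registry, "amygdala_subnucleus"))
    write_qc_report(rep, file.path(out, "qc_report.tsv"))
    rep
  })
  cohort <- .stage("aggregate", aggregate_composites(cohort, registry))
  nuclei <- analysis_nuclei(registry, config$analysis)
  nodes <- c(profile_targets(registry), nuclei)
  assoc <- .stage("adjust", {
    a <- lapply(c(control = "control", case = "case"), function(g)
      correlation_matrix(residualize(cohort, g, regions = nodes,
                                     covariates = config$covariates)))
    for (g in names(a))
      write_association_matrix(a[[g]],
                               file.path(out, paste0("assoc_", g, ".tsv")),
                               covariates = config$covariates)
    a
  })
  comparisons <- .stage("covary", {
    cmp <- run_profile_comparisons(assoc, registry, config$analysis,
                                   config$fdr_family_size, config$alpha)
    write_comparisons(cmp, out)
    cmp
  })
  graphs <- .stage("graph", {
    d_min <- find_dmin(assoc$control, assoc$case,
                       step = config$density_step, d_max = config$d_max)
    grid <- seq(d_min, config$d_max + 1e-12, by = config$density_step)
    scores <- hubs <- list()
    for (g in names(assoc)) {
      sw <- sweep_metrics(assoc[[g]], grid)
      utils::write.table(sw, file.path(out, paste0("metrics_", g, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      scores[[g]] <- integrate_metric_curves(sw)
      hubs[[g]] <- detect_hubs(scores[[g]], g)
    }
    hub_tab <- do.call(rbind, hubs)
    utils::write.table(hub_tab, file.path(out, "hubs.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    list(d_min = d_min, grid = grid, scores = scores, hubs = hub_tab)
  })
  hqs_ref <- .stage("infer-null", {
    ref <- do.call(rbind, lapply(names(assoc), function(g) {
      df <- hqs_null_reference(assoc[[g]], graphs$grid,
                               n_null = config$n_null,
                               seed = config$seed)
      df$group <- g
      df
    }))
    utils::write.table(ref, file.path(out, "hqs_reference.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    ref
  })
  perm <- .stage("infer", {
    pr <- permutation_group_test(cohort, regions = nodes,
                                 covariates = config$covariates,
                                 step = config$density_step,
                                 d_max = config$d_max, R = config$R,
                                 seed = config$seed,
                                 alpha = config$alpha)
    utils::write.table(pr, file.path(out, "permutation.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    pr
  })
  volumes <- .stage("volumes", {
    vc <- compare_volumes(cohort, config$analysis, registry,
                          covariates = config$covariates,
                          alpha = config$alpha)
    write_volume_comparisons(vc, file.path(out, "volume_comparisons.tsv"))
    vc
  })
  manifest_path <- file.path(out, "manifest.json")
  files <- setdiff(list.files(out, full.names = TRUE), manifest_path)
  manifest <- list(package = "scovnet",
                   version = as.character(utils::packageVersion("scovnet")),
                   seed = config$seed, config = unclass(config),
                   d_min = graphs$d_min,
                   checksums = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(cohort = cohort, qc = qc, assoc = assoc,
                 comparisons = comparisons, d_min = graphs$d_min,
                 scores = graphs$scores, hubs = graphs$hubs,
                 hqs_reference = hqs_ref, permutation = perm,
                 volumes = volumes, manifest = manifest_path))
}

.cli_fail <- function(status, msg) {
  message("error: ", msg)
  status
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic cohort), `qc`, `adjust`,
#' `covary`, `graph`, `infer`, `volumes`, and `run` (the full pipeline).
#' Invoked by the `inst/cli/scovnet` wrapper script; returns the process
#' exit status (0 ok, 2 validation error, 3 compute error) so it can be
#' exercised in-process.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status, invisibly.
#' @export
scovnet_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!requireNamespace("optparse", quietly = TRUE))
    return(invisible(.cli_fail(2L, "optparse is required for the CLI")))
  if (!length(args))
    return(invisible(.cli_fail(
      2L, paste("usage: scovnet",
                "<simulate|qc|adjust|covary|graph|infer|volumes|run> ..."))))
  cmd <- args[1]
  rest <- args[-1]
  opts_def <- list(
    optparse::make_option("--volumes", type = "character"),
    optparse::make_option("--covariates", type = "character"),
    optparse::make_option("--config", type = "character"),
    optparse::make_option("--scenario", type = "character",
                          default = "A_null"),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--out", type = "character",
                          default = "results"))
  opt <- tryCatch(
    optparse::parse_args(optparse::OptionParser(option_list = opts_def),
                         args = rest),
    error = function(e) e)
  if (inherits(opt, "error"))
    return(invisible(.cli_fail(2L, conditionMessage(opt))))
  cfg <- tryCatch({
    base <- if (!is.null(opt$config)) read_run_config(opt$config)
            else run_config()
    base$seed <- opt$seed
    base$out_dir <- opt$out
    base
  }, error = function(e) e)
  if (inherits(cfg, "error"))
    return(invisible(.cli_fail(2L, conditionMessage(cfg))))
  dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
  registry <- region_registry()

  load_or_fail <- function() {
    if (is.null(opt$volumes) || is.null(opt$covariates))
      stop("--volumes and --covariates are required")
    load_cohort(opt$volumes, opt$covariates, registry)
  }
  status <- tryCatch({
    switch(cmd,
      simulate = {
        lib <- scenario_library(registry)
        if (!opt$scenario %in% names(lib))
          stop("unknown scenario '", opt$scenario, "'; available: ",
               paste(names(lib), collapse = ", "))
        cohort <- generate_cohort(lib[[opt$scenario]], seed = opt$seed)
        write_cohort(cohort, opt$out)
        gt <- attr(cohort, "ground_truth")
        gt$corr_control <- NULL; gt$corr_case <- NULL
        gt$loadings <- NULL
        jsonlite::write_json(gt, file.path(opt$out, "ground_truth.json"),
                             auto_unbox = TRUE, digits = NA)
        0L
      },
      qc = {
        cohort <- load_or_fail()
        write_qc_report(iqr_qc(cohort), file.path(opt$out,
                                                  "qc_report.tsv"))
        0L
      },
      adjust = {
        cohort <- aggregate_composites(load_or_fail(), registry)
        nodes <- c(profile_targets(registry),
                   analysis_nuclei(registry, cfg$analysis))
        for (g in c("control", "case"))
          write_association_matrix(
            correlation_matrix(residualize(cohort, g, regions = nodes,
                                           covariates = cfg$covariates)),
            file.path(opt$out, paste0("assoc_", g, ".tsv")),
            covariates = cfg$covariates)
        0L
      },
      covary = , graph = , infer = , run = {
        cohort <- load_or_fail()
        run_pipeline(cohort, cfg, registry = registry)
        0L
      },
      volumes = {
        cohort <- aggregate_composites(load_or_fail(), registry)
        write_volume_comparisons(
          compare_volumes(cohort, cfg$analysis, registry,
                          covariates = cfg$covariates, alpha = cfg$alpha),
          file.path(opt$out, "volume_comparisons.tsv"))
        0L
      },
      stop("unknown subcommand '", cmd, "'"))
  }, error = function(e) {
    msg <- conditionMessage(e)
    validation <- grepl(
      "required|unknown|missing|must|duplicate|not found|lacks", msg)
    .cli_fail(if (validation) 2L else 3L, msg)
  })
  invisible(status)
}
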