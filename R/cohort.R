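# Cohort container: subject covariates + a subjects x regions volume matrix.

#' Construct a cohort table
#'
#' @param covariates Data frame with columns `subject_id`, `group`
#'   (`control`/`case`), `age` (years, > 0), `sex` (0/1 coded) and `tbv`
#'   (total brain volume, mm^3, > 0).
#' @param volumes Numeric matrix, one row per subject (rownames =
#'   `subject_id`), one column per region (mm^3, > 0).
#' @param sex_coding Character note recording what 0 and 1 mean.
#' @return A `cohort_table` object.
#' @export
cohort_table <- function(covariates, volumes,
                         sex_coding = "0=female,1=male") {
  need <- c("subject_id", "group", "age", "sex", "tbv")
  miss <- setdiff(need, names(covariates))
  if (length(miss))
    stop("covariate table lacks column(s): ", paste(miss, collapse = ", "))
  covariates$subject_id <- as.character(covariates$subject_id)
  if (anyDuplicated(covariates$subject_id))
    stop("duplicate subject_id in covariate table")
  if (!all(covariates$group %in% c("control", "case")))
    stop("group labels must be 'control' or 'case'")
  covariates$group <- factor(covariates$group, levels = c("control", "case"))
  if (any(covariates$age <= 0) || any(covariates$tbv <= 0))
    stop("age and tbv must be positive")
  if (!all(covariates$sex %in% c(0, 1)))
    stop("sex must be coded 0/1 (", sex_coding, ")")
  volumes <- as.matrix(volumes)
  if (is.null(rownames(volumes)))
    stop("volume matrix needs subject_id rownames")
  if (!setequal(rownames(volumes), covariates$subject_id))
    stop("subjects in volume and covariate tables differ")
  volumes <- volumes[covariates$subject_id, , drop = FALSE]
  if (any(!is.finite(volumes)) || any(volumes <= 0))
    stop("all volumes must be finite and positive (mm^3)")
  structure(list(covariates = covariates, volumes = volumes,
                 sex_coding = sex_coding),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  n <- table(x$covariates$group)
  cat("Cohort:", nrow(x$volumes), "subjects (control =", n[["control"]],
      ", case =", n[["case"]], "),", ncol(x$volumes), "regions\n")
  invisible(x)
}

#' Group sizes of a cohort
#' @param cohort A `cohort_table`.
#' @return Named integer vector `c(control=, case=)`.
#' @export
group_sizes <- function(cohort) {
  tab <- table(cohort$covariates$group)
  c(control = unname(tab["control"]), case = unname(tab["case"]))
}

.read_table_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "")
}

#' Load a cohort from volume and covariate tables
#'
#' Reads a wide volume table (`subject_id` + one column per region, mm^3 --
#' CSV, TSV, or an asegstats2table-style TSV whose first column is the
#' subject id) and a covariate table (`subject_id`, `group`, `age`, `sex`,
#' `tbv`), resolves headers to registry region ids case- and
#' separator-insensitively, and joins on `subject_id`.
#'
#' Unrecognized volume columns are reported and dropped; a missing measured
#' region is an error naming the absent ids.
#'
#' @param volumes_path Path to the volume table.
#' @param covariates_path Path to the covariate table.
#' @param registry A `region_registry` (default: canonical).
#' @return A validated `cohort_table`.
#' @export
load_cohort <- function(volumes_path, covariates_path,
                        registry = region_registry()) {
  vols <- .read_table_auto(volumes_path)
  covs <- .read_table_auto(covariates_path)
  names(covs) <- tolower(names(covs))
  id_col <- names(vols)[1]
  subj <- as.character(vols[[id_col]])
  if (anyDuplicated(subj))
    stop("duplicate subject_id in volume table: ",
         paste(unique(subj[duplicated(subj)]), collapse = ", "))
  want <- measured_regions(registry)
  keys <- .normalize_region_key(want)
  have_keys <- .normalize_region_key(names(vols)[-1])
  hit <- match(keys, have_keys)
  if (anyNA(hit))
    stop("volume table is missing region column(s): ",
         paste(want[is.na(hit)], collapse = ", "))
  extra <- setdiff(seq_along(have_keys), hit)
  if (length(extra))
    message("ignoring ", length(extra), " unrecognized volume column(s): ",
            paste(utils::head(names(vols)[-1][extra], 5), collapse = ", "),
            if (length(extra) > 5) ", ..." else "")
  m <- as.matrix(vols[, -1, drop = FALSE][, hit, drop = FALSE])
  if (!is.numeric(m)) stop("volume columns must be numeric")
  colnames(m) <- want
  rownames(m) <- subj
  cohort_table(covs, m)
}

#' Write cohort tables to disk
#'
#' Writes `volumes.csv` and `covariates.csv` under `dir` in the layout
#' [load_cohort()] reads, preserving full double precision so that a
#' load -> write -> load round trip is value-exact.
#'
#' @param cohort A `cohort_table`.
#' @param dir Output directory (created if absent).
#' @return Named character vector of the two paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vp <- file.path(dir, "volumes.csv")
  cp <- file.path(dir, "covariates.csv")
  vol <- data.frame(subject_id = rownames(cohort$volumes),
                    cohort$volumes, check.names = FALSE)
  utils::write.csv(vol, vp, row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$covariates, cp, row.names = FALSE, quote = FALSE)
  invisible(c(volumes = vp, covariates = cp))
}

#' Interquartile-range quality check
#'
#' Flags, per group and region, volumes outside
#' `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` with linear-interpolation quartiles
#' (`stats::quantile` type 7). Flagged values are reported for inspection;
#' nothing is removed.
#'
#' @param cohort A `cohort_table`.
#' @param regions Region ids to check (default: all columns).
#' @return A `qc_report` data frame: `subject_id`, `group`, `region_id`,
#'   `value`, `lower_fence`, `upper_fence`.
#' @export
iqr_qc <- function(cohort, regions = colnames(cohort$volumes)) {
  if (!length(regions)) stop("empty region subset")
  miss <- setdiff(regions, colnames(cohort$volumes))
  if (length(miss)) stop("unknown region(s): ", paste(miss, collapse = ", "))
  if (any(table(cohort$covariates$group) < 4))
    stop("need >= 4 subjects per group for quartiles")
  out <- list()
  for (g in levels(cohort$covariates$group)) {
    idx <- cohort$covariates$group == g
    sub <- cohort$volumes[idx, regions, drop = FALSE]
    q <- apply(sub, 2, stats::quantile, probs = c(0.25, 0.75),
               names = FALSE, type = 7)
    iqr <- q[2, ] - q[1, ]
    lo <- q[1, ] - 1.5 * iqr
    hi <- q[2, ] + 1.5 * iqr
    bad <- which(sweep(sub, 2, lo, "<") | sweep(sub, 2, hi, ">"),
                 arr.ind = TRUE)
    if (nrow(bad)) {
      out[[g]] <- data.frame(
        subject_id = rownames(sub)[bad[, 1]], group = g,
        region_id = regions[bad[, 2]],
        value = sub[bad],
        lower_fence = lo[bad[, 2]], upper_fence = hi[bad[, 2]],
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  rep <- if (length(out)) do.call(rbind, out) else
    data.frame(subject_id = character(), group = character(),
               region_id = character(), value = numeric(),
               lower_fence = numeric(), upper_fence = numeric())
  rownames(rep) <- NULL
  class(rep) <- c("qc_report", "data.frame")
  rep
}

#' Write a QC report as TSV
#' @param report A `qc_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Aggregate subnuclei into composite nuclei
#'
#' Adds the six composite columns (left/right BLA, CMA, SFA), each the sum
#' of its constituent subnucleus volumes for that subject and hemisphere.
#' Existing composite columns are recomputed, so the operation is
#' idempotent; all original columns are retained.
#'
#' @param cohort A `cohort_table` containing all 18 subnucleus columns.
#' @param registry A `region_registry`.
#' @return The cohort with composite columns appended.
#' @export
aggregate_composites <- function(cohort, registry = region_registry()) {
  cons <- composite_constituents(registry)
  vols <- cohort$volumes
  vols <- vols[, setdiff(colnames(vols), names(cons)), drop = FALSE]
  for (comp in names(cons)) {
    miss <- setdiff(cons[[comp]], colnames(vols))
    if (length(miss))
      stop("missing constituent(s) for ", comp, ": ",
           paste(miss, collapse = ", "))
    vols <- cbind(vols, rowSums(vols[, cons[[comp]], drop = FALSE]))
    colnames(vols)[ncol(vols)] <- comp
  }
  cohort$volumes <- vols
  cohort
}
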