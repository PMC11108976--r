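# Canonical region inventory: 63 cortical + 24 subcortical + 18 amygdala
# subnuclei = 105 analysed regions, plus 6 composite nuclei (BLA/CMA/SFA per
# hemisphere) that are derived, never analysed as part of the 105.

.dkt_cortical <- c(
  "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus", "entorhinal",
  "fusiform", "inferiorparietal", "inferiortemporal", "isthmuscingulate",
  "lateraloccipital", "lateralorbitofrontal", "lingual", "medialorbitofrontal",
  "middletemporal", "parahippocampal", "paracentral", "parsopercularis",
  "parsorbitalis", "parstriangularis", "pericalcarine", "postcentral",
  "posteriorcingulate", "precentral", "precuneus", "rostralanteriorcingulate",
  "rostralmiddlefrontal", "superiorfrontal", "superiorparietal",
  "superiortemporal", "supramarginal", "transversetemporal", "insula")

.aseg_bilateral <- c(
  "Thalamus-Proper", "Caudate", "Putamen", "Pallidum", "Hippocampus",
  "Amygdala", "Accumbens-area", "VentralDC", "Cerebellum-Cortex")

.aseg_midline <- c("Brainstem", "CC_Posterior", "CC_Mid_Posterior",
                   "CC_Central", "CC_Mid_Anterior", "CC_Anterior")

.subnuclei <- c("anterior-amygdaloid-area", "cortico-amygdaloid-transition",
                "accessory-basal", "basal", "central", "cortical", "lateral",
                "medial", "paralaminar")

.composite_map <- c(
  "accessory-basal" = "bla", "basal" = "bla", "lateral" = "bla",
  "paralaminar" = "bla",
  "central" = "cma", "medial" = "cma",
  "anterior-amygdaloid-area" = "sfa", "cortico-amygdaloid-transition" = "sfa",
  "cortical" = "sfa")

#' Canonical region registry
#'
#' Builds the inventory of regions used throughout the pipeline: 63 cortical
#' labels (Desikan-Killiany-Tourville style), 24 subcortical labels
#' (FreeSurfer aseg style), the 18 amygdala subnuclei (nine per hemisphere),
#' and the six derived composite nuclei BLA, CMA and SFA per hemisphere.
#' The published region list is not available, so the cortical/subcortical
#' names are a count-faithful reconstruction using standard atlas labels.
#'
#' @return A `region_registry` data frame with columns `region_id`,
#'   `hemisphere` (`left`/`right`/`midline`), `region_class` (`cortical`,
#'   `subcortical`, `amygdala_subnucleus`, `amygdala_composite`) and
#'   `parent_composite` (`NA` except for subnuclei).
#' @export
#' @examples
#' reg <- region_registry()
#' table(reg$region_class)
region_registry <- function() {
  cortical <- c(paste0("ctx-lh-", .dkt_cortical),
                paste0("ctx-rh-", .dkt_cortical),
                "ctx-lh-temporalpole")
  cort_hemi <- c(rep("left", length(.dkt_cortical)),
                 rep("right", length(.dkt_cortical)), "left")
  subcort <- c(paste0("Left-", .aseg_bilateral),
               paste0("Right-", .aseg_bilateral), .aseg_midline)
  subc_hemi <- c(rep("left", length(.aseg_bilateral)),
                 rep("right", length(.aseg_bilateral)),
                 rep("midline", length(.aseg_midline)))
  subn <- c(paste0("left-", .subnuclei), paste0("right-", .subnuclei))
  subn_hemi <- rep(c("left", "right"), each = length(.subnuclei))
  subn_parent <- paste0(subn_hemi, "-", .composite_map[rep(.subnuclei, 2)])
  comp <- c(paste0("left-", c("bla", "cma", "sfa")),
            paste0("right-", c("bla", "cma", "sfa")))
  reg <- data.frame(
    region_id = c(cortical, subcort, subn, comp),
    hemisphere = c(cort_hemi, subc_hemi, subn_hemi,
                   rep(c("left", "right"), each = 3)),
    region_class = c(rep("cortical", length(cortical)),
                     rep("subcortical", length(subcort)),
                     rep("amygdala_subnucleus", length(subn)),
                     rep("amygdala_composite", length(comp))),
    parent_composite = c(rep(NA_character_,
                             length(cortical) + length(subcort)),
                         subn_parent, rep(NA_character_, length(comp))),
    stringsAsFactors = FALSE)
  stopifnot(!anyDuplicated(reg$region_id))
  class(reg) <- c("region_registry", "data.frame")
  reg
}

#' @export
print.region_registry <- function(x, ...) {
  cat("Region registry:", nrow(x), "entries\n")
  print(table(x$region_class))
  invisible(x)
}

#' Region ids by class
#'
#' Convenience selectors over a registry.
#'
#' @param registry A `region_registry`.
#' @param class One of the registry's `region_class` values.
#' @return Character vector of region ids.
#' @export
registry_ids <- function(registry, class = NULL) {
  stopifnot(inherits(registry, "region_registry"))
  if (is.null(class)) return(registry$region_id)
  registry$region_id[registry$region_class %in% class]
}

#' Measured (non-composite) regions
#'
#' The 105 regions a cohort table must supply a volume for: composites are
#' derived by [aggregate_composites()], never measured.
#'
#' @param registry A `region_registry`.
#' @return Character vector of 105 region ids.
#' @export
measured_regions <- function(registry) {
  registry_ids(registry,
               c("cortical", "subcortical", "amygdala_subnucleus"))
}

#' Covariance-profile target regions
#'
#' The regions a subnucleus profile is correlated against: every measured
#' region that is not itself part of the amygdala subnucleus system
#' (87 in the canonical registry).
#'
#' @param registry A `region_registry`.
#' @return Character vector of target region ids.
#' @export
profile_targets <- function(registry) {
  registry_ids(registry, c("cortical", "subcortical"))
}

#' Nuclei entering a given analysis
#'
#' @param registry A `region_registry`.
#' @param analysis `"three_nuclei"` (six composite nuclei) or
#'   `"nine_nuclei"` (18 individual subnuclei).
#' @return Character vector of nucleus region ids.
#' @export
analysis_nuclei <- function(registry,
                            analysis = c("three_nuclei", "nine_nuclei")) {
  analysis <- match.arg(analysis)
  cls <- if (analysis == "three_nuclei") "amygdala_composite"
         else "amygdala_subnucleus"
  registry_ids(registry, cls)
}

#' Constituents of each composite nucleus
#'
#' @param registry A `region_registry`.
#' @return Named list mapping each composite id to its subnucleus ids.
#' @export
composite_constituents <- function(registry) {
  subn <- registry[registry$region_class == "amygdala_subnucleus", ]
  split(subn$region_id, subn$parent_composite)
}

# case/sep-insensitive key used to resolve external column headers
.normalize_region_key <- function(x) {
  gsub("[^a-z0-9]+", "-", tolower(trimws(x)))
}

#' Write / read the registry as versioned JSON
#'
#' @param registry A `region_registry`.
#' @param path Output (input) file path.
#' @param version Version string recorded in the file.
#' @return `write_registry_json` returns `path` invisibly;
#'   `read_registry_json` returns a `region_registry`.
#' @export
write_registry_json <- function(registry, path, version = "1.0") {
  payload <- list(format = "scovnet-region-registry", version = version,
                  entries = registry)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_registry_json
#' @export
read_registry_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "scovnet-region-registry"))
    stop("not a scovnet region registry file: ", path)
  reg <- as.data.frame(payload$entries, stringsAsFactors = FALSE)
  reg$parent_composite[reg$parent_composite == "null"] <- NA_character_
  class(reg) <- c("region_registry", "data.frame")
  reg
}
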