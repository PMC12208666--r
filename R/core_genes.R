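# Core-gene selection: the four HVC vocal-learning contrasts, per-contrast
# gene-of-interest thresholds on module membership and trait correlation,
# strict intersection to a core set, and hypergeometric Z-chromosome
# enrichment of that set.

#' The four HVC vocal-learning contrasts
#'
#' 1. All male HVC samples against all male DN samples; 2. E2-treated female
#' HVC against all other female samples at the node (including vehicle
#' HVC); 3. vehicle-treated male HVC against vehicle-treated female HVC;
#' 4. E2-treated female HVC against vehicle-treated female HVC. The
#' vocal-capable class is coded 1 in each.
#'
#' @param samples Sample table; errors if a required sex x treatment x region
#'   cell is missing.
#' @return Named list of four [contrast_spec()] objects.
#' @export
hvc_contrast_suite <- function(samples) {
  need <- expand.grid(sex = c("male", "female"), treatment = c("vehicle", "E2"),
                      region = c("HVC", "DN"), stringsAsFactors = FALSE)
  have <- unique(samples[, c("sex", "treatment", "region")])
  miss <- !mapply(function(sx, tr, rg)
    any(have$sex == sx & have$treatment == tr & have$region == rg),
    need$sex, need$treatment, need$region)
  if (any(miss))
    .stopf("design lacks cell(s): %s",
           paste(apply(need[miss, ], 1L, paste, collapse = "/"), collapse = ", "))
  list(
    male_HVC_vs_DN = contrast_spec("male_HVC_vs_DN",
      subset = function(s) s$sex == "male" & s$region %in% c("HVC", "DN"),
      trait = function(s) s$region == "HVC"),
    E2_female_vocal_HVC = contrast_spec("E2_female_vocal_HVC",
      subset = function(s) s$sex == "female" & s$region %in% c("HVC", "DN"),
      trait = function(s) s$treatment == "E2" & s$region == "HVC"),
    vehicle_HVC_male_vs_female = contrast_spec("vehicle_HVC_male_vs_female",
      subset = function(s) s$treatment == "vehicle" & s$region == "HVC",
      trait = function(s) s$sex == "male"),
    E2_vs_vehicle_female_HVC = contrast_spec("E2_vs_vehicle_female_HVC",
      subset = function(s) s$sex == "female" & s$region == "HVC",
      trait = function(s) s$treatment == "E2")
  )
}

#' Core-gene selection criteria
#'
#' @param focal_module Label of the focal module (the HVC-specialized module).
#' @param r2_membership_min Minimum squared kME to the focal eigengene;
#'   default 0.5.
#' @param r2_trait_min Minimum squared gene-trait correlation per contrast;
#'   default 0.5.
#' @param p_max Maximum trait-correlation p-value; default 0.05.
#' @param require_positive Restrict to positive trait correlations; default
#'   FALSE (the printed criterion is r-squared based).
#' @return A list of class `selection_criteria`.
#' @export
selection_criteria <- function(focal_module, r2_membership_min = 0.5,
                               r2_trait_min = 0.5, p_max = 0.05,
                               require_positive = FALSE) {
  stopifnot(r2_membership_min > 0, r2_membership_min <= 1,
            r2_trait_min > 0, r2_trait_min <= 1, p_max > 0, p_max <= 1)
  structure(list(focal_module = focal_module,
                 r2_membership_min = r2_membership_min,
                 r2_trait_min = r2_trait_min, p_max = p_max,
                 require_positive = require_positive),
            class = "selection_criteria")
}

#' Genes of interest per contrast
#'
#' A gene qualifies in a contrast iff its trait-correlation p <= `p_max`, its
#' trait r-squared >= `r2_trait_min`, and its squared membership (kME^2) in
#' the focal module >= `r2_membership_min`.
#'
#' @param kme_focal Named numeric vector: gene -> kME to the focal eigengene.
#' @param gene_assoc Named list of per-contrast gene association tables (from
#'   [associate_genes()]), all covering the same genes.
#' @param criteria A [selection_criteria()] list.
#' @return Named list of per-contrast gene-id vectors.
#' @export
select_genes_of_interest <- function(kme_focal, gene_assoc, criteria) {
  lapply(gene_assoc, function(tbl) {
    km <- kme_focal[tbl$gene_id]
    ok <- !is.na(tbl$p) & tbl$p <= criteria$p_max &
      !is.na(tbl$r2) & tbl$r2 >= criteria$r2_trait_min &
      !is.na(km) & km^2 >= criteria$r2_membership_min
    if (isTRUE(criteria$require_positive)) ok <- ok & tbl$r > 0
    sort(tbl$gene_id[ok])
  })
}

#' Core genes: strict intersection of the four contrast sets
#'
#' @param per_contrast_sets List of exactly 4 gene-id vectors.
#' @return Sorted character vector of core gene ids.
#' @export
core_gene_intersection <- function(per_contrast_sets) {
  if (length(per_contrast_sets) != 4L)
    .stopf("core-gene intersection expects exactly 4 contrast sets, got %d",
           length(per_contrast_sets))
  sort(Reduce(intersect, per_contrast_sets))
}

#' Z-chromosome enrichment of the core gene set
#'
#' Upper-tailed hypergeometric test treating each core gene as a draw without
#' replacement from the background. Reported for both backgrounds: all
#' module-assigned genes and the focal module's members.
#'
#' @param core Character vector of core gene ids.
#' @param assignment Named gene -> module vector.
#' @param genes Gene table (supplies `chromosome`).
#' @param focal_module Focal module label.
#' @return Named list of [hypergeometric_enrichment()] results for the
#'   `all_assigned` and `focal_module` backgrounds.
#' @export
core_z_enrichment <- function(core, assignment, genes, focal_module) {
  is_z <- function(ids) genes$chromosome[match(ids, genes$gene_id)] == "Z"
  run <- function(background, core_bg) {
    miss <- setdiff(core_bg, background)
    if (length(miss))
      .stopf("core gene(s) outside the background: %s",
             paste(utils::head(miss, 3L), collapse = ", "))
    if (!length(core_bg)) return(NULL)
    hypergeometric_enrichment(
      k = sum(is_z(core_bg)), n = length(core_bg),
      K = sum(is_z(background)), N = length(background))
  }
  assigned <- names(assignment)[assignment != UNASSIGNED]
  focal <- names(assignment)[assignment == focal_module]
  # against the focal-module background only its own members are draws
  list(all_assigned = run(assigned, core),
       focal_module = run(focal, intersect(core, focal)))
}
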