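# Sex-chromosome dosage analysis: per-gene male expression fraction against
# copy-number predictions, per-region one-tailed sex tests, and cross-region
# set intersections.
#
# ZW system: males are ZZ, females ZW. Without compensation the copy-number
# model predicts a 2/3 male share of Z expression and a zero male share of W
# expression; autosomes predict 1/2.

#' Copy-number-predicted male expression fraction
#'
#' `male_copies / (male_copies + female_copies)`: Z -> 2/3 (printed as
#' 66.6%), W -> 0, autosome -> 1/2. Exact rational arithmetic.
#'
#' @param chromosome_class `"Z"`, `"W"`, or `"autosome"` (vectorized).
#' @return Numeric vector of predicted fractions.
#' @export
predicted_fraction <- function(chromosome_class) {
  pred <- c(Z = 2 / 3, W = 0, autosome = 1 / 2)
  bad <- setdiff(unique(chromosome_class), names(pred))
  if (length(bad)) .stopf("unknown chromosome class(es): %s", paste(bad, collapse = ", "))
  unname(pred[chromosome_class])
}

# Map chromosome labels to dosage classes.
.chrom_class <- function(chromosome) {
  ifelse(chromosome == "Z", "Z", ifelse(chromosome == "W", "W", "autosome"))
}

#' Per-gene male expression fraction
#'
#' For each gene: average FPKM over the male samples of each region, average
#' those region means, likewise for females, then
#' `male_fraction = male_avg / (male_avg + female_avg)`. Region averaging
#' precedes the fraction. Genes with zero total expression get `NA`, never
#' 0/0.
#'
#' @param em Genes x samples expression matrix (FPKM).
#' @param samples Sample table.
#' @param genes Gene table (supplies `chromosome`).
#' @param regions Regions to average over; default the four surrounds.
#' @param treatment Treatment subset; default `"vehicle"`.
#' @param assignment Optional named gene -> module vector to annotate records.
#' @return Data.frame with `gene_id`, `chromosome_class`, `male_avg`,
#'   `female_avg`, `male_fraction`, `predicted_fraction`, `total_expression`,
#'   `module`.
#' @export
male_expression_fraction <- function(em, samples, genes,
                                     regions = c("DN", "LAI", "AN", "Str"),
                                     treatment = "vehicle",
                                     assignment = NULL) {
  sel <- samples$region %in% regions & samples$treatment %in% treatment
  sub <- samples[sel, , drop = FALSE]
  if (length(unique(sub$sex)) < 2L)
    .stopf("both sexes must be represented in the filtered sample set")
  region_sex_mean <- function(sx) {
    cols <- lapply(regions, function(rg) {
      ids <- sub$sample_id[sub$sex == sx & sub$region == rg]
      ids <- intersect(ids, colnames(em))
      if (!length(ids)) return(NULL)
      rowMeans(em[, ids, drop = FALSE])
    })
    cols <- Filter(Negate(is.null), cols)
    if (!length(cols)) .stopf("no %s samples in the requested regions", sx)
    rowMeans(do.call(cbind, cols))
  }
  male_avg <- region_sex_mean("male")
  female_avg <- region_sex_mean("female")
  total <- male_avg + female_avg
  cls <- .chrom_class(genes$chromosome[match(rownames(em), genes$gene_id)])
  data.frame(
    gene_id = rownames(em),
    chromosome_class = cls,
    male_avg = male_avg,
    female_avg = female_avg,
    male_fraction = ifelse(total > 0, male_avg / total, NA_real_),
    predicted_fraction = predicted_fraction(cls),
    total_expression = total,
    module = if (is.null(assignment)) NA_character_ else
      unname(assignment[rownames(em)]),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Summarize dosage records by module and chromosome class
#'
#' Mean, median, and expression-weighted mean male fraction per (module,
#' class) cell, with a `compensated` flag when the class mean deviates from
#' the copy-number prediction by more than `margin`.
#'
#' @param records Output of [male_expression_fraction()].
#' @param margin Deviation margin for the compensation flag; default 0.1.
#' @return A data.frame, one row per non-empty (module, class) cell.
#' @export
summarize_dosage_by_module <- function(records, margin = 0.1) {
  if (!nrow(records)) .stopf("no dosage records")
  rec <- records[!is.na(records$male_fraction), , drop = FALSE]
  rec$module[is.na(rec$module)] <- "(none)"
  key <- interaction(rec$module, rec$chromosome_class, drop = TRUE)
  rows <- lapply(levels(key), function(kk) {
    r <- rec[key == kk, , drop = FALSE]
    w <- r$total_expression / sum(r$total_expression)
    data.frame(
      module = r$module[1L],
      chromosome_class = r$chromosome_class[1L],
      n_genes = nrow(r),
      mean_fraction = mean(r$male_fraction),
      median_fraction = stats::median(r$male_fraction),
      weighted_mean_fraction = sum(w * r$male_fraction),
      predicted_fraction = r$predicted_fraction[1L],
      compensated = abs(mean(r$male_fraction) - r$predicted_fraction[1L]) > margin,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Per-region one-tailed sex tests on sex-chromosome genes
#'
#' Within each region's sample subset (default: vehicle-treated birds), each
#' W gene is tested upper-tailed and each Z gene lower-tailed against sex
#' coded female = 1, so expressed W genes correlate positively and
#' male-biased Z genes negatively. Genes with zero total expression in a
#' region are excluded from that region's tests. Raw alpha, no correction,
#' unless `correct = TRUE` applies Benjamini-Hochberg within each (region,
#' chromosome) family.
#'
#' @param em Genes x samples expression matrix.
#' @param samples Sample table.
#' @param genes Gene table (supplies `chromosome`).
#' @param alpha Significance level; default 0.05.
#' @param regions Regions tested; default the four surrounds.
#' @param treatment Treatment subset; default `"vehicle"`.
#' @param correct Apply BH within each region x chromosome family; default
#'   FALSE.
#' @return A list of class `regional_sex_sets`: per region, character vectors
#'   `significant_W_expressed` and `significant_Z_depleted`.
#' @export
regional_sex_tests <- function(em, samples, genes, alpha = 0.05,
                               regions = c("DN", "LAI", "AN", "Str"),
                               treatment = "vehicle", correct = FALSE) {
  stopifnot(alpha >= 0, alpha <= 1)
  cls <- .chrom_class(genes$chromosome[match(rownames(em), genes$gene_id)])
  w_genes <- rownames(em)[cls == "W"]
  z_genes <- rownames(em)[cls == "Z"]
  out <- list()
  for (rg in regions) {
    ids <- samples$sample_id[samples$region == rg & samples$treatment %in% treatment]
    ids <- intersect(ids, colnames(em))
    if (!length(ids)) { .warnf("region %s has no samples; skipped", rg); next }
    sx <- samples$sex[match(ids, samples$sample_id)]
    if (length(unique(sx)) < 2L) { .warnf("region %s lacks one sex; skipped", rg); next }
    female <- as.numeric(sx == "female")
    test_set <- function(gs, tail) {
      if (!length(gs)) return(character(0))
      X <- em[gs, ids, drop = FALSE]
      expressed <- rowSums(X) > 0
      gs <- gs[expressed]
      if (!length(gs)) return(character(0))
      r <- .cor_vec(t(em[gs, ids, drop = FALSE]), female)
      p <- .cor_p(r, length(ids), tail)
      if (correct) p <- bh_fdr(ifelse(is.na(p), 1, p))
      gs[!is.na(p) & p < alpha]
    }
    out[[rg]] <- list(
      significant_W_expressed = test_set(w_genes, "upper"),
      significant_Z_depleted = test_set(z_genes, "lower")
    )
  }
  structure(out, class = "regional_sex_sets")
}

#' Union and intersection of regional sex-test gene sets
#'
#' @param sets A `regional_sex_sets` list from [regional_sex_tests()]
#'   (>= 2 regions).
#' @return A list per chromosome side (`W_expressed`, `Z_depleted`) with
#'   `union`, `intersection`, per-region counts, and the pairwise
#'   intersection-count matrix.
#' @export
region_set_overlap <- function(sets) {
  if (length(sets) < 2L) .stopf("set overlap needs >= 2 regions")
  summarize <- function(field) {
    by_region <- lapply(sets, `[[`, field)
    uni <- sort(Reduce(union, by_region))
    inter <- sort(Reduce(intersect, by_region))
    nms <- names(by_region)
    pair <- outer(seq_along(by_region), seq_along(by_region),
                  Vectorize(function(i, j) length(intersect(by_region[[i]], by_region[[j]]))))
    dimnames(pair) <- list(nms, nms)
    list(union = uni, intersection = inter,
         n_union = length(uni), n_intersection = length(inter),
         n_per_region = vapply(by_region, length, integer(1L)),
         pairwise = pair)
  }
  list(W_expressed = summarize("significant_W_expressed"),
       Z_depleted = summarize("significant_Z_depleted"))
}
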