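# End-to-end orchestration: normalize -> filter -> outlier QC -> network ->
# reassignment -> overfit flagging -> trait association -> chromosome
# enrichment -> dosage -> core genes, with a JSON-able run manifest.

#' Cross-check pipeline inputs
#'
#' Checks id consistency between the count matrix, gene table, and sample
#' table, design completeness, and chromosome labels. Failures are collected
#' into the report rather than thrown.
#'
#' @param counts Genes x samples count matrix.
#' @param genes Gene table.
#' @param samples Sample table.
#' @return A list with `ok` (logical) and `failures` (character vector).
#' @export
validate_inputs <- function(counts, genes, samples) {
  failures <- character(0)
  add <- function(msg) failures <<- c(failures, msg)
  missing_genes <- setdiff(rownames(counts), genes$gene_id)
  if (length(missing_genes))
    add(sprintf("gene(s) in counts missing from gene table: %s",
                paste(utils::head(missing_genes, 5L), collapse = ", ")))
  missing_samples <- setdiff(colnames(counts), samples$sample_id)
  if (length(missing_samples))
    add(sprintf("sample(s) in counts missing from sample table: %s",
                paste(utils::head(missing_samples, 5L), collapse = ", ")))
  no_chrom <- genes$gene_id[is.na(genes$chromosome) | !nzchar(genes$chromosome)]
  if (length(no_chrom))
    add(sprintf("gene(s) without chromosome label: %s",
                paste(utils::head(no_chrom, 5L), collapse = ", ")))
  bad_len <- genes$gene_id[!is.finite(genes$length_bp) | genes$length_bp <= 0]
  if (length(bad_len))
    add(sprintf("gene(s) with invalid length_bp: %s",
                paste(utils::head(bad_len, 5L), collapse = ", ")))
  tab <- samples[samples$sample_id %in% colnames(counts), , drop = FALSE]
  cells <- unique(tab[, c("sex", "treatment")])
  if (nrow(cells) < 4L)
    add("design does not cover all four sex x treatment groups")
  list(ok = length(failures) == 0L, failures = failures)
}

#' Pipeline configuration
#'
#' Bundles data, thresholds, and the seed for [run_pipeline()]. Default
#' thresholds are the published analysis values: soft-threshold power 6,
#' minimum module size 100, 50000 enrichment permutations, r-squared
#' thresholds of 0.5 for core-gene membership and trait correlation, alpha
#' 0.05.
#'
#' @param counts,genes,samples In-memory inputs, or paths to their TSVs.
#' @param network A [network_params()] list.
#' @param n_perm Chromosome-enrichment permutations; default 50000.
#' @param min_fpkm,min_fraction Expression filter; defaults 1 FPKM in >= 25%
#'   of samples.
#' @param outlier_z Outlier-sample z threshold; default 2.5.
#' @param alpha Association significance level; default 0.05.
#' @param r2_membership_min,r2_trait_min Core-gene thresholds; defaults 0.5.
#' @param focal_module Focal module label for core-gene selection, or `NULL`
#'   to pick the module whose eigengene associates most strongly with the
#'   four HVC vocal-learning contrasts.
#' @param out_dir Output directory for TSV intermediates and the manifest, or
#'   `NULL` to keep everything in memory.
#' @param seed Master seed; every stochastic stage derives its seed from it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(counts, genes, samples,
                            network = network_params(),
                            n_perm = 50000L, min_fpkm = 1, min_fraction = 0.25,
                            outlier_z = 2.5, alpha = 0.05,
                            r2_membership_min = 0.5, r2_trait_min = 0.5,
                            focal_module = NULL, out_dir = NULL, seed = 1L) {
  if (is.character(counts)) counts <- read_count_matrix(counts)
  if (is.character(genes)) genes <- read_gene_table(genes)
  if (is.character(samples)) samples <- read_sample_table(samples)
  structure(list(counts = counts, genes = genes,
                 samples = validate_sample_table(samples),
                 network = network, n_perm = as.integer(n_perm),
                 min_fpkm = min_fpkm, min_fraction = min_fraction,
                 outlier_z = outlier_z, alpha = alpha,
                 r2_membership_min = r2_membership_min,
                 r2_trait_min = r2_trait_min, focal_module = focal_module,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes, in order: input validation, FPKM normalization, expression
#' filtering, outlier-sample removal, unsigned network construction and
#' module detection (correlations on log2(FPKM + 1)), iterative gene
#' reassignment, overfit-module flagging, module-trait association over the
#' built-in contrast presets, bootstrap chromosome enrichment, sex-chromosome
#' dosage analysis, and four-contrast core-gene selection. A stage failure
#' aborts with the stage name; completed intermediates are retained in the
#' returned object (and on disk when `out_dir` is set).
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_result` with per-stage outputs and a
#'   `manifest` recording parameters, seed, and per-stage counts.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  res <- list()
  stages <- character(0)
  counts_by_stage <- list()
  run_stage <- function(name, fn) {
    out <- tryCatch(fn(), error = function(e)
      .stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    stages <<- c(stages, name)
    out
  }

  report <- run_stage("validate", function()
    validate_inputs(config$counts, config$genes, config$samples))
  if (!report$ok)
    .stopf("pipeline stage 'validate' failed: %s",
           paste(report$failures, collapse = "; "))
  res$validation <- report

  res$fpkm <- run_stage("normalize", function()
    fpkm_normalize(config$counts, config$genes))
  counts_by_stage$genes_input <- nrow(res$fpkm)

  res$fpkm_filtered <- run_stage("filter", function()
    filter_expressed(res$fpkm, config$min_fpkm, config$min_fraction))
  counts_by_stage$genes_expressed <- nrow(res$fpkm_filtered)

  res$outliers <- run_stage("qc_outliers", function()
    detect_outlier_samples(log2(res$fpkm_filtered + 1), z_cut = config$outlier_z))
  keep <- setdiff(colnames(res$fpkm_filtered), res$outliers)
  res$fpkm_clean <- res$fpkm_filtered[, keep, drop = FALSE]
  samples <- config$samples[config$samples$sample_id %in% keep, , drop = FALSE]
  res$samples <- samples
  counts_by_stage$samples_removed <- length(res$outliers)
  counts_by_stage$samples_retained <- length(keep)

  logem <- log2(res$fpkm_clean + 1)
  sds <- apply(logem, 1L, stats::sd)
  logem <- logem[sds > 0, , drop = FALSE]
  res$log_expression <- logem

  assignment0 <- run_stage("network", function() {
    adj <- adjacency_matrix(logem, beta = config$network$beta)
    tom <- topological_overlap(adj)
    detect_modules(tom, config$network)
  })
  counts_by_stage$modules_initial <-
    length(setdiff(unique(assignment0), UNASSIGNED))

  res$decomposition <- run_stage("reassign", function()
    reassign_genes(logem, assignment0, reassign_p = config$network$reassign_p))
  counts_by_stage$modules_after_reassignment <- nrow(res$decomposition$eigengenes)
  counts_by_stage$genes_assigned <-
    sum(res$decomposition$assignment != UNASSIGNED)

  res$decomposition$excluded_modules <- run_stage("flag_overfit", function()
    flag_overfit_modules(res$decomposition$eigengenes, samples))
  res$bird_attribution <- attribute_modules_to_birds(
    res$decomposition$eigengenes, samples)
  counts_by_stage$modules_excluded <- length(res$decomposition$excluded_modules)
  counts_by_stage$modules_retained <- counts_by_stage$modules_after_reassignment -
    counts_by_stage$modules_excluded

  res$module_associations <- run_stage("associate", function() {
    tabs <- lapply(contrast_presets(), function(spec)
      associate_modules(res$decomposition$eigengenes, samples, spec,
                        alpha = config$alpha,
                        exclude = res$decomposition$excluded_modules))
    do.call(rbind, c(tabs, make.row.names = FALSE))
  })

  res$chromosome_enrichment <- run_stage("enrich", function()
    chromosome_module_enrichment(res$decomposition$assignment, config$genes,
                                 n_perm = config$n_perm,
                                 seed = .derive_seed(config$seed, "enrich")))

  res$dosage <- run_stage("dosage", function() {
    records <- male_expression_fraction(res$fpkm_clean, samples, config$genes,
                                        assignment = res$decomposition$assignment)
    sets <- regional_sex_tests(logem, samples, config$genes, alpha = config$alpha)
    list(records = records,
         by_module = summarize_dosage_by_module(records),
         regional_sets = sets,
         overlap = if (length(sets) >= 2L) region_set_overlap(sets) else NULL)
  })

  res$core <- run_stage("core_genes", function() {
    suite <- hvc_contrast_suite(samples)
    focal <- config$focal_module
    if (is.null(focal)) {
      retained <- setdiff(rownames(res$decomposition$eigengenes),
                          res$decomposition$excluded_modules)
      score <- vapply(suite, function(spec) {
        a <- associate_modules(res$decomposition$eigengenes, samples, spec,
                               exclude = res$decomposition$excluded_modules)
        stats::setNames(a$r2, a$module)[retained]
      }, numeric(length(retained)))
      focal <- retained[which.max(rowMeans(score))]
    }
    criteria <- selection_criteria(focal,
                                   r2_membership_min = config$r2_membership_min,
                                   r2_trait_min = config$r2_trait_min,
                                   p_max = config$alpha)
    gene_assoc <- lapply(suite, function(spec)
      associate_genes(logem, samples, spec))
    sets <- select_genes_of_interest(res$decomposition$kme[, focal], gene_assoc,
                                     criteria)
    core <- core_gene_intersection(sets)
    z <- core_z_enrichment(core, res$decomposition$assignment, config$genes,
                           focal_module = focal)
    list(focal_module = focal, criteria = criteria, per_contrast = sets,
         core = core, z_enrichment = z)
  })
  counts_by_stage$core_genes <- length(res$core$core)

  res$manifest <- list(
    package = "songmod",
    version = as.character(utils::packageVersion("songmod")),
    seed = config$seed,
    parameters = list(
      beta = config$network$beta,
      min_module_size = config$network$min_module_size,
      cut_height = config$network$cut_height,
      reassign_p = config$network$reassign_p,
      n_perm = config$n_perm,
      min_fpkm = config$min_fpkm,
      min_fraction = config$min_fraction,
      outlier_z = config$outlier_z,
      alpha = config$alpha,
      r2_membership_min = config$r2_membership_min,
      r2_trait_min = config$r2_trait_min,
      focal_module = res$core$focal_module
    ),
    stages = stages,
    counts = counts_by_stage
  )

  if (!is.null(config$out_dir)) .write_pipeline_outputs(res, config$out_dir)
  structure(res, class = "pipeline_result")
}

.write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  .write_matrix_tsv(res$fpkm_clean, file.path(out_dir, "fpkm.tsv"))
  utils::write.table(
    data.frame(gene_id = names(res$decomposition$assignment),
               module = unname(res$decomposition$assignment)),
    file.path(out_dir, "modules.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  .write_matrix_tsv(res$decomposition$eigengenes,
                    file.path(out_dir, "eigengenes.tsv"), id_col = "module")
  .write_matrix_tsv(res$decomposition$kme, file.path(out_dir, "kme.tsv"))
  utils::write.table(res$module_associations,
                     file.path(out_dir, "module_associations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$chromosome_enrichment,
                     file.path(out_dir, "chromosome_enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$dosage$records, file.path(out_dir, "dosage_records.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(res$core$core, file.path(out_dir, "core_genes.txt"))
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("songmod pipeline result\n")
  cat("  genes expressed:", x$manifest$counts$genes_expressed, "\n")
  cat("  outlier samples removed:", x$manifest$counts$samples_removed, "\n")
  cat("  modules retained:", x$manifest$counts$modules_retained,
      "(of", x$manifest$counts$modules_after_reassignment, "detected)\n")
  cat("  focal module:", x$core$focal_module,
      "| core genes:", length(x$core$core), "\n")
  invisible(x)
}
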