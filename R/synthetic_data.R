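# Synthetic-data generator emulating the study design: 2 sexes x 2 treatments
# x n birds x 8 regions, planted co-expression modules with region/sex/
# treatment-specific expression, Z/W dosage classes, and injectable artifacts
# (outlier samples, bird-specific modules), with full ground truth for
# recovery testing.
#
# Count model: lognormal-Poisson. Per-gene baseline fragment weights are
# lognormal; planted-module members multiply their baseline by
# exp(effect * eigengene + noise) where the module's latent eigengene is its
# design pattern plus sample-level noise; per-sample rates are scaled so each
# library's expected size equals library_size_mean; counts are Poisson.
# Planted-module (and sex-chromosome, and bird-block) genes are drawn at
# moderate abundance while the unstructured background pool is a stable
# high-abundance majority of the library, keeping planted on/off folds small
# relative to total library mass so FPKM normalization stays well behaved.

#' Default planted-module plan
#'
#' Five modules emulating the study's headline patterns: an Area X/striatum
#' module, an RA (arcopallium) module, an LMAN module, an HVC vocal-learning
#' module (high in male HVC and in E2-treated female HVC), and a male-biased
#' module that the sex-chromosome genes attach to. Effects are natural-log
#' fold amplitudes separating pattern-on from pattern-off samples.
#'
#' @return A list of module plan entries (`label`, `size`, `effect`,
#'   `pattern`, `attach_sex_chromosomes`).
#' @export
default_module_plan <- function() {
  list(
    list(label = "areax_str", size = 300L, effect = 2,
         pattern = function(s) s$region %in% c("AreaX", "Str")),
    list(label = "ra", size = 250L, effect = 2,
         pattern = function(s) s$region == "RA"),
    list(label = "lman", size = 200L, effect = 2,
         pattern = function(s) s$region == "LMAN"),
    list(label = "hvc_vocal", size = 150L, effect = 3,
         pattern = function(s) (s$sex == "male" & s$region == "HVC") |
           (s$sex == "female" & s$treatment == "E2" & s$region == "HVC")),
    list(label = "sexZW", size = 120L, effect = 1.2,
         pattern = function(s) s$sex == "male",
         attach_sex_chromosomes = TRUE)
  )
}

#' Simulation configuration
#'
#' Defaults encode the emulated study design: 3 birds per sex x treatment
#' group, all 8 circuit regions per bird (96 samples), 2000 genes with the
#' [default_module_plan()], 5% of genes on Z (half dosage-compensated), 1%
#' on W (female-only), two injectable outlier samples and one bird-specific
#' module.
#'
#' @param n_birds_per_group Birds per sex x treatment cell; default 3.
#' @param regions Regions sampled per bird; default the full 8-region grid.
#' @param n_genes Total genes; default 2000.
#' @param module_plan Planted-module plan; default [default_module_plan()].
#' @param z_fraction,w_fraction Fractions of genes on Z / W; defaults 0.05 /
#'   0.01.
#' @param z_compensated_fraction Fraction of Z genes simulated sex-equal;
#'   default 0.5.
#' @param w_leakage Male paralog-leakage factor for W genes in `[0, 1]`;
#'   default 0 (W genes absent in males).
#' @param noise_sd Per-gene lognormal dispersion (natural-log SD); default
#'   0.2.
#' @param module_latent_sd Sample-level SD of each module's latent eigengene
#'   around its design pattern; default 0.05.
#' @param library_size_mean Expected fragments per sample; default 3e7.
#' @param outlier_samples Outlier samples injected by [inject_artifacts()];
#'   default 2.
#' @param bird_specific_modules Bird-marking gene blocks injected by
#'   [inject_artifacts()]; default 1.
#' @param bird_module_size,bird_module_effect Size and log-fold elevation of
#'   each bird block; defaults 120 and 2.
#' @param seed Mandatory integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_birds_per_group = 3L, n_genes = 2000L,
                       regions = region_pairing()$region,
                       module_plan = default_module_plan(),
                       z_fraction = 0.05, w_fraction = 0.01,
                       z_compensated_fraction = 0.5, w_leakage = 0,
                       noise_sd = 0.2, module_latent_sd = 0.05,
                       library_size_mean = 3e7,
                       outlier_samples = 2L, bird_specific_modules = 1L,
                       bird_module_size = 120L, bird_module_effect = 2,
                       seed) {
  if (missing(seed)) .stopf("sim_config requires an explicit seed")
  stopifnot(n_birds_per_group >= 1, n_genes >= 1,
            z_fraction >= 0, z_fraction <= 1, w_fraction >= 0, w_fraction <= 1,
            z_compensated_fraction >= 0, z_compensated_fraction <= 1,
            w_leakage >= 0, w_leakage <= 1, noise_sd >= 0,
            library_size_mean > 0, outlier_samples >= 0,
            bird_specific_modules >= 0)
  bad_regions <- setdiff(regions, region_pairing()$region)
  if (length(bad_regions))
    .stopf("unknown region(s): %s", paste(bad_regions, collapse = ", "))
  structure(list(
    n_birds_per_group = as.integer(n_birds_per_group),
    regions = regions,
    n_genes = as.integer(n_genes), module_plan = module_plan,
    z_fraction = z_fraction, w_fraction = w_fraction,
    z_compensated_fraction = z_compensated_fraction, w_leakage = w_leakage,
    noise_sd = noise_sd, module_latent_sd = module_latent_sd,
    library_size_mean = library_size_mean,
    outlier_samples = as.integer(outlier_samples),
    bird_specific_modules = as.integer(bird_specific_modules),
    bird_module_size = as.integer(bird_module_size),
    bird_module_effect = bird_module_effect,
    seed = as.integer(seed)), class = "sim_config")
}

#' Simulate the sample design
#'
#' 2 sexes x 2 treatments x `n_birds_per_group` birds x 8 regions. Every bird
#' contributes all 8 regions; the vehicle-female Area X row stands for the
#' striatal placeholder taken where Area X would be.
#'
#' @param config A [sim_config()].
#' @return A sample table data.frame.
#' @export
simulate_design <- function(config) {
  pairing <- region_pairing()
  grid <- expand.grid(
    region = intersect(pairing$region, config$regions),
    bird = seq_len(config$n_birds_per_group),
    treatment = c("vehicle", "E2"),
    sex = c("male", "female"),
    stringsAsFactors = FALSE
  )
  bird_id <- sprintf("%s_%s_%d", ifelse(grid$sex == "male", "M", "F"),
                     ifelse(grid$treatment == "vehicle", "veh", "E2"), grid$bird)
  df <- data.frame(
    sample_id = paste(bird_id, grid$region, sep = "."),
    bird_id = bird_id,
    sex = grid$sex,
    treatment = grid$treatment,
    region = grid$region,
    stringsAsFactors = FALSE
  )
  validate_sample_table(df)
}

#' Simulate a structured count dataset
#'
#' Generates the count matrix, gene table, sample table, and ground-truth
#' labels under the configured generative model. Sex-chromosome genes carry
#' their dose effects only (uncompensated Z: 2x in males; W: female-only with
#' optional `w_leakage` male paralog leakage); uncompensated-Z and W genes
#' carry the sex module's truth label (their dosage-driven dimorphism is the
#' module signal), compensated Z genes are unstructured. Artifact gene blocks
#' for [inject_artifacts()] are reserved but not yet elevated. Fully
#' reproducible given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list of class `songmod_sim`: `counts`, `genes`, `samples`,
#'   `truth`, `config`.
#' @export
simulate_expression <- function(config) {
  set.seed(.derive_seed(config$seed, "expression"))
  samples <- simulate_design(config)
  ns <- nrow(samples)
  ng <- config$n_genes
  plan <- config$module_plan
  plan_sizes <- vapply(plan, function(pl) as.integer(pl$size), integer(1L))
  n_z <- round(config$z_fraction * ng)
  n_w <- round(config$w_fraction * ng)
  n_reserve <- config$bird_specific_modules * config$bird_module_size
  n_structured <- sum(plan_sizes) + n_z + n_w + n_reserve
  if (n_structured > ng)
    .stopf("module plan + sex chromosomes + artifact reserves need %d genes but n_genes = %d",
           n_structured, ng)

  gene_ids <- sprintf("g%05d", seq_len(ng))
  length_bp <- round(exp(stats::runif(ng, log(300), log(10000))))

  # Gene allocation, in blocks: planted modules, Z, W, artifact reserves,
  # then the unstructured background pool.
  module <- rep(UNASSIGNED, ng)
  offset <- 0L
  plan_idx <- vector("list", length(plan))
  for (i in seq_along(plan)) {
    plan_idx[[i]] <- offset + seq_len(plan_sizes[i])
    module[plan_idx[[i]]] <- plan[[i]]$label
    offset <- offset + plan_sizes[i]
  }
  z_idx <- offset + seq_len(n_z); offset <- offset + n_z
  w_idx <- offset + seq_len(n_w); offset <- offset + n_w
  reserve_idx <- if (n_reserve > 0) offset + seq_len(n_reserve) else integer(0)
  offset <- offset + n_reserve
  background_idx <- setdiff(seq_len(ng), seq_len(offset))

  n_z_comp <- round(config$z_compensated_fraction * n_z)
  z_comp_idx <- z_idx[seq_len(n_z_comp)]
  z_unc_idx <- setdiff(z_idx, z_comp_idx)

  dosage_class <- rep("autosome", ng)
  dosage_class[z_unc_idx] <- "Z_uncompensated"
  dosage_class[z_comp_idx] <- "Z_compensated"
  dosage_class[w_idx] <- "W"

  sex_module <- NULL
  for (pl in plan) if (isTRUE(pl$attach_sex_chromosomes)) sex_module <- pl$label
  if (!is.null(sex_module)) module[c(z_unc_idx, w_idx)] <- sex_module

  chromosome <- sample(c("1", "1A", "2", "3", "4", "4A", "5", "6", "7", "8"),
                       ng, replace = TRUE)
  chromosome[z_idx] <- "Z"
  chromosome[w_idx] <- "W"

  # Baselines are expression-scale (FPKM-like); fragment weights multiply by
  # exonic length so counts, not FPKM, scale with gene length. Structured
  # genes sit at moderate abundance; the unstructured background pool is a
  # stable high-abundance majority of the library, as the unsimulated
  # remainder of a real transcriptome is.
  baseline <- numeric(ng)
  structured <- c(unlist(plan_idx), z_idx, w_idx, reserve_idx)
  baseline[structured] <- stats::rlnorm(length(structured), log(28), 0.4)
  baseline[background_idx] <- stats::rlnorm(length(background_idx), log(4000), 0.5)

  # Latent eigengenes and member log-fold factors.
  logf <- matrix(0, ng, ns)
  latents <- matrix(NA_real_, length(plan), ns,
                    dimnames = list(vapply(plan, `[[`, character(1L), "label"), NULL))
  for (i in seq_along(plan)) {
    pat <- as.numeric(plan[[i]]$pattern(samples))
    eig <- pat + stats::rnorm(ns, 0, config$module_latent_sd)
    latents[i, ] <- eig
    logf[plan_idx[[i]], ] <- rep(plan[[i]]$effect * eig, each = plan_sizes[i])
  }

  eps <- matrix(stats::rnorm(ng * ns, 0, config$noise_sd), ng, ns)
  w <- baseline * length_bp * exp(logf + eps)

  male_col <- samples$sex == "male"
  w[z_unc_idx, male_col] <- 2 * w[z_unc_idx, male_col]
  w[w_idx, male_col] <- config$w_leakage * w[w_idx, male_col]
  w[w_idx, !male_col] <- w[w_idx, !male_col]

  lambda <- sweep(w, 2L, colSums(w), "/") * config$library_size_mean
  counts <- matrix(stats::rpois(ng * ns, lambda), ng, ns,
                   dimnames = list(gene_ids, samples$sample_id))

  genes <- data.frame(gene_id = gene_ids, chromosome = chromosome,
                      length_bp = length_bp, stringsAsFactors = FALSE)
  truth <- list(
    module = stats::setNames(module, gene_ids),
    dosage_class = stats::setNames(dosage_class, gene_ids),
    planted_effects = data.frame(
      label = vapply(plan, `[[`, character(1L), "label"),
      size = plan_sizes,
      effect = vapply(plan, `[[`, numeric(1L), "effect"),
      stringsAsFactors = FALSE),
    latents = latents,
    reserved_bird_blocks = if (n_reserve > 0)
      split(gene_ids[reserve_idx],
            rep(seq_len(config$bird_specific_modules),
                each = config$bird_module_size)) else list(),
    outlier_samples = character(0),
    bird_modules = list()
  )
  structure(list(counts = counts, genes = genes, samples = samples,
                 truth = truth, config = config), class = "songmod_sim")
}

#' Inject technical artifacts into a simulated dataset
#'
#' Adds (a) outlier samples, whose counts are replaced by an independent
#' lognormal-Poisson noise profile unrelated to the planted structure, and
#' (b) bird-specific modules: each reserved gene block is elevated
#' `exp(bird_module_effect)`-fold in all samples of one bird. Ground truth is
#' updated (`outlier_samples`, `bird_modules`, and the blocks' truth module
#' labels). With zero configured artifacts the dataset is returned unchanged.
#'
#' @param sim A `songmod_sim` from [simulate_expression()].
#' @param config Artifact configuration; defaults to `sim$config`.
#' @return The mutated `songmod_sim`.
#' @export
inject_artifacts <- function(sim, config = sim$config) {
  ns <- ncol(sim$counts)
  if (config$outlier_samples > ns)
    .stopf("cannot inject %d outliers into %d samples", config$outlier_samples, ns)
  set.seed(.derive_seed(config$seed, "artifacts"))
  if (config$outlier_samples > 0L) {
    out_cols <- sample.int(ns, config$outlier_samples)
    for (j in out_cols) {
      wj <- stats::rlnorm(nrow(sim$counts), log(100), 1.5)
      lam <- wj / sum(wj) * config$library_size_mean
      sim$counts[, j] <- stats::rpois(nrow(sim$counts), lam)
    }
    sim$truth$outlier_samples <- colnames(sim$counts)[out_cols]
  }
  n_blocks <- min(config$bird_specific_modules, length(sim$truth$reserved_bird_blocks))
  if (n_blocks > 0L) {
    birds <- unique(sim$samples$bird_id)
    target_birds <- sample(birds, n_blocks)
    for (i in seq_len(n_blocks)) {
      block <- sim$truth$reserved_bird_blocks[[i]]
      cols <- sim$samples$sample_id[sim$samples$bird_id == target_birds[i]]
      sim$counts[block, cols] <- round(sim$counts[block, cols] *
                                         exp(config$bird_module_effect))
      label <- sprintf("bird_module_%d", i)
      sim$truth$module[block] <- label
      sim$truth$bird_modules[[i]] <- list(label = label, genes = block,
                                          bird_id = target_birds[i])
    }
  }
  sim
}

#' Simulate a complete dataset with artifacts
#'
#' [simulate_expression()] followed by [inject_artifacts()].
#'
#' @param config A [sim_config()].
#' @return A `songmod_sim` list.
#' @export
simulate_dataset <- function(config) {
  inject_artifacts(simulate_expression(config), config)
}

#' Write a simulated dataset to TSV + JSON
#'
#' Writes `counts.tsv`, `genes.tsv`, `samples.tsv`, and `truth.json` under
#' `dir`.
#'
#' @param sim A `songmod_sim`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  .write_matrix_tsv(sim$counts, file.path(dir, "counts.tsv"))
  utils::write.table(sim$genes, file.path(dir, "genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$samples, file.path(dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- sim$truth
  truth$latents <- NULL
  truth$module <- data.frame(gene_id = names(truth$module),
                             module = unname(truth$module))
  truth$dosage_class <- data.frame(gene_id = names(truth$dosage_class),
                                   dosage_class = unname(truth$dosage_class))
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(dir)
}
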