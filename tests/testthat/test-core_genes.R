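# Four-contrast HVC core-gene selection and Z-chromosome enrichment.

test_that("the four HVC contrasts carve the design as specified", {
  design <- simulate_design(sim_config(seed = 1))
  suite <- hvc_contrast_suite(design)
  expect_named(suite, c("male_HVC_vs_DN", "E2_female_vocal_HVC",
                        "vehicle_HVC_male_vs_female", "E2_vs_vehicle_female_HVC"))
  ct1 <- build_contrast(design, suite$male_HVC_vs_DN)
  expect_identical(length(ct1$sample_ids), 12L)   # 6 male HVC + 6 male DN
  expect_identical(sum(ct1$trait), 6L)
  ct2 <- build_contrast(design, suite$E2_female_vocal_HVC)
  expect_identical(length(ct2$sample_ids), 12L)   # all female HVC + DN
  expect_identical(sum(ct2$trait), 3L)            # E2 female HVC only
  # contrast 3 subset is exactly vehicle male HVC plus vehicle female HVC
  ct3 <- build_contrast(design, suite$vehicle_HVC_male_vs_female)
  sub3 <- design[design$sample_id %in% ct3$sample_ids, ]
  expect_true(all(sub3$region == "HVC" & sub3$treatment == "vehicle"))
  expect_identical(sort(unique(sub3$sex)), c("female", "male"))
  expect_identical(ct3$trait, as.integer(sub3$sex == "male"))  # vocal-capable = 1
  ct4 <- build_contrast(design, suite$E2_vs_vehicle_female_HVC)
  expect_identical(length(ct4$sample_ids), 6L)
  # a design without E2 females fails with the missing cell named
  broken <- design[!(design$sex == "female" & design$treatment == "E2"), ]
  expect_error(hvc_contrast_suite(broken), "female/E2")
})

test_that("gene-of-interest thresholds act jointly and monotonically", {
  kme <- c(pass = 1, border = sqrt(0.49), strong = 0.9)
  assoc <- list(c1 = data.frame(
    gene_id = names(kme), r = c(1, 1, 0.6), r2 = c(1, 1, 0.36),
    p = c(1e-6, 1e-6, 0.01), stringsAsFactors = FALSE))
  crit <- selection_criteria("G")
  sets <- select_genes_of_interest(kme, assoc, crit)
  expect_identical(sets$c1, "pass")     # border fails kME^2, strong fails r2
  # raising any threshold never enlarges the set
  for (loose in list(selection_criteria("G", r2_membership_min = 0.3),
                     selection_criteria("G", r2_trait_min = 0.3),
                     selection_criteria("G", p_max = 0.5))) {
    bigger <- select_genes_of_interest(kme, assoc, loose)$c1
    expect_true(all(sets$c1 %in% bigger))
  }
  # require_positive drops negative-r qualifiers
  assoc_neg <- list(c1 = transform(assoc$c1, r = -r))
  expect_identical(
    select_genes_of_interest(kme, assoc_neg,
                             selection_criteria("G", require_positive = TRUE))$c1,
    character(0))
})

test_that("core intersection is strict, ordered, and order-invariant", {
  sets <- list(c("A", "B", "C"), c("B", "C", "D"), c("B", "C"), c("B", "C", "E"))
  expect_identical(core_gene_intersection(sets), c("B", "C"))
  expect_identical(core_gene_intersection(rev(sets)), c("B", "C"))
  expect_identical(core_gene_intersection(rep(list(c("x", "y")), 4)), c("x", "y"))
  expect_identical(core_gene_intersection(c(sets[1:3], list(character(0)))),
                   character(0))
  expect_error(core_gene_intersection(sets[1:3]), "exactly 4")
})

test_that("core Z enrichment delegates to the hypergeometric with both backgrounds", {
  genes <- data.frame(gene_id = paste0("g", 1:40),
                      chromosome = c(rep("Z", 8), rep("2", 32)),
                      length_bp = 1L)
  assignment <- stats::setNames(c(rep("G", 14), rep("A", 20),
                                  rep("unassigned", 6)), genes$gene_id)
  core <- c("g1", "g2", "g3", "g10")   # 3 Z genes of 4
  res <- core_z_enrichment(core, assignment, genes, focal_module = "G")
  expect_equal(res$all_assigned$p_upper, hyper_enumerate(3, 4, 8, 34))
  expect_equal(res$focal_module$p_upper, hyper_enumerate(3, 4, 8, 14))
  expect_gt(res$all_assigned$fold, 3)
  # zero Z hits gives p = 1
  res0 <- core_z_enrichment(c("g9", "g10"), assignment, genes, "G")
  expect_equal(res0$all_assigned$p_upper, 1)
  # core outside the module-assigned background errors
  expect_error(core_z_enrichment("g35", assignment, genes, "G"), "outside")
  # core genes not in the focal module are not draws from it
  res_mixed <- core_z_enrichment(c("g1", "g20"), assignment, genes, "G")
  expect_identical(res_mixed$focal_module$n, 1L)
})

test_that("planted HVC-specialized genes are recovered on the small sim", {
  sim <- small_sim()
  logem <- small_logem()
  samples <- sim$samples[sim$samples$sample_id %in% colnames(logem), ]
  truth <- sim$truth$module[rownames(logem)]
  dec <- reassign_genes(logem, truth)
  focal <- dec$assignment[names(truth)[truth == "hvc_vocal"][1]]
  suite <- hvc_contrast_suite(samples)
  assoc <- lapply(suite, function(spec) associate_genes(logem, samples, spec))
  sets <- select_genes_of_interest(dec$kme[, focal], assoc,
                                   selection_criteria(focal))
  core <- core_gene_intersection(sets)
  truth_focal <- names(truth)[truth == "hvc_vocal"]
  tp <- length(intersect(core, truth_focal))
  expect_gte(tp / length(core), 0.9)          # precision
  expect_gte(tp / length(truth_focal), 0.9)   # recall
})
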