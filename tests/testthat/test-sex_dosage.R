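# Dosage predictions, male expression fractions, regional sex tests,
# cross-region overlaps.

test_that("copy-number predictions are exact rationals", {
  expect_identical(predicted_fraction("Z"), 2 / 3)
  expect_identical(predicted_fraction("W"), 0)
  expect_identical(predicted_fraction("autosome"), 1 / 2)
  expect_identical(predicted_fraction(c("Z", "W", "autosome")),
                   c(2 / 3, 0, 1 / 2))
  expect_error(predicted_fraction("X"), "unknown chromosome class")
})

make_dosage_fixture <- function() {
  samples <- simulate_design(sim_config(seed = 1, n_birds_per_group = 1))
  genes <- data.frame(gene_id = c("z1", "w1", "a1"),
                      chromosome = c("Z", "W", "3"), length_bp = 1000L)
  em <- matrix(0, 3, nrow(samples),
               dimnames = list(genes$gene_id, samples$sample_id))
  male <- samples$sex == "male"
  em["z1", male] <- 2; em["z1", !male] <- 1
  em["w1", male] <- 0; em["w1", !male] <- 5
  list(em = em, samples = samples, genes = genes)
}

test_that("male fraction is region-averaged means then ratio", {
  fx <- make_dosage_fixture()
  rec <- male_expression_fraction(fx$em, fx$samples, fx$genes)
  expect_equal(rec$male_fraction[rec$gene_id == "z1"], 2 / 3)
  expect_equal(rec$male_fraction[rec$gene_id == "w1"], 0)
  expect_true(is.na(rec$male_fraction[rec$gene_id == "a1"]))   # 0/0 -> NA
  expect_equal(rec$predicted_fraction, c(2 / 3, 0, 1 / 2))
  # scaling all FPKM leaves fractions unchanged
  rec2 <- male_expression_fraction(fx$em * 37, fx$samples, fx$genes)
  expect_equal(rec2$male_fraction, rec$male_fraction)
  # one-sex subsets are rejected
  male_only <- fx$samples[fx$samples$sex == "male", ]
  expect_error(male_expression_fraction(fx$em, male_only, fx$genes), "both sexes")
})

test_that("dosage summary flags deviation from the copy-number prediction", {
  rec <- data.frame(
    gene_id = paste0("g", 1:20),
    chromosome_class = "Z",
    male_avg = c(rep(2, 10), rep(1, 10)),
    female_avg = 1,
    male_fraction = c(rep(2 / 3, 10), rep(1 / 2, 10)),
    predicted_fraction = 2 / 3,
    total_expression = 3,
    module = rep(c("dose", "comp"), each = 10),
    stringsAsFactors = FALSE
  )
  s <- summarize_dosage_by_module(rec, margin = 0.1)
  expect_false(s$compensated[s$module == "dose"])   # at prediction
  expect_true(s$compensated[s$module == "comp"])    # sex-equal, deviates
  expect_equal(s$mean_fraction[s$module == "dose"], 2 / 3)
})

test_that("uncompensated Z genes concentrate at the dose prediction", {
  # dedicated config matching the stated condition: 100 uncompensated Z
  # genes, 3 birds per sex
  cfg <- sim_config(seed = 31, z_compensated_fraction = 0,
                    outlier_samples = 0L, bird_specific_modules = 0L)
  sim <- simulate_expression(cfg)
  fpkm <- fpkm_normalize(sim$counts, sim$genes)
  rec <- male_expression_fraction(fpkm, sim$samples, sim$genes)
  zu <- names(sim$truth$dosage_class)[sim$truth$dosage_class == "Z_uncompensated"]
  expect_length(zu, 100L)
  expect_lt(abs(mean(rec$male_fraction[rec$gene_id %in% zu]) - 2 / 3), 0.02)
  w <- names(sim$truth$dosage_class)[sim$truth$dosage_class == "W"]
  expect_equal(rec$male_fraction[rec$gene_id %in% w], rep(0, length(w)))
})

test_that("W-gene male fraction rises monotonically with paralog leakage", {
  means <- vapply(c(0, 0.2, 0.5), function(lam) {
    cfg <- sim_config(seed = 17, n_genes = 800, w_fraction = 0.05,
                      w_leakage = lam, outlier_samples = 0L,
                      bird_specific_modules = 0L,
                      module_plan = default_module_plan()[4:5])
    sim <- simulate_expression(cfg)
    fpkm <- fpkm_normalize(sim$counts, sim$genes)
    rec <- male_expression_fraction(fpkm, sim$samples, sim$genes)
    w <- names(sim$truth$dosage_class)[sim$truth$dosage_class == "W"]
    mean(rec$male_fraction[rec$gene_id %in% w], na.rm = TRUE)
  }, numeric(1L))
  expect_identical(means[1], 0)
  expect_true(all(diff(means) > 0))
})

test_that("regional sex tests recover W genes and respect alpha = 0", {
  sim <- small_sim()
  logem <- small_logem()
  samples <- sim$samples[sim$samples$sample_id %in% colnames(logem), ]
  sets <- regional_sex_tests(logem, samples, sim$genes)
  w <- names(sim$truth$dosage_class)[sim$truth$dosage_class == "W"]
  w <- intersect(w, rownames(logem))
  for (rg in names(sets))
    expect_setequal(intersect(sets[[rg]]$significant_W_expressed, w), w)
  empty <- regional_sex_tests(logem, samples, sim$genes, alpha = 0)
  expect_true(all(vapply(empty, function(s)
    length(s$significant_W_expressed) + length(s$significant_Z_depleted) == 0L,
    logical(1L))))
})

test_that("region set overlap handles identical, disjoint, and shared cores", {
  identical_sets <- structure(list(
    r1 = list(significant_W_expressed = c("a", "b"), significant_Z_depleted = "z"),
    r2 = list(significant_W_expressed = c("a", "b"), significant_Z_depleted = "z")
  ), class = "regional_sex_sets")
  ov <- region_set_overlap(identical_sets)
  expect_identical(ov$W_expressed$union, ov$W_expressed$intersection)
  disjoint <- structure(list(
    r1 = list(significant_W_expressed = c("a", "b"), significant_Z_depleted = "z1"),
    r2 = list(significant_W_expressed = c("c"), significant_Z_depleted = "z2")
  ), class = "regional_sex_sets")
  ov2 <- region_set_overlap(disjoint)
  expect_identical(ov2$W_expressed$n_intersection, 0L)
  expect_identical(ov2$W_expressed$n_union, 3L)
  expect_error(region_set_overlap(identical_sets[1]), ">= 2 regions")
})
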