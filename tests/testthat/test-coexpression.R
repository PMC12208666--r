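# Network construction, module detection, eigengenes, kME, reassignment,
# overfit flagging.

test_that("adjacency is |r|^beta with unit diagonal", {
  # two indicator profiles with Pearson r exactly -0.5
  em <- rbind(g1 = c(1, 0, 0), g2 = c(0, 1, 0))
  colnames(em) <- paste0("s", 1:3)
  a <- adjacency_matrix(em, beta = 6)
  expect_equal(a["g1", "g2"], 0.5^6)  # 0.015625
  expect_equal(diag(a), c(g1 = 1, g2 = 1))
  em2 <- rbind(g1 = 1:4, g2 = 2 * (1:4) + 3)   # r = 1
  colnames(em2) <- paste0("s", 1:4)
  expect_equal(adjacency_matrix(em2, beta = 9)["g1", "g2"], 1)
  expect_error(adjacency_matrix(rbind(g1 = c(1, 1, 1), g2 = c(1, 2, 3))), "g1")
})

test_that("adjacency matches an elementwise pairwise-loop oracle", {
  set.seed(42)
  em <- matrix(rnorm(10 * 12), 10, 12,
               dimnames = list(paste0("g", 1:10), paste0("s", 1:12)))
  a <- adjacency_matrix(em, beta = 6)
  for (i in 1:10) for (j in 1:10) {
    expected <- if (i == j) 1 else abs(stats::cor(em[i, ], em[j, ]))^6
    expect_equal(a[i, j], expected, tolerance = 1e-12)
  }
})

test_that("TOM reduces correctly on tiny networks", {
  a2 <- matrix(c(1, 0.3, 0.3, 1), 2, 2)
  expect_equal(topological_overlap(a2)[1, 2], 0.3)     # two-node reduction
  a3 <- matrix(1, 3, 3)
  expect_equal(topological_overlap(a3)[1, 2], 1)       # clique saturation
})

test_that("TOM equals the brute-force triple loop on all small instances", {
  for (n in 5:12) {
    a <- random_adjacency(n, seed = n)
    tom <- topological_overlap(a)
    expect_equal(unname(tom), tom_bruteforce(unname(a)), tolerance = 1e-12)
    expect_true(isSymmetric(unname(tom), tol = 1e-12))
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
  }
})

test_that("module detection recovers noiseless planted blocks", {
  set.seed(9)
  ns <- 20
  lat <- matrix(rnorm(3 * ns), 3, ns)
  em <- lat[rep(1:3, each = 60), ]      # zero within-block noise
  dimnames(em) <- list(paste0("g", 1:180), paste0("s", 1:ns))
  asg <- detect_modules(topological_overlap(adjacency_matrix(em, 6)),
                        network_params(min_module_size = 30))
  truth <- rep(c("a", "b", "c"), each = 60)
  expect_equal(adjusted_rand_index(asg, truth), 1)
  expect_setequal(unique(asg), c("A", "B", "C"))
})

test_that("adjusted Rand index agrees with the mclust implementation", {
  set.seed(14)
  for (i in 1:5) {
    a <- sample(letters[1:4], 60, replace = TRUE)
    b <- sample(letters[1:3], 60, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b))
  }
  expect_equal(adjusted_rand_index(1:10, rep(1:5, 2)),
               mclust::adjustedRandIndex(1:10, rep(1:5, 2)))
})

test_that("clusters below the minimum size become unassigned", {
  set.seed(10)
  ns <- 30
  sizes <- c(150, 120, 90)
  lat <- matrix(rnorm(3 * ns), 3, ns)
  em <- lat[rep(1:3, times = sizes), ] + matrix(rnorm(sum(sizes) * ns, 0, 0.1),
                                                sum(sizes), ns)
  dimnames(em) <- list(paste0("g", seq_len(sum(sizes))), paste0("s", 1:ns))
  asg <- detect_modules(topological_overlap(adjacency_matrix(em, 6)),
                        network_params(min_module_size = 100))
  truth_block <- rep(c("x", "y", "z"), times = sizes)
  expect_true(all(asg[truth_block == "z"] == "unassigned"))
  expect_identical(sum(asg == "A"), 150L)   # labels letter by descending size
  expect_identical(sum(asg == "B"), 120L)
  expect_warning(
    detect_modules(topological_overlap(adjacency_matrix(em, 6)),
                   network_params(min_module_size = 10000)),
    "unassigned")
})

test_that("eigengenes equal the first principal component", {
  logem <- small_logem()
  sim <- small_sim()
  asg <- sim$truth$module[rownames(logem)]
  eig <- module_eigengene(logem, asg)
  # independent oracle: leading eigenvector of the z-scored crossproduct
  for (m in rownames(eig)) {
    x <- logem[names(asg)[asg == m], , drop = FALSE]
    z <- (x - rowMeans(x)) / apply(x, 1, stats::sd)
    v <- eigen(crossprod(z), symmetric = TRUE)$vectors[, 1]
    expect_gte(abs(sum(eig[m, ] * v)), 1 - 1e-10)
    expect_equal(sum(eig[m, ]^2), 1)                     # unit norm
    kme <- module_membership(logem, eig[m, , drop = FALSE])
    expect_gt(mean(kme[names(asg)[asg == m], 1]), 0)     # sign convention
  }
})

test_that("eigengene handles rank-1 and sign-flip degeneracies", {
  x <- matrix(rep(c(1, 3, 2, 5), each = 2), 2, 4, byrow = FALSE)
  em <- rbind(x[1, ], x[1, ])
  dimnames(em) <- list(c("g1", "g2"), paste0("s", 1:4))
  eig <- module_eigengene(em, c(g1 = "A", g2 = "A"))
  prof <- scale(em[1, ])[, 1]
  expect_equal(abs(sum(eig["A", ] * prof / sqrt(sum(prof^2)))), 1, tolerance = 1e-10)
  # flipping all member signs is unobservable after orientation
  eig_flip <- module_eigengene(-em, c(g1 = "A", g2 = "A"))
  kme <- module_membership(em, eig)
  kme_flip <- module_membership(-em, eig_flip)
  expect_equal(kme, kme_flip)
})

test_that("kME hits the exact endpoints and a null bound", {
  set.seed(21)
  eig <- matrix(rnorm(96), 1, 96, dimnames = list("A", paste0("s", 1:96)))
  em <- rbind(same = eig[1, ], neg = -eig[1, ])
  colnames(em) <- colnames(eig)
  kme <- module_membership(em, eig)
  expect_equal(kme["same", "A"], 1)
  expect_equal(kme["neg", "A"], -1)
  # null correlations at n = 96 stay small (binomial-safe bound over 200 draws)
  null_em <- matrix(rnorm(200 * 96), 200, 96,
                    dimnames = list(paste0("n", 1:200), colnames(eig)))
  expect_lt(mean(abs(module_membership(null_em, eig)) >= 0.35), 0.01)
})

test_that("reassignment is a fixed point on converged data and repairs mislabels", {
  logem <- small_logem()
  sim <- small_sim()
  truth <- sim$truth$module[rownames(logem)]
  dec <- reassign_genes(logem, truth)
  # truth labels are already optimal: assignments only reletter
  expect_equal(adjusted_rand_index(dec$assignment, truth), 1)
  # mislabel a planted gene; it must return to its true module
  wrong <- truth
  member <- names(truth)[truth == "areax_str"][1]
  wrong[member] <- "hvc_vocal"
  dec2 <- reassign_genes(logem, wrong)
  expect_equal(dec2$assignment[member], dec$assignment[member])
  # an unreachable threshold freezes the assignment
  dec3 <- reassign_genes(logem, wrong, reassign_p = 1e-300)
  expect_equal(adjusted_rand_index(dec3$assignment, wrong), 1)
})

test_that("module labels are letters in non-increasing size order", {
  dec <- reassign_genes(small_logem(), small_sim()$truth$module[rownames(small_logem())])
  sizes <- table(dec$assignment[dec$assignment != "unassigned"])
  expect_identical(sort(names(sizes)), LETTERS[seq_along(sizes)])
  expect_true(all(diff(as.integer(sizes[LETTERS[seq_along(sizes)]])) <= 0))
})

test_that("overfit flagging targets single-sample modules of one bird", {
  sim <- small_sim()
  samples <- sim$samples
  ns <- nrow(samples)
  single <- rep(0.001, ns); single[5] <- 1
  single <- single / sqrt(sum(single^2))
  set.seed(3)
  spread <- rnorm(ns); spread <- spread / sqrt(sum(spread^2))
  eig <- rbind(single = single, spread = spread)
  colnames(eig) <- samples$sample_id
  expect_identical(flag_overfit_modules(eig, samples), "single")
  expect_identical(flag_overfit_modules(eig, samples, z_cut = Inf), character(0))
  # region-structured eigengenes across many birds are never flagged
  region_eig <- as.numeric(samples$region == "RA")
  region_eig <- region_eig / sqrt(sum(region_eig^2))
  eig2 <- rbind(ra = region_eig)
  colnames(eig2) <- samples$sample_id
  expect_identical(flag_overfit_modules(eig2, samples), character(0))
})

test_that("soft-threshold scan recovers a scale-free regime and falls back on noise", {
  # single shared factor with loadings chosen so connectivity at the
  # generating power is Pareto-distributed (scale-free)
  set.seed(11)
  ng <- 800; ns <- 100
  t <- pmin(0.002 * runif(ng)^(-1 / 1.5), 0.98)
  cc <- t^(1 / 6)
  em <- outer(cc, rnorm(ns)) + matrix(rnorm(ng * ns), ng, ns) * sqrt(1 - cc^2)
  dimnames(em) <- list(paste0("g", 1:ng), paste0("s", 1:ns))
  ps <- pick_soft_threshold(em, candidate_powers = c(1, 2, 3, 4, 6, 8, 10, 12))
  expect_lte(ps$beta, 12)
  expect_gte(max(ps$fit_table$r_squared, na.rm = TRUE), 0.8)
  expect_lt(ps$fit_table$slope[ps$fit_table$power == ps$beta], 0)
  # forced single candidate
  expect_identical(suppressWarnings(pick_soft_threshold(em, 6L))$beta, 6L)
  # pure noise: low fit everywhere, argmax fallback with a warning
  set.seed(12)
  noise <- matrix(rnorm(60 * 20), 60, 20,
                  dimnames = list(paste0("g", 1:60), paste0("s", 1:20)))
  expect_warning(psn <- pick_soft_threshold(noise, c(2, 4, 6)), "argmax")
  expect_true(psn$beta %in% c(2L, 4L, 6L))
})
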