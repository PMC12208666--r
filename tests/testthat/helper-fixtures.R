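# Shared fixtures, built in code and cached for the session.

.fixture_cache <- new.env(parent = emptyenv())

# A small, fast simulated dataset for unit tests: two region modules plus a
# male-biased module carrying the sex chromosomes.
small_sim <- function() {
  if (!is.null(.fixture_cache$small_sim)) return(.fixture_cache$small_sim)
  cfg <- sim_config(
    seed = 5, n_genes = 600,
    module_plan = list(
      list(label = "areax_str", size = 120L, effect = 2,
           pattern = function(s) s$region %in% c("AreaX", "Str")),
      list(label = "hvc_vocal", size = 100L, effect = 3,
           pattern = function(s) (s$sex == "male" & s$region == "HVC") |
             (s$sex == "female" & s$treatment == "E2" & s$region == "HVC")),
      list(label = "sexZW", size = 80L, effect = 1.2,
           pattern = function(s) s$sex == "male",
           attach_sex_chromosomes = TRUE)
    ),
    outlier_samples = 1L, bird_specific_modules = 0L
  )
  .fixture_cache$small_sim <- simulate_dataset(cfg)
  .fixture_cache$small_sim
}

# Log-scale filtered expression of the small sim, outliers removed.
small_logem <- function() {
  if (!is.null(.fixture_cache$small_logem)) return(.fixture_cache$small_logem)
  sim <- small_sim()
  ff <- filter_expressed(fpkm_normalize(sim$counts, sim$genes))
  out <- detect_outlier_samples(log2(ff + 1))
  .fixture_cache$small_logem <- log2(ff[, setdiff(colnames(ff), out)] + 1)
  .fixture_cache$small_logem
}

# Full default-condition pipeline run used by the recovery and fidelity
# checks: default simulator (2000 genes, 96 samples) with the published
# analysis thresholds (beta 6, min module size 100, 50000 permutations,
# r^2 >= 0.5, alpha 0.05).
default_pipeline <- function() {
  if (!is.null(.fixture_cache$default_pipeline)) return(.fixture_cache$default_pipeline)
  sim <- simulate_dataset(sim_config(seed = 101))
  res <- run_pipeline(pipeline_config(sim$counts, sim$genes, sim$samples,
                                      n_perm = 50000L, seed = 101))
  .fixture_cache$default_pipeline <- list(sim = sim, res = res)
  .fixture_cache$default_pipeline
}

# Brute-force TOM oracle: explicit triple loop over the formula.
tom_bruteforce <- function(a) {
  n <- nrow(a)
  tom <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    shared <- 0
    for (u in seq_len(n)) if (u != i && u != j) shared <- shared + a[i, u] * a[u, j]
    ki <- sum(a[i, -i])
    kj <- sum(a[j, -j])
    tom[i, j] <- (shared + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
  }
  tom
}

# Exhaustive hypergeometric upper tail by enumerating every draw of size n
# from a universe of N with K labeled elements.
hyper_enumerate <- function(k, n, K, N) {
  draws <- utils::combn(N, n)
  labeled <- seq_len(K)
  hits <- apply(draws, 2L, function(d) sum(d %in% labeled))
  mean(hits >= k)
}

random_adjacency <- function(n, seed) {
  set.seed(seed)
  r <- matrix(stats::runif(n * n), n, n)
  a <- (r + t(r)) / 2
  diag(a) <- 1
  dimnames(a) <- list(paste0("g", seq_len(n)), paste0("g", seq_len(n)))
  a
}
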