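# Gene-set and chromosome enrichment: GMT parsing, a one-tailed set-vs-
# background test on per-gene statistics, bootstrap chromosome-module
# enrichment with empirical null distributions, the hypergeometric test, and
# Benjamini-Hochberg FDR.

#' Parse a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-delimited, fields are set name,
#' description, then member gene ids. Sets are restricted to `universe` when
#' given; sets empty after restriction are dropped with a warning.
#'
#' @param path Path to the GMT file.
#' @param universe Optional character vector of background gene ids.
#' @return A list with `sets` (name -> character vector) and `universe`.
#' @export
parse_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      .stopf("malformed GMT line %d: expected name, description, members", i)
    members <- unique(fields[-(1:2)])
    if (!is.null(universe)) members <- intersect(members, universe)
    if (!length(members)) {
      .warnf("gene set '%s' has no overlap with the universe; dropped", fields[1L])
      next
    }
    sets[[fields[1L]]] <- members
  }
  list(sets = sets, universe = universe)
}

#' Write gene sets to GMT
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional named descriptions; defaults to `"na"`.
#' @return The path, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  lines <- vapply(names(sets), function(nm) {
    desc <- if (!is.null(descriptions) && nm %in% names(descriptions))
      descriptions[[nm]] else "na"
    paste(c(nm, desc, sets[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' One-tailed gene-set test on per-gene statistics
#'
#' Welch two-sample t-test of the member genes' statistics against the
#' non-member background. `tail = "upper"` asks whether the set's statistics
#' are shifted above the background.
#'
#' @param stats Named numeric vector of per-gene statistics (e.g. kME or a
#'   contrast correlation).
#' @param set Character vector of member gene ids (>= 2 within `stats`).
#' @param tail `"upper"` (default) or `"lower"`.
#' @return A list with `p`, `t`, `n_set`, `n_background`.
#' @export
gene_set_test <- function(stats, set, tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  member <- names(stats) %in% set
  if (sum(member) < 2L) .stopf("gene set has fewer than 2 members within the statistics")
  if (sum(!member) < 2L) .stopf("background has fewer than 2 genes")
  alt <- if (tail == "upper") "greater" else "less"
  ht <- stats::t.test(stats[member], stats[!member], alternative = alt)
  list(p = unname(ht$p.value), t = unname(ht$statistic),
       n_set = sum(member), n_background = sum(!member))
}

#' Bootstrap chromosome-module enrichment
#'
#' For every (chromosome, module) pairing among module-assigned genes, fold
#' enrichment is observed/expected with expected = module size x chromosome
#' fraction of the assigned universe. The empirical p-value randomizes the
#' mapping between genes and modules `n_perm` times (module sizes preserved)
#' and applies the add-one rule `p = (1 + #{permuted >= observed}) /
#' (n_perm + 1)`; q-values are Benjamini-Hochberg over the full grid.
#'
#' @param assignment Named gene -> module vector; `"unassigned"` is excluded
#'   from the universe.
#' @param genes Gene table supplying `chromosome` per gene.
#' @param n_perm Number of label permutations; default 50000.
#' @param seed Integer seed; permutations are reproducible given it.
#' @return Data.frame with `category` (chromosome), `module`, `observed`,
#'   `expected`, `fold`, `p`, `q`.
#' @export
chromosome_module_enrichment <- function(assignment, genes, n_perm = 50000L,
                                         seed = 1L) {
  stopifnot(n_perm >= 1L)
  assignment <- assignment[assignment != UNASSIGNED]
  if (!length(assignment)) .stopf("no module-assigned genes")
  chrom <- genes$chromosome[match(names(assignment), genes$gene_id)]
  if (anyNA(chrom)) .stopf("assigned gene(s) missing a chromosome label")
  mods <- sort(unique(assignment))
  chroms <- sort(unique(chrom))
  ci <- match(chrom, chroms)
  mi <- match(assignment, mods)
  nc <- length(chroms); nm <- length(mods)
  n <- length(assignment)
  cells <- nc * nm
  obs <- tabulate((mi - 1L) * nc + ci, nbins = cells)
  mod_size <- tabulate(mi, nbins = nm)
  chr_tot <- tabulate(ci, nbins = nc)
  if (any(mod_size == 0L)) .warnf("empty module(s) skipped in enrichment")
  expected <- as.vector(outer(chr_tot, mod_size)) / n
  # Permutation: shuffling gene -> module labels is equivalent to permuting
  # the chromosome labels against a fixed module vector.
  set.seed(seed)
  ge <- integer(cells)
  base <- (mi - 1L) * nc
  for (b in seq_len(n_perm)) {
    perm_ci <- ci[sample.int(n)]
    cnt <- tabulate(base + perm_ci, nbins = cells)
    ge <- ge + (cnt >= obs)
  }
  p <- (1 + ge) / (n_perm + 1)
  out <- data.frame(
    category = rep(chroms, times = nm),
    module = rep(mods, each = nc),
    observed = obs,
    expected = expected,
    fold = ifelse(expected > 0, obs / expected, NA_real_),
    p = p,
    stringsAsFactors = FALSE
  )
  out <- out[mod_size[match(out$module, mods)] > 0L, , drop = FALSE]
  out$q <- bh_fdr(out$p)
  rownames(out) <- NULL
  out
}

#' Upper-tailed hypergeometric enrichment
#'
#' `p_upper = P[X >= k]` for `X ~ Hypergeometric(N, K, n)`: drawing `n` genes
#' without replacement from a universe of `N` containing `K` labeled genes.
#' Fold enrichment is `(k/n) / (K/N)`.
#'
#' @param k Labeled genes among the draws (hits).
#' @param n Number of draws.
#' @param K Labeled genes in the universe.
#' @param N Universe size.
#' @return A list with `p_upper`, `fold`, and the four counts.
#' @export
hypergeometric_enrichment <- function(k, n, K, N) {
  if (!(k >= 0 && k <= n && n <= N && k <= K && K <= N))
    .stopf("inconsistent hypergeometric counts: k=%d n=%d K=%d N=%d", k, n, K, N)
  if (n == 0L) .stopf("hypergeometric enrichment needs at least one draw")
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  fold <- if (K > 0) (k / n) / (K / N) else NA_real_
  list(p_upper = p, fold = fold, k = k, n = n, K = K, N = N)
}

#' Benjamini-Hochberg step-up q-values
#'
#' Order-preserving with the input vector.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values.
#' @export
bh_fdr <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) .stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
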