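# Unsigned weighted co-expression network: soft-thresholded adjacency,
# topological overlap, static tree-cut module detection, eigengenes, kME,
# iterative gene reassignment, and technical-overfit flagging.
#
# Conventions: expression matrices are genes x samples; module labels are
# capital letters A, B, C, ... in strictly non-increasing member count, with
# the reserved label "unassigned" for genes outside every module.

UNASSIGNED <- "unassigned"

#' Default network parameters
#'
#' Soft-threshold power 6 and minimum module size 100 are the defaults the
#' full songbird dataset was analysed with; the static cut height, the
#' reassignment p threshold, and the candidate power grid are package choices.
#'
#' @param beta Soft-threshold power applied to |Pearson r|; default 6.
#' @param min_module_size Smallest branch retained as a module; default 100.
#' @param cut_height Static cut height on the 1 - TOM dendrogram scale, in
#'   (0, 1]; default 0.90. At beta = 6 a merge below this height requires a
#'   mean topological overlap above 0.1 — genuine shared-neighbour structure
#'   rather than the sampling-noise correlations (|r| ~ 0.2 at ~100 samples)
#'   that accumulate just below height 1.
#' @param reassign_p Correlation p-value a gene must beat to be moved to a
#'   better-matching module; default 1e-6.
#' @param candidate_powers Powers scanned by [pick_soft_threshold()].
#' @return A list of class `network_params`.
#' @export
network_params <- function(beta = 6L, min_module_size = 100L, cut_height = 0.90,
                           reassign_p = 1e-6,
                           candidate_powers = c(1:10, 12L, 14L, 16L, 18L, 20L)) {
  stopifnot(beta >= 1, min_module_size >= 1, cut_height > 0, cut_height <= 1,
            reassign_p > 0, reassign_p < 1, all(candidate_powers >= 1))
  structure(list(beta = as.integer(beta),
                 min_module_size = as.integer(min_module_size),
                 cut_height = cut_height, reassign_p = reassign_p,
                 candidate_powers = as.integer(candidate_powers)),
            class = "network_params")
}

#' Scan soft-threshold powers for scale-free topology fit
#'
#' For each candidate power, builds the unsigned adjacency, bins the
#' connectivity distribution (default 10 bins), and reports the R-squared of
#' the log10 p(k) on log10 k regression together with the regression slope and
#' mean connectivity. Selects the smallest power reaching `r2_threshold`, or
#' falls back to the argmax R-squared with a warning when no power reaches it.
#'
#' @param em Genes x samples expression matrix (>= 20 genes, >= 8 samples).
#' @param candidate_powers Integer powers to scan.
#' @param n_bins Number of connectivity bins; default 10.
#' @param r2_threshold Scale-free fit target; default 0.8.
#' @return A list with `fit_table` (power, r_squared, slope, mean_connectivity)
#'   and the selected `beta`.
#' @export
pick_soft_threshold <- function(em, candidate_powers = c(1:10, 12L, 14L, 16L, 18L, 20L),
                                n_bins = 10L, r2_threshold = 0.8) {
  if (nrow(em) < 20L) .stopf("soft-threshold scan needs >= 20 genes")
  if (ncol(em) < 8L) .stopf("soft-threshold scan needs >= 8 samples")
  sds <- apply(em, 1L, stats::sd)
  if (any(sds == 0)) {
    .warnf("excluding %d constant-expression gene(s) from the power scan", sum(sds == 0))
    em <- em[sds > 0, , drop = FALSE]
  }
  r_abs <- abs(stats::cor(t(em)))
  diag(r_abs) <- 0
  fit_one <- function(power) {
    k <- colSums(r_abs^power)
    bins <- cut(k, breaks = n_bins)
    pk <- as.vector(table(bins)) / length(k)
    kmid <- tapply(k, bins, mean)
    ok <- pk > 0 & is.finite(kmid) & kmid > 0
    if (sum(ok) < 3L) return(c(r2 = NA_real_, slope = NA_real_, mean_k = mean(k)))
    fit <- stats::lm(log10(pk[ok]) ~ log10(kmid[ok]))
    c(r2 = summary(fit)$r.squared, slope = unname(stats::coef(fit)[2L]),
      mean_k = mean(k))
  }
  rows <- t(vapply(candidate_powers, fit_one, numeric(3L)))
  fit_table <- data.frame(power = candidate_powers, r_squared = rows[, "r2"],
                          slope = rows[, "slope"], mean_connectivity = rows[, "mean_k"])
  hit <- which(!is.na(fit_table$r_squared) & fit_table$r_squared >= r2_threshold)
  if (length(hit)) {
    beta <- candidate_powers[hit[1L]]
  } else {
    .warnf("no candidate power reaches scale-free fit R^2 >= %.2f; using argmax", r2_threshold)
    beta <- candidate_powers[which.max(fit_table$r_squared)]
  }
  list(fit_table = fit_table, beta = as.integer(beta))
}

#' Unsigned soft-thresholded adjacency
#'
#' `a_ij = |Pearson r(gene_i, gene_j)|^beta`, diagonal set to 1.
#'
#' @param em Genes x samples expression matrix; no constant gene rows.
#' @param beta Soft-threshold power.
#' @return A symmetric genes x genes adjacency matrix in `[0, 1]`.
#' @export
adjacency_matrix <- function(em, beta = 6L) {
  sds <- apply(em, 1L, stats::sd)
  if (any(sds == 0))
    .stopf("constant expression row(s): %s",
           paste(utils::head(rownames(em)[sds == 0], 5L), collapse = ", "))
  a <- abs(stats::cor(t(em)))^beta
  diag(a) <- 1
  a
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_{u != i,j} a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)`
#' with `k_i = sum_{u != i} a_iu`, and `TOM_ii = 1`. Computed in a single
#' block via one matrix product.
#'
#' @param adjacency Symmetric adjacency in `[0, 1]` with unit diagonal.
#' @return The TOM, same shape as `adjacency`.
#' @export
topological_overlap <- function(adjacency) {
  if (!isSymmetric(unname(adjacency), tol = 1e-10)) .stopf("adjacency must be symmetric")
  if (any(adjacency < 0 | adjacency > 1)) .stopf("adjacency values must lie in [0, 1]")
  a <- adjacency
  diag(a) <- 1
  k <- rowSums(a) - 1
  s <- a %*% a
  # sum over u != i,j of a_iu a_uj equals S_ij - 2 a_ij when the diagonal is 1
  num <- s - 2 * a + a  # = S - A
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

# Relabel module ids as letters by descending size; deterministic tie-break on
# the first gene index carrying each label. Input: character vector of raw
# labels (UNASSIGNED passes through).
.relabel_by_size <- function(assignment) {
  mods <- setdiff(unique(assignment), UNASSIGNED)
  if (!length(mods)) return(assignment)
  size <- vapply(mods, function(m) sum(assignment == m), integer(1L))
  first <- vapply(mods, function(m) which(assignment == m)[1L], integer(1L))
  ord <- order(-size, first)
  letters_pool <- c(LETTERS, as.vector(outer(LETTERS, LETTERS, paste0)))
  new <- stats::setNames(letters_pool[seq_along(mods)], mods[ord])
  out <- assignment
  assigned <- assignment != UNASSIGNED
  out[assigned] <- new[assignment[assigned]]
  out
}

#' Detect modules by static tree cut of the TOM dendrogram
#'
#' Average-linkage hierarchical clustering of the dissimilarity 1 - TOM;
#' branches are cut at `cut_height` and clusters smaller than
#' `min_module_size` are sent to `"unassigned"`. Deterministic given input
#' order. Labels are letters in descending module size.
#'
#' @param tom Topological overlap matrix with gene rownames.
#' @param params A [network_params()] list (uses `cut_height`,
#'   `min_module_size`).
#' @return Named character vector: gene id -> module label.
#' @export
detect_modules <- function(tom, params = network_params()) {
  d <- stats::as.dist(1 - tom)
  hc <- stats::hclust(d, method = "average")
  cl <- stats::cutree(hc, h = min(params$cut_height, max(hc$height)))
  sizes <- table(cl)
  keep <- as.integer(names(sizes)[sizes >= params$min_module_size])
  assignment <- ifelse(cl %in% keep, paste0("m", cl), UNASSIGNED)
  names(assignment) <- rownames(tom)
  if (all(assignment == UNASSIGNED))
    .warnf("no cluster reaches min_module_size = %d; all genes unassigned",
           params$min_module_size)
  .relabel_by_size(assignment)
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component over samples of
#' the module's z-scored member expression: member rows are standardized, the
#' first right-singular vector is taken, scaled to unit norm, and
#' sign-oriented so that the mean correlation of member genes with the
#' eigengene is positive.
#'
#' @param em Genes x samples expression matrix.
#' @param assignment Named gene -> module label vector; `"unassigned"` genes
#'   are ignored.
#' @return A modules x samples matrix of eigengene values (unit-norm rows).
#' @export
module_eigengene <- function(em, assignment) {
  assignment <- assignment[names(assignment) %in% rownames(em)]
  mods <- setdiff(sort(unique(assignment)), UNASSIGNED)
  eig <- matrix(NA_real_, length(mods), ncol(em),
                dimnames = list(mods, colnames(em)))
  for (m in mods) {
    members <- names(assignment)[assignment == m]
    if (length(members) < 2L) .stopf("module %s has fewer than 2 members", m)
    x <- em[members, , drop = FALSE]
    sds <- apply(x, 1L, stats::sd)
    z <- x[sds > 0, , drop = FALSE]
    if (nrow(z) == 0L) { eig[m, ] <- 0; next }
    z <- (z - rowMeans(z)) / apply(z, 1L, stats::sd)
    v <- svd(z, nu = 0L, nv = 1L)$v[, 1L]
    mean_r <- mean(.cor_vec(t(z), v), na.rm = TRUE)
    if (is.finite(mean_r) && mean_r < 0) v <- -v
    eig[m, ] <- v
  }
  eig
}

#' Continuous module membership (kME)
#'
#' `kME[g, m]` is the Pearson correlation of gene `g`'s expression profile
#' with eigengene `m` across all samples. Constant genes get `NA` with a
#' warning.
#'
#' @param em Genes x samples expression matrix.
#' @param eigengenes Modules x samples eigengene matrix.
#' @return A genes x modules matrix of correlations in `[-1, 1]`.
#' @export
module_membership <- function(em, eigengenes) {
  kme <- matrix(NA_real_, nrow(em), nrow(eigengenes),
                dimnames = list(rownames(em), rownames(eigengenes)))
  sds <- apply(em, 1L, stats::sd)
  if (any(sds == 0))
    .warnf("kME undefined for %d constant gene(s); reported as NA", sum(sds == 0))
  ok <- sds > 0
  esd <- apply(eigengenes, 1L, stats::sd)
  for (j in seq_len(nrow(eigengenes))) {
    if (esd[j] > 0)
      kme[ok, j] <- as.vector(stats::cor(t(em[ok, , drop = FALSE]), eigengenes[j, ]))
  }
  kme
}

#' Iteratively reassign genes to best-correlated modules
#'
#' Repeats: compute kME of every assigned gene against every eigengene; move a
#' gene to the module of its largest |kME| when that is strictly larger than
#' its current module's |kME| and the corresponding correlation p-value is
#' below `reassign_p`; recompute eigengenes. Stops at a fixed point or after
#' `max_iter` sweeps (with a warning). Ties in the argmax are broken in favour
#' of the current module, then lexicographic label order. Unassigned genes are
#' not recruited. Modules are relettered by size on exit.
#'
#' @param em Genes x samples expression matrix.
#' @param assignment Named gene -> module label vector.
#' @param reassign_p Student-t correlation p-value threshold; default 1e-6.
#' @param max_iter Sweep cap; default 50.
#' @return A list of class `module_decomposition` with `assignment`,
#'   `eigengenes`, `kme`, `excluded_modules`, and `n_iterations`.
#' @export
reassign_genes <- function(em, assignment, reassign_p = 1e-6, max_iter = 50L) {
  assignment <- assignment[rownames(em)]
  names(assignment) <- rownames(em)
  n <- ncol(em)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    eig <- module_eigengene(em, assignment)
    if (nrow(eig) == 0L) break
    kme <- module_membership(em, eig)
    assigned <- which(assignment != UNASSIGNED & assignment %in% rownames(eig))
    if (!length(assigned)) break
    akme <- abs(kme[assigned, , drop = FALSE])
    cur <- assignment[assigned]
    cur_k <- akme[cbind(seq_along(assigned), match(cur, colnames(akme)))]
    # favour the current module on ties by a half-ulp bump, then first
    # (lexicographically smallest) column wins in max.col
    bumped <- akme
    bumped[cbind(seq_along(assigned), match(cur, colnames(akme)))] <-
      cur_k * (1 + 1e-12) + 1e-300
    best_j <- max.col(replace(bumped, is.na(bumped), -Inf), ties.method = "first")
    best <- colnames(akme)[best_j]
    best_k <- akme[cbind(seq_along(assigned), best_j)]
    p_best <- .cor_p(best_k, n, tail = "two_sided")
    move <- !is.na(best_k) & best != cur & best_k > cur_k & p_best < reassign_p
    if (!any(move) || iter > max_iter) {
      if (iter > max_iter) .warnf("gene reassignment did not converge in %d sweeps", max_iter)
      break
    }
    assignment[assigned[move]] <- best[move]
  }
  assignment <- .relabel_by_size(assignment)
  eig <- module_eigengene(em, assignment)
  kme <- module_membership(em, eig)
  structure(list(assignment = assignment, eigengenes = eig, kme = kme,
                 excluded_modules = character(0), n_iterations = iter),
            class = "module_decomposition")
}

#' @export
print.module_decomposition <- function(x, ...) {
  sizes <- table(x$assignment[x$assignment != UNASSIGNED])
  cat("Module decomposition:", length(sizes), "modules,",
      sum(x$assignment == UNASSIGNED), "unassigned genes\n")
  if (length(sizes)) print(sort(sizes, decreasing = TRUE))
  if (length(x$excluded_modules))
    cat("Excluded (overfit):", paste(x$excluded_modules, collapse = ", "), "\n")
  invisible(x)
}

#' Flag technically overfit modules
#'
#' A module is flagged when the samples whose eigengene values are more than
#' `z_cut` standard deviations from that eigengene's mean (i) exist, (ii)
#' number at most `max_samples`, and (iii) all come from a single bird —
#' the signature of a module fitted to individual samples rather than to
#' biological structure.
#'
#' @param eigengenes Modules x samples eigengene matrix.
#' @param samples Sample table aligned to the eigengene columns.
#' @param z_cut Outlier z threshold; default 4.
#' @param max_samples Maximum number of outlying samples; default 2.
#' @return Character vector of flagged module labels.
#' @export
flag_overfit_modules <- function(eigengenes, samples, z_cut = 4, max_samples = 2L) {
  if (ncol(eigengenes) < 4L) .stopf("overfit flagging needs >= 4 samples")
  birds <- samples$bird_id[match(colnames(eigengenes), samples$sample_id)]
  flagged <- character(0)
  for (m in rownames(eigengenes)) {
    v <- eigengenes[m, ]
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) next
    z <- (v - mean(v)) / s
    out <- which(abs(z) > z_cut)
    if (length(out) >= 1L && length(out) <= max_samples &&
        length(unique(birds[out])) == 1L)
      flagged <- c(flagged, m)
  }
  flagged
}

#' Attribute modules to individual birds
#'
#' For each module, correlates the eigengene against each bird's indicator
#' vector and reports the best-matching bird with its r-squared and two-sided
#' p-value. Modules tracking all samples of one animal (rather than a brain
#' region or treatment) show up with a large single-bird r-squared.
#'
#' @param eigengenes Modules x samples eigengene matrix.
#' @param samples Sample table aligned to the eigengene columns.
#' @return A data.frame with columns `module`, `bird_id`, `r2`, `p`.
#' @export
attribute_modules_to_birds <- function(eigengenes, samples) {
  birds <- samples$bird_id[match(colnames(eigengenes), samples$sample_id)]
  ids <- sort(unique(birds))
  res <- lapply(rownames(eigengenes), function(m) {
    v <- eigengenes[m, ]
    r <- vapply(ids, function(b) {
      ind <- as.numeric(birds == b)
      if (stats::sd(v) == 0 || stats::sd(ind) == 0) return(NA_real_)
      stats::cor(v, ind)
    }, numeric(1L))
    best <- which.max(abs(r))
    data.frame(module = m, bird_id = ids[best], r2 = r[best]^2,
               p = .cor_p(abs(r[best]), length(v), "two_sided"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
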