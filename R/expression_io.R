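# Reading the tabular inputs, FPKM normalization, expression filtering and
# outlier-sample QC. The pipeline starts at the gene-level fragment count
# matrix; alignment and counting are upstream and out of scope.

#' Read a gene-level fragment count matrix from TSV
#'
#' Expects a tab-delimited file with a header row of sample ids and gene ids
#' in the first column. Counts must be non-negative integers (fragments per
#' gene per sample). Row and column order are preserved.
#'
#' @param path Path to the TSV file.
#' @return An integer-valued numeric matrix, genes x samples, with gene ids as
#'   rownames and sample ids as colnames.
#' @export
read_count_matrix <- function(path) {
  first <- tryCatch(readLines(path, n = 1L), error = function(e) character(0))
  if (length(first) == 0L || !nzchar(first))
    .stopf("count matrix '%s' is empty: missing header row of sample ids", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    .stopf("count matrix '%s' has no sample columns", path)
  gene_ids <- as.character(df[[1L]])
  counts <- as.matrix(df[, -1L, drop = FALSE])
  rownames(counts) <- gene_ids
  validate_count_matrix(counts)
  counts
}

#' Validate count-matrix invariants
#'
#' Checks for duplicate gene/sample ids and negative or non-integer counts.
#'
#' @param counts A genes x samples matrix with dimnames.
#' @return The matrix, invisibly, if valid; otherwise an error.
#' @export
validate_count_matrix <- function(counts) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    .stopf("count matrix must carry gene ids (rownames) and sample ids (colnames)")
  if (anyDuplicated(rownames(counts)))
    .stopf("duplicate gene id(s): %s",
           paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    .stopf("duplicate sample id(s): %s",
           paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (!is.numeric(counts)) .stopf("counts must be numeric")
  if (anyNA(counts)) .stopf("counts contain missing values")
  if (any(counts < 0)) .stopf("counts must be non-negative")
  if (any(abs(counts - round(counts)) > 1e-8)) .stopf("counts must be integers")
  invisible(counts)
}

#' Read a gene metadata table from TSV
#'
#' Requires columns `gene_id`, `chromosome`, `length_bp` (summed exonic
#' length); an optional `human_ortholog` column is carried through.
#'
#' @param path Path to the TSV file.
#' @return A data.frame, one row per gene.
#' @export
read_gene_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("gene_id", "chromosome", "length_bp")
  miss <- setdiff(need, names(df))
  if (length(miss)) .stopf("gene table missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(df$gene_id)) .stopf("gene table has duplicated gene_id rows")
  if (any(!nzchar(df$chromosome))) .stopf("gene table has empty chromosome labels")
  if (any(df$length_bp <= 0)) .stopf("gene table has non-positive length_bp")
  df
}

#' Read the sample design table from TSV
#'
#' Requires columns `sample_id`, `bird_id`, `sex`, `treatment`, `region`.
#' `region_class` and `node` are derived from the fixed nucleus-surround
#' pairing if absent, and checked against it if present.
#'
#' @param path Path to the TSV file.
#' @return A data.frame, one row per sample.
#' @export
read_sample_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  validate_sample_table(df)
}

#' Validate and complete a sample design table
#'
#' @param df A data.frame with at least `sample_id`, `bird_id`, `sex`,
#'   `treatment`, `region`.
#' @return The completed data.frame with `region_class` and `node` columns.
#' @export
validate_sample_table <- function(df) {
  need <- c("sample_id", "bird_id", "sex", "treatment", "region")
  miss <- setdiff(need, names(df))
  if (length(miss)) .stopf("sample table missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) .stopf("sample table has duplicated sample_id rows")
  bad_sex <- setdiff(unique(df$sex), c("male", "female"))
  if (length(bad_sex)) .stopf("unknown sex level(s): %s", paste(bad_sex, collapse = ", "))
  bad_trt <- setdiff(unique(df$treatment), c("vehicle", "E2"))
  if (length(bad_trt)) .stopf("unknown treatment level(s): %s", paste(bad_trt, collapse = ", "))
  bad_reg <- setdiff(unique(df$region), names(.NODE_MAP))
  if (length(bad_reg)) .stopf("unknown region(s): %s", paste(bad_reg, collapse = ", "))
  pairing <- region_pairing()
  derived_class <- pairing$region_class[match(df$region, pairing$region)]
  derived_node <- pairing$node[match(df$region, pairing$region)]
  if ("region_class" %in% names(df)) {
    if (!identical(df$region_class, derived_class))
      .stopf("region_class inconsistent with the fixed nucleus-surround pairing")
  } else df$region_class <- derived_class
  if ("node" %in% names(df)) {
    if (!identical(df$node, derived_node))
      .stopf("node inconsistent with the fixed nucleus-surround pairing")
  } else df$node <- derived_node
  if (anyDuplicated(df[, c("bird_id", "region")]))
    .stopf("a bird contributes more than one sample for some region")
  df
}

#' Normalize fragment counts to FPKM
#'
#' FPKM = count * 1e9 / (length_bp * library_size), with library size taken as
#' the per-sample column sum of counts over all genes in the matrix
#' (normalization precedes any expression filtering).
#'
#' @param counts Genes x samples count matrix.
#' @param genes Gene table with `gene_id` and `length_bp`; every gene in
#'   `counts` must be present with positive length.
#' @return A genes x samples matrix of FPKM values.
#' @export
fpkm_normalize <- function(counts, genes) {
  validate_count_matrix(counts)
  idx <- match(rownames(counts), genes$gene_id)
  if (anyNA(idx))
    .stopf("gene(s) missing from gene table: %s",
           paste(utils::head(rownames(counts)[is.na(idx)], 5L), collapse = ", "))
  len <- genes$length_bp[idx]
  if (any(len <= 0)) .stopf("non-positive gene length in gene table")
  lib <- colSums(counts)
  if (any(lib <= 0))
    .stopf("zero library size for sample(s): %s",
           paste(colnames(counts)[lib <= 0], collapse = ", "))
  fpkm <- counts * 1e9 / outer(len, lib)
  dimnames(fpkm) <- dimnames(counts)
  fpkm
}

#' Filter to well-expressed genes
#'
#' Retains genes with FPKM at or above `min_fpkm` in at least `min_fraction`
#' of samples. The sample set is unchanged. Idempotent.
#'
#' @param em Genes x samples expression matrix (FPKM).
#' @param min_fpkm Expression threshold (FPKM); default 1.
#' @param min_fraction Minimum fraction of samples meeting the threshold, in
#'   `[0, 1]`; default 0.25.
#' @return The row-subset expression matrix.
#' @export
filter_expressed <- function(em, min_fpkm = 1, min_fraction = 0.25) {
  stopifnot(min_fraction >= 0, min_fraction <= 1)
  keep <- rowMeans(em >= min_fpkm) >= min_fraction
  if (!any(keep)) .warnf("expression filter removed all genes")
  em[keep, , drop = FALSE]
}

#' Detect outlier samples
#'
#' Flags samples whose mean 1 - Pearson distance to all other samples exceeds
#' mean + `z_cut` * SD of that statistic across samples (default mode), or
#' samples falling into small detached clusters of an average-linkage
#' dendrogram of the same distance (`method = "dendrogram"`). Deterministic
#' and invariant to sample order.
#'
#' @param em Genes x samples expression matrix; at least 4 samples.
#' @param z_cut Z-score threshold on the mean inter-sample distance; default 2.5.
#' @param method `"zscore"` (default) or `"dendrogram"`.
#' @param max_cluster_fraction For the dendrogram mode, clusters holding at
#'   most this fraction of samples are treated as outliers; default 0.1.
#' @return Character vector of flagged sample ids (possibly empty).
#' @export
detect_outlier_samples <- function(em, z_cut = 2.5,
                                   method = c("zscore", "dendrogram"),
                                   max_cluster_fraction = 0.1) {
  method <- match.arg(method)
  n <- ncol(em)
  if (n < 4L) .stopf("outlier detection needs at least 4 samples, got %d", n)
  keep <- apply(em, 1L, stats::sd) > 0
  if (!any(keep)) return(character(0))  # constant matrix: no outliers possible
  d <- 1 - stats::cor(em[keep, , drop = FALSE])
  if (method == "zscore") {
    mean_d <- (rowSums(d)) / (n - 1L)  # self-distance is 0
    s <- stats::sd(mean_d)
    if (!is.finite(s) || s == 0) return(character(0))
    flagged <- mean_d > mean(mean_d) + z_cut * s
    return(colnames(em)[flagged])
  }
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  off <- d[upper.tri(d)]
  h <- mean(off) + z_cut * stats::sd(off)
  if (!is.finite(h)) return(character(0))
  cl <- stats::cutree(hc, h = min(h, max(hc$height)))
  sizes <- table(cl)
  small <- as.integer(names(sizes)[sizes <= max_cluster_fraction * n])
  if (length(small) == length(sizes)) return(character(0))
  colnames(em)[cl %in% small]
}
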