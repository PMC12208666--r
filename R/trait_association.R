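# Module-eigengene and single-gene association to binarized design traits,
# with Student-t correlation p-values and the study's named contrast presets.
#
# Trait coding convention: 1 marks the song nucleus / vocal-capable / female
# class, so that positive correlations read as enrichment in that class.

# Student-t tail probability for a Pearson correlation at sample size n.
.cor_p <- function(r, n, tail = c("two_sided", "upper", "lower")) {
  tail <- match.arg(tail)
  df <- n - 2L
  r <- pmin(pmax(r, -1), 1)
  t <- r * sqrt(df) / sqrt(pmax(1 - r^2, 0))
  t[r == 1] <- Inf
  t[r == -1] <- -Inf
  switch(tail,
    two_sided = 2 * stats::pt(-abs(t), df),
    upper = stats::pt(t, df, lower.tail = FALSE),
    lower = stats::pt(t, df))
}

#' Pearson correlation with a Student-t p-value
#'
#' The test statistic is `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2`
#' degrees of freedom, the classical test for a Pearson correlation.
#'
#' @param x,y Numeric vectors of equal length (n >= 3), neither constant.
#' @param tail `"two_sided"` (default), `"upper"`, or `"lower"`.
#' @return A one-row data.frame with `r`, `r2`, `t`, `df`, `p`, `n`.
#' @export
correlation_test <- function(x, y, tail = c("two_sided", "upper", "lower")) {
  tail <- match.arg(tail)
  n <- length(x)
  if (length(y) != n) .stopf("x and y must have equal length")
  if (n < 3L) .stopf("correlation test needs n >= 3, got %d", n)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) .stopf("constant vector in correlation test")
  r <- stats::cor(x, y)
  df <- n - 2L
  t <- if (abs(r) >= 1) sign(r) * Inf else r * sqrt(df) / sqrt(1 - r^2)
  data.frame(r = r, r2 = r^2, t = t, df = df, p = .cor_p(r, n, tail), n = n)
}

#' Define a sample contrast
#'
#' A contrast is a subset rule (which samples take part) and a trait rule
#' (which of those samples form the 1 class), both predicates over the sample
#' table columns.
#'
#' @param name Contrast name.
#' @param subset Function of the sample table returning a logical vector.
#' @param trait Function of the *subset* sample table returning a logical
#'   vector (TRUE = class 1).
#' @param tail Test tail used for gene-level association.
#' @return A list of class `contrast_spec`.
#' @export
contrast_spec <- function(name, subset, trait, tail = "two_sided") {
  stopifnot(is.character(name), is.function(subset), is.function(trait))
  structure(list(name = name, subset = subset, trait = trait, tail = tail),
            class = "contrast_spec")
}

#' Materialize a contrast on a sample table
#'
#' @param samples Sample table.
#' @param spec A [contrast_spec()].
#' @return A list with `sample_ids` and the aligned 0/1 `trait` vector.
#' @export
build_contrast <- function(samples, spec) {
  sel <- spec$subset(samples)
  if (!any(sel)) .stopf("contrast '%s' selects no samples", spec$name)
  sub <- samples[sel, , drop = FALSE]
  trait <- as.integer(spec$trait(sub))
  if (length(unique(trait)) < 2L)
    .stopf("contrast '%s' has a single trait class", spec$name)
  list(sample_ids = sub$sample_id, trait = trait, name = spec$name, tail = spec$tail)
}

#' Named contrast presets of the study design
#'
#' Returns the built-in contrast families: per node and sex x treatment cell,
#' song nucleus vs surround; per node, E2-treated female song-system samples
#' vs all other female samples at that node (vocal-capable = 1); and per
#' region among vehicle-treated birds, female vs male (female = 1), split
#' into song-system and surround regions.
#'
#' @return Named list of [contrast_spec()] objects.
#' @export
contrast_presets <- function() {
  presets <- list()
  nodes <- unique(unname(.NODE_MAP))
  for (sx in c("male", "female")) for (tr in c("vehicle", "E2")) for (nd in nodes) {
    nm <- sprintf("%s_%s_%s_nucleus_vs_surround", sx, tr, sub("-", "_", nd))
    presets[[nm]] <- local({
      sx0 <- sx; tr0 <- tr; nd0 <- nd
      contrast_spec(nm,
        subset = function(s) s$sex == sx0 & s$treatment == tr0 & s$node == nd0,
        trait = function(s) s$region_class == "nucleus")
    })
  }
  for (nd in nodes) {
    nm <- sprintf("female_E2_vocal_%s", sub("-", "_", nd))
    presets[[nm]] <- local({
      nd0 <- nd
      contrast_spec(nm,
        subset = function(s) s$sex == "female" & s$node == nd0,
        trait = function(s) s$treatment == "E2" & s$region_class == "nucleus")
    })
  }
  for (rg in c(.NUCLEI, .SURROUNDS)) {
    nm <- sprintf("sex_vehicle_%s", rg)
    presets[[nm]] <- local({
      rg0 <- rg
      contrast_spec(nm,
        subset = function(s) s$treatment == "vehicle" & s$region == rg0,
        trait = function(s) s$sex == "female")
    })
  }
  presets
}

# Vectorized correlation test of every row of `em` (restricted to `ids`)
# against a trait vector.
.assoc_rows <- function(em, ids, trait, tail, what) {
  X <- t(em[, ids, drop = FALSE])
  r <- .cor_vec(X, trait)
  n <- length(trait)
  df <- n - 2L
  t <- ifelse(abs(r) >= 1, sign(r) * Inf, r * sqrt(df) / sqrt(pmax(1 - r^2, 1e-300)))
  p <- .cor_p(r, n, tail)
  out <- data.frame(id = rownames(em), r = r, r2 = r^2, t = t, df = df,
                    p = p, n = n, stringsAsFactors = FALSE)
  names(out)[1L] <- what
  out
}

#' Associate module eigengenes with a contrast
#'
#' One correlation test per non-excluded module between its eigengene values
#' over the contrast's samples and the 0/1 trait.
#'
#' @param eigengenes Modules x samples eigengene matrix.
#' @param samples Sample table.
#' @param spec A [contrast_spec()] (or the list from [build_contrast()]).
#' @param alpha Significance level for the `significant` flag; default 0.05.
#' @param exclude Module labels to drop (e.g. overfit modules).
#' @param tail Test tail; default two-sided.
#' @return Data.frame with one row per module: `module`, `contrast`, `r`,
#'   `r2`, `t`, `df`, `p`, `n`, `significant`.
#' @export
associate_modules <- function(eigengenes, samples, spec, alpha = 0.05,
                              exclude = character(0), tail = "two_sided") {
  ct <- if (inherits(spec, "contrast_spec")) build_contrast(samples, spec) else spec
  missing_ids <- setdiff(ct$sample_ids, colnames(eigengenes))
  if (length(missing_ids))
    .stopf("contrast '%s' selects sample(s) absent from the eigengenes: %s",
           ct$name, paste(utils::head(missing_ids, 3L), collapse = ", "))
  em <- eigengenes[setdiff(rownames(eigengenes), exclude), , drop = FALSE]
  out <- .assoc_rows(em, ct$sample_ids, ct$trait, tail, "module")
  out$contrast <- ct$name
  out$significant <- !is.na(out$p) & out$p < alpha
  out[, c("module", "contrast", "r", "r2", "t", "df", "p", "n", "significant")]
}

#' Associate single genes with a contrast
#'
#' As [associate_modules()] but applied to gene rows, with one-tailed support
#' for the sex-chromosome tests. Constant genes are reported with `NA`.
#'
#' @inheritParams associate_modules
#' @param em Genes x samples expression matrix.
#' @return Data.frame with one row per gene.
#' @export
associate_genes <- function(em, samples, spec, tail = c("two_sided", "upper", "lower"),
                            alpha = 0.05) {
  tail <- match.arg(tail)
  ct <- if (inherits(spec, "contrast_spec")) build_contrast(samples, spec) else spec
  missing_ids <- setdiff(ct$sample_ids, colnames(em))
  if (length(missing_ids))
    .stopf("contrast '%s' selects sample(s) absent from the expression matrix: %s",
           ct$name, paste(utils::head(missing_ids, 3L), collapse = ", "))
  out <- .assoc_rows(em, ct$sample_ids, ct$trait, tail, "gene_id")
  out$contrast <- ct$name
  out$significant <- !is.na(out$p) & out$p < alpha
  out
}
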