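# Internal helpers shared across modules.

# The fixed nucleus-surround pairing of the song circuit.
.NODE_MAP <- c(
  HVC = "HVC-DN", DN = "HVC-DN",
  RA = "RA-LAI", LAI = "RA-LAI",
  LMAN = "LMAN-AN", AN = "LMAN-AN",
  AreaX = "AreaX-Str", Str = "AreaX-Str"
)
.NUCLEI <- c("HVC", "RA", "LMAN", "AreaX")
.SURROUNDS <- c("DN", "LAI", "AN", "Str")

#' Region metadata for the song circuit
#'
#' Returns the fixed pairing of the four song nuclei with their surrounding
#' motor control regions and the circuit node each pair forms.
#'
#' @return A data.frame with columns `region`, `region_class`
#'   (`"nucleus"`/`"surround"`), and `node`.
#' @export
region_pairing <- function() {
  regions <- c(.NUCLEI, .SURROUNDS)
  data.frame(
    region = regions,
    region_class = rep(c("nucleus", "surround"), each = 4L),
    node = unname(.NODE_MAP[regions]),
    stringsAsFactors = FALSE
  )
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Column-wise Pearson correlation of matrix columns with a vector, tolerating
# zero-variance columns (returned as NA rather than an error/warning).
.cor_vec <- function(X, y) {
  sx <- apply(X, 2L, stats::sd)
  r <- rep(NA_real_, ncol(X))
  ok <- is.finite(sx) & sx > 0 & stats::sd(y) > 0
  if (any(ok)) r[ok] <- as.vector(stats::cor(X[, ok, drop = FALSE], y))
  r
}

#' Adjusted Rand index between two labelings
#'
#' Permutation-model-corrected agreement between two partitions of the same
#' items; 1 means identical partitions, 0 is chance-level agreement. Used to
#' score recovery of planted modules by the network pipeline.
#'
#' @param a,b Vectors of cluster labels of equal length.
#' @return The adjusted Rand index, a scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) .stopf("labelings have different lengths")
  tab <- table(a, b)
  n <- sum(tab)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  expected <- sum_a * sum_b / ch2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

# Derive a per-stage 32-bit seed from a master seed, keeping results
# reproducible from one number while decoupling stages.
.derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  (as.integer(seed) %% 1000003L) * 31L + sum(utf8ToInt(stage)) %% 997L
}

# Write a numeric matrix as TSV with row ids in the first column.
.write_matrix_tsv <- function(m, path, id_col = "gene_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  m
}
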