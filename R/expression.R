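#' Remove genes with zero counts in more than half the samples
#'
#' A gene is removed iff it has 0 reads in strictly more than 50% of the
#' samples; a gene with zeros in exactly half of them is kept.
#'
#' @param counts Non-negative integer matrix, genes x samples.
#' @return The filtered count matrix.
#' @export
filter_zero_genes <- function(counts) {
  if (any(counts < 0)) stop("negative counts")
  zeros <- rowSums(counts == 0)
  counts[zeros <= 0.5 * ncol(counts), , drop = FALSE]
}

#' Counts-per-million, log2 transformed
#'
#' Library-size normalization to counts per million followed by
#' `log2(cpm + 1)`; the pseudo-count of 1 avoids zeros. The pre-log cpm
#' columns each sum to 1e6.
#'
#' @param counts Filtered count matrix, genes x samples.
#' @return Matrix of `log2(cpm + 1)` values, same dimnames.
#' @export
cpm_log2 <- function(counts) {
  lib <- colSums(counts)
  if (any(lib == 0))
    stop("zero library size for sample(s): ",
         paste(colnames(counts)[lib == 0], collapse = ", "))
  log2(edgeR::cpm(counts) + 1)
}

#' Per-gene expression z-values
#'
#' Standardizes each feature against its cohort mean and standard deviation
#' (sample sd, n-1 denominator). Features with zero variance get `NA`
#' z-values and can never be flagged as dysregulated.
#'
#' @param m Normalized expression matrix, features x samples.
#' @return Matrix of z-values.
#' @export
z_values <- function(m) {
  mu <- rowMeans(m)
  sd <- apply(m, 1, stats::sd)
  degen <- sd == 0
  if (any(degen)) {
    message(sum(degen), " feature(s) with zero variance: z undefined")
    sd[degen] <- NA_real_
  }
  (m - mu) / sd
}

#' Dysregulation flag from z-values
#'
#' A feature is potentially dysregulated in a sample iff its z-value is
#' strictly below -1 or strictly above 1; `NA` z-values are never flagged.
#'
#' @param z Matrix of z-values.
#' @return Logical matrix of the same shape.
#' @export
z_flags <- function(z) {
  fl <- z < -1 | z > 1
  fl[is.na(fl)] <- FALSE
  fl
}

#' Convert ASCAT allele counts to the 5-level GISTIC code
#'
#' Total copy number (nMinor + nMajor) of 0 maps to -2 (homozygous loss), 1
#' to -1 (hemizygous loss), 2 to 0 (normal), 3 to 1 (gain), and more than 3
#' to 2 (amplification).
#'
#' @param nMinor,nMajor Non-negative integer vectors of minor/major allele
#'   copy numbers.
#' @return Integer vector in `{-2,-1,0,1,2}`.
#' @export
ascat_to_gistic <- function(nMinor, nMajor) {
  if (any(nMinor < 0) || any(nMajor < 0)) stop("negative allele counts")
  total <- nMinor + nMajor
  ifelse(total == 0, -2L,
         ifelse(total == 1, -1L,
                ifelse(total == 2, 0L,
                       ifelse(total == 3, 1L, 2L))))
}

#' Filter to expressed genes via a two-component mixture
#'
#' Computes the 90th percentile of each feature's expression across samples,
#' decomposes the distribution of these per-feature values into two Gaussian
#' components (low and high expression) by EM, and keeps the features whose
#' posterior probability of belonging to the high component is at least
#' `posterior_min`.
#'
#' @param m Normalized expression matrix, features x samples (at least 20
#'   features so the mixture is fittable).
#' @param posterior_min Minimum posterior of the high component; default 0.8.
#' @return Character vector of retained feature ids.
#' @export
expressed_gene_filter <- function(m, posterior_min = 0.8) {
  if (nrow(m) < 20)
    stop("need at least 20 features to fit the expressed/unexpressed mixture")
  p90 <- apply(m, 1, stats::quantile, probs = 0.9, names = FALSE)
  if (stats::sd(p90) == 0)
    stop("all 90th-percentile values identical; mixture unfit. ",
         "Bypass this filter for pre-filtered input.")
  fit <- gaussian_mixture_em(p90, k = 2)
  post_high <- mixture_posteriors(p90, fit)[, 2]
  rownames(m)[post_high >= posterior_min]
}

#' Read an expression matrix from TSV
#'
#' Feature rows by sample columns, first column feature ids, header row of
#' sample ids.
#'
#' @param path Path to the TSV.
#' @return Numeric matrix with dimnames.
#' @export
read_expression <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                          check.names = FALSE)
  as.matrix(df)
}

#' Write an expression matrix as TSV
#'
#' @param m Matrix with dimnames.
#' @param path Output path.
#' @param feature_col Name of the leading feature-id column.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path, feature_col = "feature") {
  df <- data.frame(rownames(m), m, check.names = FALSE)
  names(df)[1] <- feature_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a matrix in MatrixMarket form with row/column name files
#'
#' @param mtx Path to the `.mtx` file.
#' @param row_names,col_names Paths to one-name-per-line text files.
#' @return Dense numeric matrix with dimnames.
#' @export
read_expression_mtx <- function(mtx, row_names, col_names) {
  m <- as.matrix(Matrix::readMM(mtx))
  rownames(m) <- readLines(row_names)
  colnames(m) <- readLines(col_names)
  m
}

#' Read a gene x sample CNA matrix (GISTIC coding) from TSV
#'
#' @param path Path to the TSV (gene rows, sample columns).
#' @return Integer matrix; errors on values outside `{-2,...,2}`.
#' @export
read_cna <- function(path) {
  m <- read_expression(path)
  if (!all(m %in% -2:2)) stop("CNA values outside the 5-level GISTIC code")
  storage.mode(m) <- "integer"
  m
}
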