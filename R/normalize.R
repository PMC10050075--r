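#' Library-size normalization of a count matrix
#'
#' Scales each sample column to the mean library size, so that column sums
#' are equal after scaling and a sample's profile is invariant to its
#' sequencing depth.
#'
#' @param x A [quant_matrix] of non-negative counts.
#' @return A [quant_matrix] with equal column sums.
#' @export
library_size_normalize <- function(x) {
  stopifnot(inherits(x, "quant_matrix"))
  if (any(x$values < 0)) abort("Counts must be non-negative.")
  tot <- colSums(x$values)
  zero <- which(tot == 0)
  if (length(zero)) {
    abort(paste0("All-zero sample column(s): ",
                 paste(x$sample_id[zero], collapse = ", ")))
  }
  scaled <- sweep(x$values, 2, mean(tot) / tot, `*`)
  quant_matrix(x$phenotypes, scaled, x$sample_id, x$phenotype_class, quiet = TRUE)
}

#' Drop genes with too many null quantifications
#'
#' Keeps genes whose fraction of zero values is at most `max_null_fraction`
#' (strictly more than the threshold is removed, so exactly 10% of zeros is
#' kept at the default).
#'
#' @param x A [quant_matrix] with `phenotype_class = "gene"`.
#' @param max_null_fraction Maximum tolerated fraction of zeros (default 0.10).
#' @return A filtered [quant_matrix].
#' @export
filter_expressed_genes <- function(x, max_null_fraction = 0.10) {
  stopifnot(inherits(x, "quant_matrix"))
  if (x$phenotype_class != "gene") abort("filter_expressed_genes expects a gene matrix.")
  frac0 <- rowMeans(x$values == 0)
  keep <- frac0 <= max_null_fraction
  quant_matrix(x$phenotypes[keep, , drop = FALSE],
               x$values[keep, , drop = FALSE],
               x$sample_id, x$phenotype_class, quiet = TRUE)
}

#' Residualize phenotypes on sample covariates
#'
#' Replaces every phenotype row by its OLS residuals on the covariate matrix
#' (an intercept is always included). Residuals are orthogonal to every
#' covariate column.
#'
#' @param x A [quant_matrix].
#' @param covariates Numeric matrix or data frame, samples x k (k may be 0
#'   for intercept-only centering). Rank-deficient covariates are an error.
#' @return A [quant_matrix] of residuals.
#' @export
residualize <- function(x, covariates = NULL) {
  stopifnot(inherits(x, "quant_matrix"))
  n <- length(x$sample_id)
  cov <- if (is.null(covariates)) matrix(numeric(0), n, 0) else as.matrix(covariates)
  if (nrow(cov) != n) abort("Covariate rows must match the sample count.")
  if (ncol(cov) >= n) abort("Need fewer covariates than samples.")
  design <- cbind(`(Intercept)` = 1, cov)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    drop_idx <- qrd$pivot[(qrd$rank + 1):ncol(design)]
    nms <- colnames(design)[drop_idx]
    abort(paste0("Collinear covariate column(s): ", paste(nms, collapse = ", ")))
  }
  resid <- t(qr.resid(qrd, t(x$values)))
  quant_matrix(x$phenotypes, resid, x$sample_id, x$phenotype_class, quiet = TRUE)
}

#' Sample principal components of a quantification matrix
#'
#' PCA with samples as observations (phenotypes as variables), on centered
#' rows. Returns the first `k` PC coordinate columns for use as covariates.
#'
#' @param x A [quant_matrix].
#' @param k Number of components.
#' @return Numeric matrix, samples x k.
#' @export
sample_pcs <- function(x, k) {
  stopifnot(inherits(x, "quant_matrix"))
  if (k >= length(x$sample_id)) abort("k must be smaller than the sample count.")
  pr <- prcomp(t(x$values), center = TRUE, scale. = FALSE)
  pr$x[, seq_len(k), drop = FALSE]
}

#' Select the number of expression/chromatin PCs by QTL yield
#'
#' Residualizes the matrix on an increasing number of its own sample PCs
#' (computed once, on the input matrix), maps cis-QTLs at each grid point and
#' returns the grid value that maximizes the number of significant QTLs
#' (smallest value on ties). The full yield table is attached as the
#' `"yield"` attribute.
#'
#' @param x A [quant_matrix] (library-normalized).
#' @param genotypes A [geno_matrix].
#' @param grid Integer vector of PC counts to try.
#' @param cis_window_bp Cis window around each phenotype (bp).
#' @param fdr FDR level for calling a QTL significant.
#' @param n_perm Permutations per phenotype (kept small here; the sweep only
#'   ranks grid values).
#' @param seed Integer seed for the permutation engine.
#' @return The selected PC count (integer) with attribute `yield`.
#' @export
select_n_pcs <- function(x, genotypes, grid, cis_window_bp = 1e6, fdr = 0.05,
                         n_perm = 100, seed = 1L) {
  if (!length(grid)) abort("PC grid is empty.")
  grid <- sort(unique(as.integer(grid)))
  if (any(grid >= length(x$sample_id))) abort("Grid values must be < n_samples.")
  pcs_all <- sample_pcs(x, max(grid))
  yield <- map_int(grid, function(k) {
    cov <- if (k > 0) pcs_all[, seq_len(k), drop = FALSE] else NULL
    corrected <- rank_normal(residualize(x, cov))
    res <- map_cis(corrected, genotypes, window_bp = cis_window_bp,
                   n_perm = n_perm, fdr = fdr, seed = seed)
    sum(res$significant, na.rm = TRUE)
  })
  best <- grid[which.max(yield)]  # which.max takes the first (smallest) on ties
  attr(best, "yield") <- tibble(n_pcs = grid, n_qtls = yield)
  best
}

#' Rank-based inverse normal transform, per phenotype
#'
#' Each phenotype row is mapped to `qnorm((rank - 0.5) / n)` with ties given
#' their average rank, so quantifications match a normal distribution while
#' preserving the within-row order. Constant rows are an error (no rank
#' order exists).
#'
#' @param x A [quant_matrix].
#' @return A [quant_matrix] of normal scores.
#' @export
rank_normal <- function(x) {
  stopifnot(inherits(x, "quant_matrix"))
  n <- ncol(x$values)
  const <- which(apply(x$values, 1, function(v) max(v) == min(v)))
  if (length(const)) {
    abort(paste0("Constant phenotype row(s), cannot rank-normalize: ",
                 paste(head(x$phenotypes$phenotype_id[const], 5), collapse = ", ")))
  }
  out <- t(apply(x$values, 1, function(v) qnorm((rank(v, ties.method = "average") - 0.5) / n)))
  quant_matrix(x$phenotypes, out, x$sample_id, x$phenotype_class, quiet = TRUE)
}
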