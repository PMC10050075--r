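#' Quantification matrix of molecular phenotypes
#'
#' A `quant_matrix` bundles a phenotype annotation tibble (id, chromosome,
#' 0-based half-open interval) with a numeric matrix of quantifications,
#' phenotypes in rows and samples in columns. It is the common container for
#' ChIP-seq peaks, CpG probes (stored as width-1 intervals) and genes, so the
#' domain caller and the association engine are agnostic to phenotype class.
#'
#' Rows are kept sorted by (chromosome, start); a warning is emitted if the
#' input had to be re-sorted. Duplicate phenotype ids are an error, as is any
#' interval with `end <= start`.
#'
#' @param phenotypes Tibble with columns `phenotype_id`, `chrom`, `start`,
#'   `end` (0-based half-open).
#' @param values Numeric matrix, `nrow(phenotypes)` x n_samples.
#' @param sample_id Character vector of sample names (column order of
#'   `values`).
#' @param phenotype_class One of `"peak"`, `"cpg"`, `"gene"`.
#' @param quiet Suppress the re-sorting warning.
#'
#' @return An object of class `quant_matrix`.
#' @export
quant_matrix <- function(phenotypes, values, sample_id,
                         phenotype_class = c("peak", "cpg", "gene"),
                         quiet = FALSE) {
  phenotype_class <- match.arg(phenotype_class)
  phenotypes <- as_tibble(phenotypes)
  stopifnot(all(c("phenotype_id", "chrom", "start", "end") %in% names(phenotypes)))
  values <- as.matrix(values)
  if (nrow(phenotypes) != nrow(values)) {
    abort("`phenotypes` and `values` disagree on the number of phenotypes.")
  }
  if (length(sample_id) != ncol(values)) {
    abort("`sample_id` length does not match the number of value columns.")
  }
  if (anyDuplicated(phenotypes$phenotype_id)) {
    dup <- phenotypes$phenotype_id[duplicated(phenotypes$phenotype_id)]
    abort(paste0("Duplicate phenotype ids: ", paste(head(unique(dup), 5), collapse = ", ")))
  }
  bad <- which(phenotypes$end <= phenotypes$start)
  if (length(bad)) {
    abort(paste0("Intervals with end <= start (0-based half-open expected): ",
                 paste(head(phenotypes$phenotype_id[bad], 5), collapse = ", ")))
  }
  ord <- order(phenotypes$chrom, phenotypes$start, phenotypes$end)
  if (!identical(ord, seq_len(nrow(phenotypes)))) {
    if (!quiet) warn("Phenotypes were not sorted by (chrom, start); re-sorting.")
    phenotypes <- phenotypes[ord, , drop = FALSE]
    values <- values[ord, , drop = FALSE]
  }
  rownames(values) <- phenotypes$phenotype_id
  colnames(values) <- sample_id
  structure(
    list(phenotypes = phenotypes, values = values,
         sample_id = as.character(sample_id), phenotype_class = phenotype_class),
    class = "quant_matrix"
  )
}

#' @export
print.quant_matrix <- function(x, ...) {
  cat(sprintf("<quant_matrix> %d %s phenotypes x %d samples, %d chromosome(s)\n",
              nrow(x$values), x$phenotype_class, ncol(x$values),
              length(unique(x$phenotypes$chrom))))
  invisible(x)
}

#' @export
dim.quant_matrix <- function(x) dim(x$values)

#' Coerce a quant_matrix to a long tibble
#'
#' @param x A `quant_matrix`.
#' @param ... Unused.
#' @return A tibble with one row per phenotype x sample.
#' @export
as_tibble.quant_matrix <- function(x, ...) {
  wide <- bind_cols_quiet(x$phenotypes, as_tibble(x$values))
  tidyr::pivot_longer(wide, cols = all_of(x$sample_id),
                      names_to = "sample_id", values_to = "value")
}

bind_cols_quiet <- function(a, b) {
  out <- a
  for (nm in names(b)) out[[nm]] <- b[[nm]]
  out
}

#' Subset a quant_matrix by phenotype ids
#'
#' @param x A `quant_matrix`.
#' @param ids Phenotype ids to keep (order of the stored matrix preserved).
#' @return A `quant_matrix`.
#' @export
qm_subset <- function(x, ids) {
  keep <- x$phenotypes$phenotype_id %in% ids
  quant_matrix(x$phenotypes[keep, , drop = FALSE],
               x$values[keep, , drop = FALSE],
               x$sample_id, x$phenotype_class, quiet = TRUE)
}

#' Genotype dosage matrix
#'
#' Variant annotation (1-based positions, VCF convention) plus a dosage
#' matrix in `[0, 2]`, variants in rows, samples in columns. The per-variant
#' minor allele frequency is `min(f, 1 - f)` of the mean dosage over 2.
#'
#' @param variants Tibble with `variant_id`, `chrom`, `pos`, `ref`, `alt`.
#' @param dosages Numeric matrix, variants x samples, values in `[0, 2]`.
#' @param sample_id Character vector of sample names.
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(variants, dosages, sample_id) {
  variants <- as_tibble(variants)
  stopifnot(all(c("variant_id", "chrom", "pos", "ref", "alt") %in% names(variants)))
  dosages <- as.matrix(dosages)
  if (nrow(variants) != nrow(dosages)) abort("variants/dosages row mismatch.")
  if (length(sample_id) != ncol(dosages)) abort("sample_id/dosages column mismatch.")
  if (length(sample_id) == 0) abort("Genotype matrix has no samples.")
  rng <- range(dosages)
  if (rng[1] < 0 || rng[2] > 2) abort("Dosages must lie in [0, 2].")
  ord <- order(variants$chrom, variants$pos)
  variants <- variants[ord, , drop = FALSE]
  dosages <- dosages[ord, , drop = FALSE]
  f <- rowMeans(dosages) / 2
  variants$maf <- pmin(f, 1 - f)
  rownames(dosages) <- variants$variant_id
  colnames(dosages) <- sample_id
  structure(list(variants = variants, dosages = dosages,
                 sample_id = as.character(sample_id)),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d variants x %d samples\n",
              nrow(x$dosages), ncol(x$dosages)))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosages)
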