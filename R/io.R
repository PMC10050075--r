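#' Read a phenotype quantification matrix in BED dialect
#'
#' The expected layout is the QTL-mapping BED dialect: a header line
#' `#chr start end id <sample ...>` followed by one row per phenotype with
#' 0-based half-open coordinates and one numeric column per sample. Files may
#' be gzip-compressed (transparent via [readr::read_tsv()]).
#'
#' @param path File path (optionally `.gz`).
#' @param phenotype_class Phenotype class of the file contents
#'   (`"peak"`, `"cpg"` or `"gene"`).
#' @return A [quant_matrix].
#' @export
read_phenotype_bed <- function(path, phenotype_class = c("peak", "cpg", "gene")) {
  phenotype_class <- match.arg(phenotype_class)
  hdr <- strsplit(readr::read_lines(path, n_max = 1), "\t", fixed = TRUE)[[1]]
  if (length(hdr) < 5) abort("Phenotype BED needs chrom,start,end,id plus >= 1 sample column.")
  types <- setNames(rep(list(readr::col_double()), length(hdr)), hdr)
  types[[hdr[1]]] <- readr::col_character()
  types[[hdr[4]]] <- readr::col_character()
  tab <- readr::read_tsv(path, col_types = do.call(readr::cols, types),
                         progress = FALSE)
  names(tab)[1:4] <- c("chrom", "start", "end", "phenotype_id")
  bad <- which(!is.finite(tab$start) | !is.finite(tab$end) |
                 tab$start != floor(tab$start) | tab$end != floor(tab$end))
  if (length(bad)) {
    abort(paste0("Malformed coordinates at data line(s): ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  tab$start <- as.integer(tab$start)
  tab$end <- as.integer(tab$end)
  samples <- names(tab)[-(1:4)]
  quant_matrix(
    tab[, c("phenotype_id", "chrom", "start", "end")],
    as.matrix(tab[, samples, drop = FALSE]),
    samples, phenotype_class
  )
}

#' Write a quant_matrix in the phenotype BED dialect
#'
#' @param x A [quant_matrix].
#' @param path Output path (gzip if it ends in `.gz`).
#' @return `path`, invisibly.
#' @export
write_phenotype_bed <- function(x, path) {
  tab <- bind_cols_quiet(
    tibble(`#chr` = x$phenotypes$chrom, start = x$phenotypes$start,
           end = x$phenotypes$end, id = x$phenotypes$phenotype_id),
    as_tibble(x$values)
  )
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}

#' Read genotypes from a VCF or a dosage table
#'
#' VCF 4.x records are converted to dosages from the `DS` FORMAT field when
#' present, otherwise from `GT` (`0/0 -> 0`, `0/1 -> 1`, `1/1 -> 2`).
#' Missing genotypes are mean-imputed per variant (count reported via a
#' message). Multiallelic records are skipped with a warning. A dosage table
#' uses the same column layout as the phenotype BED dialect with `pos` in
#' place of the interval (columns `chrom pos variant_id ref alt <sample...>`).
#'
#' @param path Path to a `.vcf`/`.vcf.gz` file or a dosage TSV.
#' @return A [geno_matrix].
#' @export
read_genotypes <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path)) read_vcf_dosages(path) else read_dosage_table(path)
}

read_vcf_dosages <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!startsWith(lines, "##")]
  if (!length(lines) || !startsWith(lines[1], "#CHROM")) abort("Not a VCF: missing #CHROM header.")
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(hdr) < 10) abort("VCF has no sample columns.")
  samples <- hdr[-(1:9)]
  recs <- lines[-1]
  recs <- recs[nzchar(recs)]
  variants <- vector("list", length(recs))
  dos <- matrix(NA_real_, length(recs), length(samples))
  n_imputed <- 0L
  keep <- logical(length(recs))
  for (i in seq_along(recs)) {
    f <- strsplit(recs[i], "\t", fixed = TRUE)[[1]]
    if (grepl(",", f[5], fixed = TRUE)) {
      warn(paste0("Skipping multiallelic record ", f[3], " at ", f[1], ":", f[2]))
      next
    }
    fmt <- strsplit(f[9], ":", fixed = TRUE)[[1]]
    ds_i <- match("DS", fmt)
    gt_i <- match("GT", fmt)
    vals <- vapply(f[-(1:9)], function(s) {
      parts <- strsplit(s, ":", fixed = TRUE)[[1]]
      if (!is.na(ds_i) && length(parts) >= ds_i && parts[ds_i] != ".") {
        return(as.numeric(parts[ds_i]))
      }
      if (is.na(gt_i)) return(NA_real_)
      gt <- gsub("|", "/", parts[gt_i], fixed = TRUE)
      if (gt %in% c("./.", ".")) return(NA_real_)
      sum(as.integer(strsplit(gt, "/", fixed = TRUE)[[1]]) > 0)
    }, numeric(1), USE.NAMES = FALSE)
    if (anyNA(vals)) {
      n_imputed <- n_imputed + sum(is.na(vals))
      m <- mean(vals, na.rm = TRUE)
      if (is.nan(m)) m <- 0
      vals[is.na(vals)] <- m
    }
    dos[i, ] <- vals
    vid <- if (f[3] == ".") paste0(f[1], ":", f[2], "_", f[4], "_", f[5]) else f[3]
    variants[[i]] <- tibble(variant_id = vid, chrom = f[1],
                            pos = as.integer(f[2]), ref = f[4], alt = f[5])
    keep[i] <- TRUE
  }
  if (!any(keep)) abort("VCF contained no usable biallelic records.")
  if (n_imputed > 0) inform(paste0("Mean-imputed ", n_imputed, " missing genotype(s)."))
  geno_matrix(bind_rows(variants[keep]), dos[keep, , drop = FALSE], samples)
}

read_dosage_table <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), pos = readr::col_integer(),
    variant_id = readr::col_character(), ref = readr::col_character(),
    alt = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  need <- c("chrom", "pos", "variant_id", "ref", "alt")
  if (!all(need %in% names(tab))) {
    abort("Dosage table needs columns chrom, pos, variant_id, ref, alt, <samples...>.")
  }
  samples <- setdiff(names(tab), need)
  if (!length(samples)) abort("Dosage table has no sample columns.")
  geno_matrix(tab[, c("variant_id", "chrom", "pos", "ref", "alt")],
              as.matrix(tab[, samples, drop = FALSE]), samples)
}

#' Write a geno_matrix as a dosage table
#'
#' @param x A [geno_matrix].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_dosage_table <- function(x, path) {
  tab <- bind_cols_quiet(
    x$variants[, c("chrom", "pos", "variant_id", "ref", "alt")],
    as_tibble(x$dosages)
  )
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}

#' Write / read called CRDs in a BED-like dialect
#'
#' Columns: chrom, start, end, crd_id, n_members, mean_internal_abs_r,
#' comma-separated member phenotype ids, class. Round-trip stable.
#'
#' @param crds CRD tibble as returned by [call_crds()].
#' @param path File path.
#' @return `path` invisibly for the writer; a CRD tibble for the reader.
#' @export
write_crds <- function(crds, path) {
  out <- tibble(
    `#chr` = crds$chrom, start = crds$start, end = crds$end,
    crd_id = crds$crd_id, n_members = crds$n_members,
    mean_internal_abs_r = crds$mean_internal_abs_r,
    members = map_chr(crds$members, paste, collapse = ","),
    class = crds$class
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @param validate_against Optional [quant_matrix]; member ids absent from it
#'   are an error.
#' @rdname write_crds
#' @export
read_crds <- function(path, validate_against = NULL) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character(), start = readr::col_integer(),
    end = readr::col_integer(), n_members = readr::col_integer(),
    mean_internal_abs_r = readr::col_double()
  ), progress = FALSE)
  names(tab)[1] <- "chrom"
  crds <- tibble(
    crd_id = tab$crd_id, chrom = tab$chrom, start = tab$start, end = tab$end,
    n_members = tab$n_members, mean_internal_abs_r = tab$mean_internal_abs_r,
    members = strsplit(tab$members, ",", fixed = TRUE), class = tab$class
  )
  if (!is.null(validate_against)) {
    known <- validate_against$phenotypes$phenotype_id
    orphan <- setdiff(unlist(crds$members), known)
    if (length(orphan)) {
      abort(paste0("CRD member ids not present in the supplied matrix: ",
                   paste(head(orphan, 5), collapse = ", ")))
    }
  }
  crds
}

#' Read a gene TSS annotation table
#'
#' Four tab-separated columns: `gene_id`, `chrom`, `tss` (1-based), `strand`.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_tss <- function(path) {
  tab <- readr::read_tsv(path, col_types = "ccic", progress = FALSE)
  names(tab) <- c("gene_id", "chrom", "tss", "strand")
  if (anyDuplicated(tab$gene_id)) abort("Duplicate gene_id in TSS table.")
  if (!all(tab$strand %in% c("+", "-"))) abort("Strand must be + or -.")
  tab
}

#' Read a fragment-pair interaction score table
#'
#' Tab-separated with two fragment triplets and one or more score columns:
#' `chromA startA endA chromB startB endB <score...>` (0-based half-open).
#'
#' @param path File path.
#' @return A tibble with a single `score` column (row maximum over the score
#'   columns, matching the "score >= 5 in at least one cell type" rule) plus
#'   the per-column scores.
#' @export
read_interactions <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_double(),
    chromA = readr::col_character(), chromB = readr::col_character(),
    startA = readr::col_integer(), endA = readr::col_integer(),
    startB = readr::col_integer(), endB = readr::col_integer()
  ), progress = FALSE)
  need <- c("chromA", "startA", "endA", "chromB", "startB", "endB")
  if (!all(need %in% names(tab))) abort("Interaction table needs two fragment triplets.")
  score_cols <- setdiff(names(tab), c(need, "score"))
  if (!"score" %in% names(tab)) {
    if (!length(score_cols)) abort("Interaction table has no score column.")
    tab$score <- do.call(pmax, tab[score_cols])
  }
  if (any(tab$score < 0)) abort("Interaction scores must be >= 0.")
  tab
}
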