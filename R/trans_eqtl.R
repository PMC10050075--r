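#' Enumerate trans-eQTL candidates by chaining cis and trans maps
#'
#' Scenario 1 chains a CRD-QTL (variant -> CRD_A in cis) through a trans
#' CRD-CRD edge (CRD_A -> CRD_B) to a gene cis-associated with CRD_B.
#' Scenario 2 starts from an eQTL (variant -> gene g1 in cis), goes through
#' the CRD cis-associated with g1 (CRD_A), a trans edge to CRD_B, and ends
#' at a gene g2 cis-associated with CRD_B. Every link must be significant in
#' its source map; the variant and the nominated gene must sit on different
#' chromosomes. Duplicate (variant, gene) pairs are collapsed, keeping all
#' nominating chains.
#'
#' @param crd_qtls CRD-QTL table ([map_cis()], phenotype = CRD, feature =
#'   variant); only significant rows are used.
#' @param eqtls eQTL table (phenotype = gene, feature = variant; scenario 2).
#' @param crd_gene CRD-gene table (phenotype = CRD, feature = gene); used
#'   for both chain ends (the test is symmetric in p).
#' @param trans_edges Significant trans edge tibble ([trans_significant()]).
#' @param variant_info Tibble `variant_id`, `chrom`.
#' @param tss Gene TSS table (`gene_id`, `chrom`).
#' @param scenario 1 or 2.
#' @return Tibble `variant_id`, `gene_id`, `scenario`, `n_chains`, `chains`
#'   (list column of chain description strings).
#' @export
enumerate_candidates <- function(crd_qtls = NULL, eqtls = NULL, crd_gene,
                                 trans_edges, variant_info, tss,
                                 scenario = 1) {
  stopifnot(scenario %in% c(1, 2))
  sig <- function(tab) {
    tab <- tab[tab$significant & !is.na(tab$feature_id), , drop = FALSE]
    tibble(phenotype_id = tab$phenotype_id, feature_id = tab$feature_id)
  }
  cg <- sig(crd_gene)
  edges <- bind_rows(
    tibble(crd_a = trans_edges$crd_a, crd_b = trans_edges$crd_b),
    tibble(crd_a = trans_edges$crd_b, crd_b = trans_edges$crd_a)
  )
  check_ids <- function(ids, known, what) {
    orphan <- setdiff(ids, known)
    if (length(orphan)) {
      abort(paste0("Unresolvable ", what, " id(s): ",
                   paste(head(orphan, 5), collapse = ", ")))
    }
  }
  if (scenario == 1) {
    if (is.null(crd_qtls)) abort("Scenario 1 needs `crd_qtls`.")
    q <- sig(crd_qtls)
    check_ids(q$feature_id, variant_info$variant_id, "variant")
    cand <- q |>
      rename(crd_a = "phenotype_id", variant_id = "feature_id") |>
      inner_join(edges, by = "crd_a", relationship = "many-to-many") |>
      inner_join(rename(cg, crd_b = "phenotype_id", gene_id = "feature_id"),
                 by = "crd_b", relationship = "many-to-many") |>
      mutate(chain = paste(.data$variant_id, .data$crd_a, .data$crd_b,
                           .data$gene_id, sep = " -> "))
  } else {
    if (is.null(eqtls)) abort("Scenario 2 needs `eqtls`.")
    e <- sig(eqtls)
    check_ids(e$feature_id, variant_info$variant_id, "variant")
    cand <- e |>
      rename(gene1 = "phenotype_id", variant_id = "feature_id") |>
      inner_join(rename(cg, crd_a = "phenotype_id", gene1 = "feature_id"),
                 by = "gene1", relationship = "many-to-many") |>
      inner_join(edges, by = "crd_a", relationship = "many-to-many") |>
      inner_join(rename(cg, crd_b = "phenotype_id", gene_id = "feature_id"),
                 by = "crd_b", relationship = "many-to-many") |>
      filter(.data$gene_id != .data$gene1) |>
      mutate(chain = paste(.data$variant_id, .data$gene1, .data$crd_a,
                           .data$crd_b, .data$gene_id, sep = " -> "))
  }
  if (!nrow(cand)) {
    return(tibble(variant_id = character(), gene_id = character(),
                  scenario = integer(), n_chains = integer(), chains = list()))
  }
  check_ids(cand$gene_id, tss$gene_id, "gene")
  vchrom <- setNames(variant_info$chrom, variant_info$variant_id)
  gchrom <- setNames(tss$chrom, tss$gene_id)
  cand <- cand[vchrom[cand$variant_id] != gchrom[cand$gene_id], , drop = FALSE]
  cand |>
    group_by(.data$variant_id, .data$gene_id) |>
    summarise(n_chains = n(), chains = list(unique(.data$chain)),
              .groups = "drop") |>
    mutate(scenario = as.integer(scenario)) |>
    select("variant_id", "gene_id", "scenario", "n_chains", "chains")
}

#' Test nominated trans variant-gene pairs directly
#'
#' Linear regression of expression on dosage per candidate pair, q-values
#' over all tested candidates (BH by default), significance at the FDR level.
#' Candidates never extend beyond the nominated set — the chain enumeration
#' is what shrinks the trans search space.
#'
#' @param candidates Output of [enumerate_candidates()].
#' @param genotypes A [geno_matrix].
#' @param expression Gene expression [quant_matrix] (same sample order).
#' @param fdr FDR level (default 0.05).
#' @param method Q-value method. Default Benjamini-Hochberg: nominated
#'   candidate families are small (tens of pairs), where the Storey smoother
#'   pi0 estimate is unstable and anticonservative; `"storey"` is available
#'   for large candidate sets.
#' @return `candidates` with `slope`, `p`, `q_value`, `significant` added;
#'   zero-variance dosages are dropped with a message.
#' @export
test_candidates <- function(candidates, genotypes, expression, fdr = 0.05,
                            method = c("bh", "storey")) {
  method <- match.arg(method)
  if (!nrow(candidates)) {
    return(mutate(candidates, slope = numeric(0), p = numeric(0),
                  q_value = numeric(0), significant = logical(0)))
  }
  stopifnot(identical(genotypes$sample_id, expression$sample_id))
  gid <- expression$phenotypes$phenotype_id
  stats <- pmap(list(candidates$variant_id, candidates$gene_id), function(v, g) {
    dos <- genotypes$dosages[v, ]
    if (sd(dos) == 0) return(tibble(slope = NA_real_, p = NA_real_))
    y <- expression$values[match(g, gid), ]
    st <- assoc_stats(y, matrix(dos, nrow = 1))
    tibble(slope = st$slope[1], p = st$p[1])
  })
  res <- bind_cols_quiet(candidates, bind_rows(stats))
  dropped <- is.na(res$p)
  if (any(dropped)) {
    inform(paste0("Dropped ", sum(dropped), " candidate(s) with zero-variance dosage."))
    res <- res[!dropped, , drop = FALSE]
  }
  fq <- fdr_qvalue(res$p, method = method, level = fdr)
  res$q_value <- fq$q_value
  res$significant <- fq$significant
  res
}

#' Overlap trans-eQTL hits with an external variant-gene table via LD
#'
#' A hit overlaps when the external table contains the same gene paired with
#' the same variant or with any variant in LD above `r2_min`.
#'
#' @param hits Significant candidates ([test_candidates()] rows).
#' @param external Tibble `variant_id`, `gene_id`.
#' @param ld LD tibble ([ld_matrix()]).
#' @param r2_min Proxy threshold (default 0.9, strict `>`).
#' @return The overlapping subset of `hits` with a `matched_variant` column.
#' @export
overlap_external <- function(hits, external, ld, r2_min = 0.9) {
  rows <- list()
  for (i in seq_len(nrow(hits))) {
    v <- hits$variant_id[i]
    proxies <- unique(c(v,
                        ld$variant_b[ld$variant_a == v & ld$r2 > r2_min],
                        ld$variant_a[ld$variant_b == v & ld$r2 > r2_min]))
    m <- external$variant_id[external$gene_id == hits$gene_id[i] &
                               external$variant_id %in% proxies]
    if (length(m)) {
      rows[[length(rows) + 1]] <- mutate(hits[i, , drop = FALSE],
                                         matched_variant = m[1])
    }
  }
  if (!length(rows)) {
    return(mutate(hits[0, , drop = FALSE], matched_variant = character(0)))
  }
  bind_rows(rows)
}
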