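mk_tab <- function(pheno, feat, sig = TRUE) {
  tibble::tibble(phenotype_id = pheno, feature_id = feat, significant = sig)
}

toy_universe <- function() {
  list(
    variant_info = tibble::tibble(variant_id = c("v1", "v2", "v3"),
                                  chrom = c("chr1", "chr1", "chr2")),
    tss = tibble::tibble(gene_id = c("g1", "g2", "g3", "g4"),
                         chrom = c("chr2", "chr2", "chr1", "chr1"),
                         tss = c(1000L, 2000L, 3000L, 4000L), strand = "+")
  )
}

test_that("scenario-1 candidates are the three-table join", {
  u <- toy_universe()
  crd_qtls <- mk_tab("crdA", "v1")
  crd_gene <- mk_tab(c("crdB", "crdB"), c("g1", "g2"))
  edges <- tibble::tibble(crd_a = "crdA", crd_b = "crdB")
  out <- enumerate_candidates(crd_qtls = crd_qtls, crd_gene = crd_gene,
                              trans_edges = edges,
                              variant_info = u$variant_info, tss = u$tss,
                              scenario = 1)
  # 1 QTL x 1 trans edge x 2 genes on CRD_B
  expect_equal(nrow(out), 2)
  expect_setequal(out$gene_id, c("g1", "g2"))
  expect_equal(out$scenario, c(1L, 1L))

  # no trans edges: zero candidates
  out0 <- enumerate_candidates(crd_qtls = crd_qtls, crd_gene = crd_gene,
                               trans_edges = edges[0, ],
                               variant_info = u$variant_info, tss = u$tss,
                               scenario = 1)
  expect_equal(nrow(out0), 0)
})

test_that("same-chromosome variant-gene pairs are filtered out", {
  u <- toy_universe()
  crd_qtls <- mk_tab("crdA", "v1")           # v1 on chr1
  crd_gene <- mk_tab(c("crdB", "crdB"), c("g1", "g3"))  # g3 on chr1
  edges <- tibble::tibble(crd_a = "crdA", crd_b = "crdB")
  out <- enumerate_candidates(crd_qtls = crd_qtls, crd_gene = crd_gene,
                              trans_edges = edges,
                              variant_info = u$variant_info, tss = u$tss,
                              scenario = 1)
  expect_equal(out$gene_id, "g1")
})

test_that("scenario-2 chains go through the eGene's CRD", {
  u <- toy_universe()
  eqtls <- mk_tab("g3", "v1")                # v1 is an eQTL of g3 (both chr1)
  crd_gene <- mk_tab(c("crdA", "crdB"), c("g3", "g1"))
  edges <- tibble::tibble(crd_a = "crdA", crd_b = "crdB")
  out <- enumerate_candidates(eqtls = eqtls, crd_gene = crd_gene,
                              trans_edges = edges,
                              variant_info = u$variant_info, tss = u$tss,
                              scenario = 2)
  expect_equal(out$variant_id, "v1")
  expect_equal(out$gene_id, "g1")
  expect_equal(out$scenario, 2L)
})

test_that("random small tables match a brute-force join oracle", {
  set.seed(7)
  u <- list(
    variant_info = tibble::tibble(variant_id = sprintf("v%d", 1:6),
                                  chrom = rep(c("chr1", "chr2"), 3)),
    tss = tibble::tibble(gene_id = sprintf("g%d", 1:8),
                         chrom = rep(c("chr1", "chr2"), 4),
                         tss = 1:8 * 1000L, strand = "+")
  )
  crd_qtls <- mk_tab(sample(sprintf("c%d", 1:4), 6, TRUE), sprintf("v%d", 1:6))
  crd_gene <- mk_tab(sample(sprintf("c%d", 1:4), 8, TRUE), sprintf("g%d", 1:8))
  edges <- tibble::tibble(crd_a = c("c1", "c2"), crd_b = c("c3", "c4"))
  out <- enumerate_candidates(crd_qtls = crd_qtls, crd_gene = crd_gene,
                              trans_edges = edges,
                              variant_info = u$variant_info, tss = u$tss,
                              scenario = 1)
  # oracle: exhaustive triple loop over QTLs x edges (both directions) x genes
  expected <- character(0)
  vch <- setNames(u$variant_info$chrom, u$variant_info$variant_id)
  gch <- setNames(u$tss$chrom, u$tss$gene_id)
  for (i in seq_len(nrow(crd_qtls))) {
    for (e in seq_len(nrow(edges))) {
      for (dir in 1:2) {
        a <- if (dir == 1) edges$crd_a[e] else edges$crd_b[e]
        b <- if (dir == 1) edges$crd_b[e] else edges$crd_a[e]
        if (crd_qtls$phenotype_id[i] != a) next
        for (j in seq_len(nrow(crd_gene))) {
          if (crd_gene$phenotype_id[j] != b) next
          v <- crd_qtls$feature_id[i]; g <- crd_gene$feature_id[j]
          if (vch[[v]] != gch[[g]]) expected <- c(expected, paste(v, g))
        }
      }
    }
  }
  expect_setequal(paste(out$variant_id, out$gene_id), unique(expected))
})

test_that("id mismatches across tables are reported as orphans", {
  u <- toy_universe()
  crd_qtls <- mk_tab("crdA", "v_unknown")
  crd_gene <- mk_tab("crdB", "g1")
  edges <- tibble::tibble(crd_a = "crdA", crd_b = "crdB")
  expect_error(
    enumerate_candidates(crd_qtls = crd_qtls, crd_gene = crd_gene,
                         trans_edges = edges, variant_info = u$variant_info,
                         tss = u$tss, scenario = 1),
    "v_unknown"
  )
})

test_that("candidate testing regresses expression on dosage with Storey FDR", {
  set.seed(8)
  n <- 150
  g <- rbinom(n, 2, 0.4)
  expr_vals <- rbind(0.6 * as.numeric(scale(g)) + 0.8 * rnorm(n), rnorm(n))
  expr <- toy_qm(expr_vals, chrom = c("chr2", "chr2"), class = "gene")
  gm <- geno_matrix(
    tibble::tibble(variant_id = c("v1", "v2"), chrom = "chr1",
                   pos = c(100L, 200L), ref = "A", alt = "G"),
    rbind(g, rbinom(n, 2, 0.4)), expr$sample_id
  )
  cand <- tibble::tibble(variant_id = c("v1", "v2"),
                         gene_id = c("p001", "p002"),
                         scenario = 1L, n_chains = 1L,
                         chains = list("x", "y"))
  out <- test_candidates(cand, gm, expr, fdr = 0.05)
  expect_true(out$significant[out$variant_id == "v1"])
  expect_false(out$significant[out$variant_id == "v2"])
  # testing never promotes a pair absent from the candidate set
  expect_setequal(paste(out$variant_id, out$gene_id),
                  paste(cand$variant_id, cand$gene_id))
  # oracle: lm p-value for the planted pair
  p_lm <- summary(lm(expr_vals[1, ] ~ g))$coefficients[2, 4]
  expect_equal(out$p[out$variant_id == "v1"], p_lm, tolerance = 1e-10)
})

test_that("external overlap goes through identical variants or LD proxies", {
  hits <- tibble::tibble(variant_id = c("v1", "v2", "v3"),
                         gene_id = c("g1", "g2", "g3"))
  external <- tibble::tibble(variant_id = c("v1", "proxy2", "v3"),
                             gene_id = c("g1", "g2", "g9"))
  ld <- tibble::tibble(variant_a = "proxy2", variant_b = "v2", r2 = 0.95)
  out <- overlap_external(hits, external, ld)
  # v1/g1 identical; v2/g2 via proxy; v3 matches only a different gene
  expect_setequal(out$variant_id, c("v1", "v2"))
  expect_equal(out$matched_variant[out$variant_id == "v2"], "proxy2")
})
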