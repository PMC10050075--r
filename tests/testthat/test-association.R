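toy_feature_set <- function(values, pos = NULL, chrom = "chr1") {
  values <- as.matrix(values)
  if (is.null(pos)) pos <- seq(10000L, by = 10000L, length.out = nrow(values))
  feature_set(values,
              tibble::tibble(feature_id = sprintf("f%03d", seq_len(nrow(values))),
                             chrom = chrom, pos = as.integer(pos)),
              sprintf("s%02d", seq_len(ncol(values))))
}

test_that("CRD activity is the mean of member rows", {
  set.seed(1)
  qm <- toy_qm(matrix(rnorm(10 * 8), 10, 8))
  crds <- tibble::tibble(
    crd_id = c("c1", "c2"), chrom = "chr1", start = c(10000L, 20000L),
    end = c(12000L, 22000L), n_members = c(1L, 10L),
    mean_internal_abs_r = 0.5,
    members = list("p003", sprintf("p%03d", 1:10)), class = "hCRD"
  )
  act <- crd_activity(qm, crds)
  # single-member CRD: activity is that row verbatim
  expect_equal(unname(act$values["c1", ]), unname(qm$values["p003", ]))
  # brute-force mean over 10 members
  expect_equal(unname(act$values["c2", ]), unname(colMeans(qm$values)))
  # members (1, 3) average to 2
  qm2 <- toy_qm(matrix(c(1, 3), 2, 1))
  crds2 <- crds[1, ]
  crds2$members <- list(c("p001", "p002"))
  expect_equal(unname(crd_activity(qm2, crds2)$values[1, 1]), 2)
  # missing member is reported with CRD and member id
  crds3 <- crds[1, ]
  crds3$members <- list("ghost")
  expect_error(crd_activity(qm, crds3), "c1.*ghost")
})

test_that("cis scan matches closed-form OLS and excludes out-of-window features", {
  set.seed(2)
  y <- rnorm(10)
  X <- matrix(rnorm(30), 3, 10)
  fs <- toy_feature_set(X, pos = c(50000L, 60000L, 70000L))
  anchor <- list(chrom = "chr1", start = 55000L, end = 56000L)
  hit <- cis_scan(y, fs, anchor, window_bp = 1e6)
  # oracle: per-feature lm, best p
  ps <- vapply(1:3, function(i) summary(lm(y ~ X[i, ]))$coefficients[2, 4],
               numeric(1))
  slopes <- vapply(1:3, function(i) coef(lm(y ~ X[i, ]))[[2]], numeric(1))
  best <- which.min(ps)
  expect_equal(hit$nominal_p, ps[best], tolerance = 1e-12)
  expect_equal(hit$slope, slopes[best], tolerance = 1e-12)
  expect_equal(hit$feature_id, sprintf("f%03d", best))

  # a feature 1,000,001 bp beyond the boundary is excluded
  fs2 <- toy_feature_set(X, pos = c(55000L, 56000L + 1000001L, 60000L))
  hit2 <- cis_scan(y, fs2, anchor, window_bp = 1e6)
  expect_equal(hit2$n_features, 2L)

  # phenotype identical to one feature wins at extreme significance
  y3 <- X[2, ]
  hit3 <- cis_scan(y3, fs, anchor)
  expect_equal(hit3$feature_id, "f002")
  expect_lt(hit3$nominal_p, 1e-30)

  # no features in window: untested sentinel
  far <- list(chrom = "chr9", start = 1L, end = 2L)
  expect_true(is.na(cis_scan(y, fs, far)$feature_id))
})

test_that("permutation adjustment floors at 1/(n_perm+1) and warns when coarse", {
  set.seed(3)
  X <- matrix(rnorm(20 * 50), 20, 50)
  fs <- toy_feature_set(X)
  anchor <- list(chrom = "chr1", start = 1L, end = 300000L)
  y <- X[5, ] + rnorm(50, sd = 0.01)  # beats every permutation
  adj <- permutation_adjust(y, fs, anchor, n_perm = 1000, seed = 4)
  expect_equal(adj, 1 / 1001)
  expect_warning(permutation_adjust(y, fs, anchor, n_perm = 50, seed = 4),
                 "resolution")
})

test_that("q-values follow the BH step-up oracle and Storey tightens them", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  out <- fdr_qvalue(p, method = "bh", level = 0.05)
  expect_equal(out$q_value, p.adjust(p, "BH"))
  expect_true(all(out$significant))

  expect_equal(sum(fdr_qvalue(rep(1, 20), level = 0.05)$significant), 0)
  expect_equal(nrow(fdr_qvalue(numeric(0))), 0)

  set.seed(5)
  p_mix <- c(runif(7000), rbeta(3000, 0.05, 10))
  st <- fdr_qvalue(p_mix, method = "storey", level = 0.05)
  bh <- fdr_qvalue(p_mix, method = "bh", level = 0.05)
  pi0 <- attr(st, "pi0")
  expect_gt(pi0, 0.65)
  expect_lt(pi0, 0.75)
  expect_true(all(st$q_value <= bh$q_value + 1e-12))
})

test_that("map_cis finds a planted QTL and is seed-reproducible", {
  set.seed(6)
  n <- 100
  g <- matrix(rbinom(20 * n, 2, 0.4), 20, n)
  fs <- toy_feature_set(g)
  # 10 phenotypes, the 4th driven by feature 7 (~25% variance)
  vals <- matrix(rnorm(10 * n), 10, n)
  vals[4, ] <- sqrt(0.25) * as.numeric(scale(g[7, ])) + sqrt(0.75) * rnorm(n)
  qm <- toy_qm(vals, spacing = 10000L, width = 500L)
  res <- map_cis(qm, fs, window_bp = 1e6, n_perm = 200, fdr = 0.05, seed = 7)
  expect_true(res$significant[res$phenotype_id == "p004"])
  expect_equal(res$feature_id[res$phenotype_id == "p004"], "f007")
  res2 <- map_cis(qm, fs, window_bp = 1e6, n_perm = 200, fdr = 0.05, seed = 7)
  expect_identical(res, res2)
})

test_that("conditional scan recovers two independent planted signals", {
  set.seed(8)
  n <- 200
  g <- matrix(rbinom(30 * n, 2, 0.4), 30, n)
  fs <- toy_feature_set(g)
  y <- sqrt(0.25) * as.numeric(scale(g[5, ])) +
    sqrt(0.25) * as.numeric(scale(g[20, ])) + sqrt(0.5) * rnorm(n)
  anchor <- list(chrom = "chr1", start = 1L, end = 400000L)
  out <- conditional_scan(y, fs, anchor, threshold = 0.01, n_perm = 200, seed = 9)
  expect_setequal(out$feature_id, c("f005", "f020"))
  expect_equal(out$rank, 0:1)

  # a pure-null phenotype yields an empty record set
  out0 <- conditional_scan(rnorm(n), fs, anchor, threshold = 0.01,
                           n_perm = 200, seed = 10)
  expect_equal(nrow(out0), 0)
})

test_that("map_cis conditional pass appends rank >= 1 signals", {
  set.seed(12)
  n <- 200
  g <- matrix(rbinom(20 * n, 2, 0.4), 20, n)
  fs <- toy_feature_set(g)
  vals <- matrix(rnorm(4 * n), 4, n)
  vals[2, ] <- sqrt(0.25) * as.numeric(scale(g[3, ])) +
    sqrt(0.25) * as.numeric(scale(g[15, ])) + sqrt(0.5) * rnorm(n)
  qm <- toy_qm(vals, spacing = 40000L)
  res <- map_cis(qm, fs, n_perm = 200, fdr = 0.05, conditional = TRUE, seed = 13)
  sig2 <- res[res$phenotype_id == "p002", ]
  expect_gte(nrow(sig2), 2)
  expect_setequal(sig2$feature_id[sig2$rank <= 1], c("f003", "f015"))
})

test_that("co-expression pairs respect the distance cap and flag duplicates", {
  set.seed(14)
  n <- 60
  vals <- matrix(rnorm(4 * n), 4, n)
  vals[2, ] <- vals[1, ]  # duplicated expression profile
  qm <- toy_qm(vals, class = "gene", spacing = 400000L, width = 2000L)
  tss <- tibble::tibble(gene_id = qm$phenotypes$phenotype_id,
                        chrom = "chr1", tss = qm$phenotypes$start + 1L,
                        strand = "+")
  pairs <- coexpression_pairs(qm, tss, max_distance_bp = 1e6, fdr = 0.01)
  # genes 1-2 at 400 kb, 1-3 at 800 kb, 2-3 at 400 kb ... 1-4 at 1.2 Mb excluded
  expect_false(any(pairs$gene_a == "p001" & pairs$gene_b == "p004"))
  dup <- pairs[pairs$gene_a == "p001" & pairs$gene_b == "p002", ]
  expect_equal(dup$r, 1)
  expect_true(dup$significant)
})

test_that("same-CRD enrichment matches exhaustive enumeration on a toy set", {
  # 6 genes, 2 CRDs; genes 1-3 on crdA, genes 4-5 on crdB, gene 6 unlinked
  crd_gene <- tibble::tibble(
    phenotype_id = c("crdA", "crdA", "crdA", "crdB", "crdB"),
    feature_id = c("g1", "g2", "g3", "g4", "g5"),
    significant = TRUE
  )
  pairs <- tibble::tibble(
    gene_a = c("g1", "g1", "g2", "g4", "g1", "g3"),
    gene_b = c("g2", "g3", "g3", "g5", "g4", "g6"),
    distance = c(50000, 150000, 50000, 150000, 250000, 250000),
    r = 0.5, p = 0.001,
    significant = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE)
  )
  bins <- c(0, 1e5, 2e5, 1e6)
  out <- same_crd_enrichment(pairs, crd_gene, bins)
  # bin 1: co-expressed pairs {g1-g2 (same crdA)} -> fraction 1
  expect_equal(out$fraction_same_crd[1], 1)
  # bin 2: {g1-g3 same, g4-g5 same} -> 1
  expect_equal(out$fraction_same_crd[2], 1)
  # bin 3: {g1-g4 different, g3-g6 no crd} -> 0
  expect_equal(out$fraction_same_crd[3], 0)
  expect_equal(out$n_coexpressed, c(1L, 2L, 2L))
  # empty bins are NA
  out2 <- same_crd_enrichment(pairs[0, ], crd_gene, bins)
  expect_true(all(is.na(out2$fraction_same_crd)))
})
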