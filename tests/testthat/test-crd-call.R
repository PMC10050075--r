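test_that("correlation map equals the direct Pearson formula within window", {
  set.seed(8)
  vals <- matrix(rnorm(20), 5, 4)
  qm <- toy_qm(vals)
  cm <- correlation_map(qm, window = 250)
  m <- cm$chrom_maps$chr1$r
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(m[i, j], cor(vals[i, ], vals[j, ]))
  }
  # a duplicated peak row correlates at exactly 1
  vals2 <- rbind(vals, vals[1, ])
  cm2 <- correlation_map(toy_qm(vals2), window = 250)
  expect_equal(cm2$chrom_maps$chr1$r[1, 6], 1)
})

test_that("pairs beyond the index window are untested", {
  set.seed(9)
  qm <- toy_qm(matrix(rnorm(6 * 10), 6, 10))
  cm <- correlation_map(qm, window = 3)
  m <- cm$chrom_maps$chr1$r
  expect_true(is.na(m[1, 5]))   # index distance 4 > 3
  expect_false(is.na(m[1, 4]))  # distance 3 tested
  expect_error(correlation_map(qm, window = 0), "window")
})

test_that("tree building merges correlated pairs first", {
  # r(1,2) = r(3,4) ~ 0.9, cross ~ 0: (1,2) and (3,4) merge before the root
  set.seed(10)
  n <- 200
  f1 <- rnorm(n); f2 <- rnorm(n)
  vals <- rbind(sqrt(0.9) * f1 + sqrt(0.1) * rnorm(n),
                sqrt(0.9) * f1 + sqrt(0.1) * rnorm(n),
                sqrt(0.9) * f2 + sqrt(0.1) * rnorm(n),
                sqrt(0.9) * f2 + sqrt(0.1) * rnorm(n))
  cm <- correlation_map(toy_qm(vals), window = 250)
  tr <- build_tree(cm)$trees$chr1
  expect_equal(nrow(tr$merge), 3)  # n - 1 internal nodes
  first_two <- lapply(1:2, function(k) sort(as.integer(-tr$merge[k, ])))
  expect_true(
    (identical(first_two[[1]], 1:2) && identical(first_two[[2]], 3:4)) ||
      (identical(first_two[[1]], 3:4) && identical(first_two[[2]], 1:2))
  )

  # 2 peaks: a single root joining both leaves
  cm2 <- correlation_map(toy_qm(vals[1:2, ]), window = 10)
  tr2 <- build_tree(cm2)$trees$chr1
  expect_equal(nrow(tr2$merge), 1)

  # single-peak chromosome yields no tree, with a warning
  cm1 <- correlation_map(toy_qm(matrix(rnorm(10), 1, 10)), window = 5)
  expect_warning(t1 <- build_tree(cm1), "single phenotype")
  expect_length(t1$trees, 0)
})

planted_two_block_qm <- function(n = 400, m_block = 10, r = 0.8, n_bg = 20,
                                 seed = 1) {
  set.seed(seed)
  f1 <- rnorm(n); f2 <- rnorm(n)
  rows <- list()
  block1 <- sapply(1:m_block, function(i) sqrt(r) * f1 + sqrt(1 - r) * rnorm(n))
  bg1 <- matrix(rnorm(n * (n_bg / 2)), ncol = n_bg / 2)
  block2 <- sapply(1:m_block, function(i) sqrt(r) * f2 + sqrt(1 - r) * rnorm(n))
  bg2 <- matrix(rnorm(n * (n_bg / 2)), ncol = n_bg / 2)
  vals <- t(cbind(bg1[, 1:5], block1, bg1[, -(1:5)], block2, bg2))
  list(qm = toy_qm(vals),
       block_ids = list(sprintf("p%03d", 6:(5 + m_block)),
                        sprintf("p%03d", (11 + m_block):(10 + 2 * m_block))))
}

test_that("two planted blocks are called exactly, matching the exhaustive oracle", {
  fx <- planted_two_block_qm(seed = 3)
  cm <- correlation_map(fx$qm, window = 250)
  tree <- build_tree(cm)
  crds <- call_crds(tree, cm)
  expect_equal(nrow(crds), 2)
  expect_setequal(lapply(crds$members, sort), fx$block_ids)
  oracle <- exhaustive_crds(tree, cm)
  expect_setequal(lapply(crds$members, sort), oracle)
})

test_that("independent peaks yield no CRDs", {
  set.seed(14)
  qm <- toy_qm(matrix(rnorm(40 * 300), 40, 300))
  cm <- correlation_map(qm, window = 250)
  crds <- call_crds(build_tree(cm), cm)
  expect_equal(nrow(crds), 0)
})

test_that("a node of fully-overlapping member intervals is rejected", {
  # two perfectly correlated probes at the same location + background;
  # the correlated pair fails the two-non-overlapping-regions criterion
  set.seed(15)
  n <- 300
  f <- rnorm(n)
  vals <- rbind(f, f + rnorm(n, sd = 0.01), matrix(rnorm(10 * n), 10, n))
  starts <- c(50000L, 50000L, seq(100000L, 118000L, by = 2000L))
  qm <- toy_qm(vals, start = starts, width = 600L)
  cm <- correlation_map(qm, window = 250)
  crds <- call_crds(build_tree(cm), cm)
  expect_false(any(vapply(crds$members, function(m)
    all(c("p001", "p002") %in% m) && length(m) == 2, logical(1))))
})

test_that("raising the criteria factor never increases the CRD count", {
  cfg <- simulation_config(n_samples = 250, n_blocks = 8, n_chrom = 2,
                           block_r = 0.5, seed = 33)
  sim <- simulate_population(cfg)
  pk <- rank_normal(residualize(sim$peaks))
  cm <- correlation_map(pk, window = 250)
  tree <- build_tree(cm)
  counts <- vapply(c(1, 2, 4, 8), function(f)
    nrow(call_crds(tree, cm, factor = f)), numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_error(call_crds(tree, cm, factor = 0), "factor")
})

test_that("called CRDs are membership-disjoint within a chromosome", {
  cfg <- simulation_config(n_samples = 300, n_blocks = 10, n_chrom = 2, seed = 41)
  sim <- simulate_population(cfg)
  pk <- rank_normal(residualize(sim$peaks))
  cm <- correlation_map(pk, window = 250)
  crds <- call_crds(build_tree(cm), cm)
  all_members <- unlist(crds$members)
  expect_equal(anyDuplicated(all_members), 0)
  expect_true(all(all_members %in% pk$phenotypes$phenotype_id))
})

test_that("size mixture EM recovers known parameters and threshold", {
  set.seed(20)
  n <- 2000
  comp <- runif(n) < 0.5
  lengths <- 10^ifelse(comp, rnorm(n, 2.48, 0.25), rnorm(n, 4.60, 0.25))
  fit <- fit_size_mixture(lengths)
  expect_true(fit$converged)
  expect_equal(fit$mu_small, 2.48, tolerance = 0.1 / 2.48)
  expect_equal(fit$mu_large, 4.60, tolerance = 0.1 / 4.60)
  analytic <- 10^(2.48 + 1.6449 * 0.25)
  expect_lt(abs(fit$size_threshold_bp - analytic) / analytic, 0.2)
  # independent cross-check against mclust's EM on the same draws
  # (mclust must be attached: Mclust resolves mclustBIC in the search path)
  withr::local_package("mclust")
  mc <- Mclust(log10(lengths), G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(c(fit$mu_small, fit$mu_large)),
               sort(unname(mc$parameters$mean)), tolerance = 0.05)
  # tidy/glance accessors
  td <- tidy(fit)
  expect_equal(td$component, c("small", "large"))
  expect_true(glance(fit)$converged)
})

test_that("degenerate lengths trigger the single-component fallback", {
  expect_warning(fit <- fit_size_mixture(rep(500, 50)), "fallback")
  expect_false(fit$converged)
  expect_error(fit_size_mixture(rep(500, 10)), ">= 20")
})

test_that("size filtering keeps spans strictly above the threshold", {
  set.seed(21)
  lengths <- 10^c(rnorm(500, 2.48, 0.25), rnorm(500, 4.6, 0.25))
  fit <- fit_size_mixture(lengths)
  crds <- random_crds(50, seed = 2)
  crds$class <- "mCRD"
  kept <- size_filter_mcrds(crds, fit)
  manual <- crds[(crds$end - crds$start) > fit$size_threshold_bp, ]
  expect_equal(kept, manual)
  # boundary: span exactly at the threshold is removed
  thr <- as.integer(round(fit$size_threshold_bp))
  fit2 <- fit
  fit2$size_threshold_bp <- thr
  crds$end[1] <- crds$start[1] + thr
  expect_false(crds$crd_id[1] %in% size_filter_mcrds(crds, fit2)$crd_id)
  # unconverged fit without a fallback threshold is an error
  fit$converged <- FALSE
  expect_error(size_filter_mcrds(crds, fit), "fallback")
  expect_equal(nrow(size_filter_mcrds(crds, fit, fallback_threshold_bp = 0)),
               nrow(crds))
})
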