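test_that("PCHi-C support fractions match a brute-force overlap check", {
  # 10 pairs in one bin; interactions support exactly 3 of them
  pairs <- tibble::tibble(
    chrom = "chr1",
    start_a = seq(0L, by = 1000000L, length.out = 10), end_a = start_a + 5000L,
    start_b = start_a + 105000L, end_b = start_a + 110000L
  )
  interactions <- tibble::tibble(
    chromA = "chr1", startA = pairs$start_a[1:4], endA = pairs$end_a[1:4],
    chromB = "chr1", startB = pairs$start_b[1:4], endB = pairs$end_b[1:4],
    score = c(9, 7, 6, 2)  # the 4th is below the cutoff
  )
  out <- pchic_support(pairs, interactions, bins = c(2e4, 2e5))
  expect_equal(out$n_pairs, 10L)
  expect_equal(out$n_supported, 3L)
  expect_equal(out$fraction, 0.3)

  # either fragment orientation counts
  flipped <- interactions[1, ]
  names(flipped) <- c("chromB", "startB", "endB", "chromA", "startA", "endA", "score")
  out2 <- pchic_support(pairs[1, ], flipped[, names(interactions)],
                        bins = c(2e4, 2e5))
  expect_equal(out2$n_supported, 1L)
})

test_that("pairs closer than the distance floor are excluded", {
  pairs <- tibble::tibble(chrom = "chr1", start_a = 0L, end_a = 1000L,
                          start_b = 16000L, end_b = 17000L)  # 15 kb gap
  out <- pchic_support(pairs, tibble::tibble(
    chromA = character(), startA = integer(), endA = integer(),
    chromB = character(), startB = integer(), endB = integer(),
    score = numeric()
  ), bins = c(2e4, 1e6))
  expect_equal(sum(out$n_pairs), 0L)
})

test_that("support with aggregate = any is monotone non-increasing in score_min", {
  set.seed(1)
  pairs <- tibble::tibble(
    chrom = "chr1",
    start_a = seq(0L, by = 500000L, length.out = 20), end_a = start_a + 2000L,
    start_b = start_a + 50000L, end_b = start_a + 52000L
  )
  interactions <- tibble::tibble(
    chromA = "chr1", startA = pairs$start_a, endA = pairs$end_a,
    chromB = "chr1", startB = pairs$start_b, endB = pairs$end_b,
    score = runif(20, 0, 12)
  )
  fr <- vapply(c(1, 3, 5, 8), function(s) {
    sum(pchic_support(pairs, interactions, score_min = s,
                      bins = c(2e4, 1e6))$n_supported)
  }, numeric(1))
  expect_true(all(diff(fr) <= 0))
})

test_that("mean-score aggregation differs from any-score when scores straddle 5", {
  pairs <- tibble::tibble(chrom = "chr1", start_a = 0L, end_a = 1000L,
                          start_b = 100000L, end_b = 101000L)
  interactions <- tibble::tibble(
    chromA = "chr1", startA = c(0L, 0L), endA = c(1000L, 1000L),
    chromB = "chr1", startB = c(100000L, 100000L), endB = c(101000L, 101000L),
    score = c(8, 1)  # any: supported; mean = 4.5: not
  )
  any_out <- pchic_support(pairs, interactions, bins = c(2e4, 1e6),
                           aggregate = "any")
  mean_out <- pchic_support(pairs, interactions, bins = c(2e4, 1e6),
                            aggregate = "mean")
  expect_equal(any_out$n_supported, 1L)
  expect_equal(mean_out$n_supported, 0L)
})

test_that("TFBS enrichment matches the exact hypergeometric oracle", {
  # 2x2 table (10, 90, 5, 195): OR = (10*195)/(90*5) = 4.333...
  set.seed(2)
  sig <- tibble::tibble(variant_id = sprintf("s%03d", 1:100), chrom = "chr1",
                        pos = as.integer(1:100 * 1000))
  bg <- tibble::tibble(variant_id = sprintf("b%03d", 1:200), chrom = "chr1",
                       pos = as.integer(200000L + 1:200 * 1000))
  # TFBS covering the first 10 significant and first 5 background variants
  tf1 <- dplyr::bind_rows(
    tibble::tibble(chrom = "chr1", start = 1:10 * 1000 - 1L, end = 1:10 * 1000),
    tibble::tibble(chrom = "chr1", start = 200000L + 1:5 * 1000 - 1L,
                   end = 200000L + 1:5 * 1000)
  )
  peaks <- tibble::tibble(chrom = "chr1", start = 500L, end = 20000L)
  out <- tfbs_enrichment(sig, dplyr::bind_rows(sig, bg),
                         tfbs_sets = list(TF1 = tf1), peaks_in_crds = peaks,
                         top_k = 50)
  expect_equal(out$qtl_in, 10L)
  expect_equal(out$bg_in, 5L)
  expect_equal(out$odds_ratio, (10 * 195) / (90 * 5))
  # exact conditional p by hypergeometric enumeration
  m <- 15; nn <- 285; k <- 100
  probs <- dhyper(0:15, m, nn, k)
  p_oracle <- sum(probs[probs <= dhyper(10, m, nn, k) * (1 + 1e-7)])
  expect_equal(out$p, p_oracle, tolerance = 1e-8)
})

test_that("zero-overlap significant sets get a finite Haldane-corrected OR", {
  sig <- tibble::tibble(variant_id = "s1", chrom = "chr1", pos = 1000L)
  bg <- tibble::tibble(variant_id = sprintf("b%d", 1:20), chrom = "chr1",
                       pos = as.integer(1:20 * 1000 + 50000L))
  tf <- tibble::tibble(chrom = "chr1", start = 50999L, end = 56000L)
  out <- tfbs_enrichment(sig, dplyr::bind_rows(sig, bg), list(TF = tf),
                         peaks_in_crds = tibble::tibble(chrom = "chr1",
                                                        start = 50000L,
                                                        end = 60000L))
  expect_true(is.finite(out$odds_ratio))
  expect_lt(out$odds_ratio, 1)
})

test_that("LD r2 comes from dosage correlation within the 500 kb window", {
  set.seed(3)
  dos <- matrix(rbinom(4 * 1000, 2, 0.3), 4, 1000)
  dos[2, ] <- dos[1, ]  # duplicated variant
  gm <- geno_matrix(
    tibble::tibble(variant_id = c("v1", "v2", "v3", "v4"), chrom = "chr1",
                   pos = c(1000L, 2000L, 400000L, 502001L), ref = "A", alt = "G"),
    dos, sprintf("s%d", 1:1000)
  )
  ld <- ld_matrix(gm)
  expect_equal(ld$r2[ld$variant_a == "v1" & ld$variant_b == "v2"], 1)
  # pair 501 kb apart is absent
  expect_false(any(ld$variant_a == "v1" & ld$variant_b == "v4"))
  # independent variants: near-zero mean r2
  indep <- ld$r2[!(ld$variant_a == "v1" & ld$variant_b == "v2")]
  expect_lt(mean(indep), 0.01)
})

test_that("GWAS overlap finds hits directly and through LD proxies", {
  gwas <- tibble::tibble(variant_id = c("q1", "x1", "x2"),
                         p = c(1e-6, 1e-8, 0.5))
  ld <- tibble::tibble(variant_a = c("q2", "x2"), variant_b = c("x1", "q3"),
                       r2 = c(0.95, 0.95))
  # q1 overlaps via itself; q2 via proxy x1 (either LD orientation works)
  out <- gwas_overlap(c("q1", "q2", "q3"), gwas, ld)
  expect_setequal(out$qtl, c("q1", "q2"))
  expect_equal(out$proxy[out$qtl == "q2"], "x1")
  # row order invariance
  out2 <- gwas_overlap(c("q1", "q2", "q3"), gwas[3:1, ], ld[2:1, ])
  expect_equal(dplyr::arrange(out, qtl), dplyr::arrange(out2, qtl))
  # nothing below the threshold: empty result
  out3 <- gwas_overlap("q1", tibble::tibble(variant_id = "q1", p = 0.01), ld)
  expect_equal(nrow(out3), 0)
})

test_that("inflation lambda is exactly 1 at p = 0.5 and calibrated on uniforms", {
  expect_equal(as.numeric(inflation_lambda(rep(0.5, 100))), 1)
  set.seed(4)
  expect_equal(as.numeric(inflation_lambda(runif(10000))), 1, tolerance = 0.05)
  # left-shifted p-values: lambda equals the direct median-ratio computation
  p <- c(runif(5000), runif(1000) * 1e-3)
  direct <- median(qchisq(1 - p, df = 1)) / qchisq(0.5, df = 1)
  expect_equal(as.numeric(inflation_lambda(p)), direct, tolerance = 1e-9)
  expect_gt(direct, 1)
  expect_error(inflation_lambda(numeric(0)), "Empty")
})
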