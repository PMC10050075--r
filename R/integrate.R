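# half-open interval overlap predicate, vectorized over the first triple
overlaps <- function(chrom1, s1, e1, chrom2, s2, e2) {
  chrom1 == chrom2 & s1 < e2 & s2 < e1
}

#' PCHi-C support of interval-pair associations by distance
#'
#' A pair of intervals is supported when an interaction whose fragments
#' overlap both intervals (in either orientation) has score at least
#' `score_min` (`aggregate = "any"`), or when the mean score over all
#' matching interactions reaches `score_min` (`aggregate = "mean"`, the
#' convention used for co-expressed gene pairs). Pairs separated by less
#' than `min_distance_bp` are excluded because genomic-distance noise
#' dominates short-range capture signal.
#'
#' @param pairs Tibble with columns `chrom`, `start_a`, `end_a`, `start_b`,
#'   `end_b` (0-based half-open, same chromosome per pair).
#' @param interactions Interaction tibble ([read_interactions()] or
#'   [simulate_interactions()]).
#' @param score_min Significance score cutoff (default 5, the CHiCAGO
#'   convention).
#' @param min_distance_bp Minimum pair separation (default 20 kb).
#' @param bins Distance bin edges in bp (sorted).
#' @param aggregate `"any"` or `"mean"`.
#' @return Tibble per bin: `bin_lo`, `bin_hi`, `n_pairs`, `n_supported`,
#'   `fraction`; the per-pair support flags are attached as attribute
#'   `"per_pair"`.
#' @export
pchic_support <- function(pairs, interactions, score_min = 5,
                          min_distance_bp = 20000,
                          bins = c(2e4, 5e4, 1e5, 2e5, 5e5, 1e6),
                          aggregate = c("any", "mean")) {
  aggregate <- match.arg(aggregate)
  if (is.unsorted(bins, strictly = TRUE)) abort("bins must be strictly increasing.")
  # pair separation: gap between the two intervals (0 if touching/overlapping)
  dist <- pmax(pmax(pairs$start_b - pairs$end_a, pairs$start_a - pairs$end_b), 0)
  keep <- dist >= min_distance_bp
  pairs <- pairs[keep, , drop = FALSE]
  dist <- dist[keep]
  supported <- map_lgl(seq_len(nrow(pairs)), function(i) {
    fwd <- overlaps(pairs$chrom[i], pairs$start_a[i], pairs$end_a[i],
                    interactions$chromA, interactions$startA, interactions$endA) &
      overlaps(pairs$chrom[i], pairs$start_b[i], pairs$end_b[i],
               interactions$chromB, interactions$startB, interactions$endB)
    rev <- overlaps(pairs$chrom[i], pairs$start_a[i], pairs$end_a[i],
                    interactions$chromB, interactions$startB, interactions$endB) &
      overlaps(pairs$chrom[i], pairs$start_b[i], pairs$end_b[i],
               interactions$chromA, interactions$startA, interactions$endA)
    sc <- interactions$score[fwd | rev]
    if (!length(sc)) return(FALSE)
    if (aggregate == "any") any(sc >= score_min) else mean(sc) >= score_min
  })
  out <- list()
  for (k in seq_len(length(bins) - 1)) {
    in_bin <- dist >= bins[k] & dist < bins[k + 1]
    n <- sum(in_bin)
    s <- sum(supported[in_bin])
    out[[k]] <- tibble(bin_lo = bins[k], bin_hi = bins[k + 1], n_pairs = n,
                       n_supported = s,
                       fraction = if (n > 0) s / n else NA_real_)
  }
  res <- bind_rows(out)
  attr(res, "per_pair") <- mutate(pairs, distance = dist, supported = supported)
  res
}

#' TFBS enrichment of significant QTLs (Fisher's exact test)
#'
#' Ranks TFBS interval sets by how many CRD peaks they overlap, keeps the
#' `top_k` most represented, and for each builds the 2x2 table of
#' (significant QTL vs background QTL) x (variant in TFBS vs not), with
#' Fisher's exact p, odds ratio (Haldane 0.5 correction on zero cells) and
#' q-values at the given FDR.
#'
#' @param significant_qtls,background_universe Tibbles with `variant_id`,
#'   `chrom`, `pos` (background = all tested lead QTL candidates; the
#'   significant set is removed from it internally).
#' @param tfbs_sets Named list of interval tibbles (`chrom`, `start`, `end`,
#'   0-based half-open).
#' @param peaks_in_crds Interval tibble of CRD member peaks (used for the
#'   top-k ranking).
#' @param top_k Number of most-overlapping TFBS sets to test (default 50).
#' @param fdr FDR level for the q-value flags (default 0.01).
#' @return Tibble per TFBS: counts, `odds_ratio`, `p`, `q_value`,
#'   `significant`, `n_peak_overlaps`.
#' @export
tfbs_enrichment <- function(significant_qtls, background_universe, tfbs_sets,
                            peaks_in_crds, top_k = 50, fdr = 0.01) {
  in_set <- function(chrom, pos, set) {
    # variant positions are 1-based; sets are 0-based half-open
    map_lgl(seq_along(pos), function(i) {
      any(set$chrom == chrom[i] & set$start < pos[i] & pos[i] <= set$end)
    })
  }
  n_overlap <- map_int(tfbs_sets, function(set) {
    sum(map_lgl(seq_len(nrow(peaks_in_crds)), function(i) {
      any(overlaps(peaks_in_crds$chrom[i], peaks_in_crds$start[i],
                   peaks_in_crds$end[i], set$chrom, set$start, set$end))
    }))
  })
  empty <- map_int(tfbs_sets, nrow) == 0
  if (any(empty)) {
    warn(paste0("Skipping empty TFBS set(s): ",
                paste(names(tfbs_sets)[empty], collapse = ", ")))
  }
  keep <- names(sort(n_overlap[!empty], decreasing = TRUE))
  keep <- head(keep, top_k)
  bg <- anti_join(background_universe, significant_qtls, by = "variant_id")
  rows <- map(keep, function(nm) {
    set <- tfbs_sets[[nm]]
    sig_in <- in_set(significant_qtls$chrom, significant_qtls$pos, set)
    bg_in <- in_set(bg$chrom, bg$pos, set)
    a <- sum(sig_in); b <- sum(!sig_in); c_ <- sum(bg_in); d <- sum(!bg_in)
    ft <- fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE))
    or <- if (any(c(a, b, c_, d) == 0)) {
      ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
    } else (a * d) / (b * c_)
    tibble(tfbs = nm, n_peak_overlaps = n_overlap[[nm]],
           qtl_in = a, qtl_out = b, bg_in = c_, bg_out = d,
           odds_ratio = or, p = ft$p.value)
  })
  res <- bind_rows(rows)
  if (nrow(res)) {
    fq <- fdr_qvalue(res$p, method = "bh", level = fdr)
    res$q_value <- fq$q_value
    res$significant <- fq$significant
  }
  res
}

#' Local LD matrix from dosages
#'
#' Squared Pearson correlation of dosage vectors for every same-chromosome
#' variant pair within `window_bp` (default 500 kb). Zero-variance variants
#' are skipped.
#'
#' @param genotypes A [geno_matrix] (>= 2 variants).
#' @param window_bp Maximum pair distance in bp (default 500 kb).
#' @return Tibble `variant_a`, `variant_b`, `r2`.
#' @export
ld_matrix <- function(genotypes, window_bp = 5e5) {
  v <- genotypes$variants
  if (nrow(v) < 2) abort("Need >= 2 variants for LD.")
  sds <- apply(genotypes$dosages, 1, sd)
  if (any(sds == 0)) {
    inform(paste0("Skipping ", sum(sds == 0), " zero-variance variant(s) in LD."))
  }
  rows <- list()
  for (ch in unique(v$chrom)) {
    idx <- which(v$chrom == ch & sds > 0)
    if (length(idx) < 2) next
    cm <- cor(t(genotypes$dosages[idx, , drop = FALSE]))
    ij <- which(upper.tri(cm), arr.ind = TRUE)
    keep <- abs(v$pos[idx[ij[, 2]]] - v$pos[idx[ij[, 1]]]) <= window_bp
    if (!any(keep)) next
    rows[[ch]] <- tibble(
      variant_a = v$variant_id[idx[ij[keep, 1]]],
      variant_b = v$variant_id[idx[ij[keep, 2]]],
      r2 = cm[ij[keep, , drop = FALSE]]^2
    )
  }
  out <- bind_rows(rows)
  if (!nrow(out)) tibble(variant_a = character(), variant_b = character(),
                         r2 = numeric()) else out
}

#' Overlap of lead QTLs with GWAS signals through LD proxies
#'
#' A QTL overlaps a GWAS signal if the variant itself, or any variant in LD
#' with it above `r2_min`, has a GWAS p-value below `gwas_p_max`. Invariant
#' to GWAS row order and LD pair orientation.
#'
#' @param lead_qtls Character vector of lead QTL variant ids.
#' @param gwas Tibble `variant_id`, `p`.
#' @param ld LD tibble from [ld_matrix()].
#' @param r2_min LD proxy threshold (default 0.9, strict `>`).
#' @param gwas_p_max GWAS significance threshold (default 1e-5, strict `<`).
#' @return Tibble `qtl`, `proxy`, `gwas_p` (one row per qualifying proxy,
#'   the QTL itself included as its own proxy; empty when nothing overlaps).
#' @export
gwas_overlap <- function(lead_qtls, gwas, ld, r2_min = 0.9, gwas_p_max = 1e-5) {
  gp <- setNames(gwas$p, gwas$variant_id)
  rows <- list()
  for (q in lead_qtls) {
    proxies <- unique(c(q,
                        ld$variant_b[ld$variant_a == q & ld$r2 > r2_min],
                        ld$variant_a[ld$variant_b == q & ld$r2 > r2_min]))
    hit <- proxies[!is.na(gp[proxies]) & gp[proxies] < gwas_p_max]
    if (length(hit)) {
      rows[[length(rows) + 1]] <- tibble(qtl = q, proxy = hit,
                                         gwas_p = unname(gp[hit]))
    }
  }
  if (!length(rows)) return(tibble(qtl = character(), proxy = character(),
                                   gwas_p = numeric()))
  bind_rows(rows)
}

#' Genomic inflation factor lambda
#'
#' `lambda = median(qchisq(1 - p, df = 1)) / qchisq(0.5, df = 1)`, the
#' median association chi-square over its null expectation (~0.4549).
#' QQ-plot coordinates (-log10 expected vs observed) are attached as
#' attribute `"qq"`.
#'
#' @param p P-values in `(0, 1]`.
#' @return Scalar lambda.
#' @export
inflation_lambda <- function(p) {
  if (!length(p)) abort("Empty p-value vector.")
  stopifnot(all(p > 0 & p <= 1))
  lambda <- median(qchisq(p, df = 1, lower.tail = FALSE)) / qchisq(0.5, df = 1)
  n <- length(p)
  qq <- tibble(expected = -log10((seq_len(n) - 0.5) / n),
               observed = -log10(sort(p)))
  attr(lambda, "qq") <- qq
  lambda
}
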