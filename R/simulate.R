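#' Simulation configuration for population multi-omics with planted structure
#'
#' Builds the configuration consumed by [simulate_population()]. The defaults
#' encode the synthetic study conditions used throughout the package's tests:
#' 20 planted peak blocks of 8-20 peaks with within-block correlation 0.7 on
#' a zero-correlation background, 500 individuals, a cis-QTL per block
#' explaining 20% of block-activity variance, one cis gene per block
#' (25% of expression variance driven by the block), a handful of
#' inter-chromosomal block couplings, and methylation domain sizes drawn from
#' a two-component log10-normal mixture peaking near 300 bp and 40 kb.
#'
#' @param n_samples Number of individuals.
#' @param n_chrom Number of synthetic chromosomes (named `chr1`, `chr2`, ...).
#' @param block_spec Tibble with columns `block_id`, `chrom`, `n_peaks`, `r`
#'   (within-block correlation target), or `NULL` to generate one from
#'   `n_blocks`, `block_size_range` and `block_r`.
#' @param n_blocks,block_size_range,block_r Used when `block_spec` is `NULL`.
#' @param background_peaks_per_chrom Uncorrelated filler peaks per chromosome.
#' @param background_r Correlation among background peaks (shared chromosome
#'   factor; 0 = independent).
#' @param peak_width,peak_spacing Peak geometry in bp (start-to-start spacing).
#' @param qtl_var_frac Fraction of block-activity variance explained by the
#'   planted cis-QTL (applied to every block; set 0 to disable).
#' @param gene_r2 Fraction of expression variance explained by the driver
#'   block for planted cis genes (one per block; 0 disables).
#' @param background_genes_per_chrom Unlinked genes per chromosome.
#' @param trans_spec Tibble `block_a`, `block_b`, `coupling` of planted
#'   inter-chromosomal couplings, or `NULL` for a default set of 5 pairs with
#'   coupling 0.6 spanning distinct chromosomes.
#' @param n_trans_pairs,trans_coupling Used when `trans_spec` is `NULL`.
#' @param background_variants_per_chrom Variants with no planted effect.
#' @param maf_range Uniform range for allele frequencies.
#' @param methyl_size_mix Named list `mu_small`, `sigma_small`, `mu_large`,
#'   `sigma_large`, `weight_small` on log10 bp.
#' @param n_mcrds Number of planted methylation domains.
#' @param mcrd_r Within-domain CpG correlation.
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(n_samples = 500,
                              n_chrom = 4,
                              block_spec = NULL,
                              n_blocks = 20,
                              block_size_range = c(8L, 20L),
                              block_r = 0.7,
                              background_peaks_per_chrom = 30,
                              background_r = 0,
                              peak_width = 600,
                              peak_spacing = 2000,
                              qtl_var_frac = 0.2,
                              gene_r2 = 0.25,
                              background_genes_per_chrom = 10,
                              trans_spec = NULL,
                              n_trans_pairs = 5,
                              trans_coupling = 0.6,
                              background_variants_per_chrom = 20,
                              maf_range = c(0.1, 0.5),
                              methyl_size_mix = list(mu_small = 2.48, sigma_small = 0.25,
                                                     mu_large = 4.60, sigma_large = 0.25,
                                                     weight_small = 0.5),
                              n_mcrds = 40,
                              mcrd_r = 0.7,
                              seed = 1L) {
  stopifnot(n_samples >= 3, n_chrom >= 1)
  if (!is.null(block_spec)) {
    block_spec <- as_tibble(block_spec)
    stopifnot(all(c("block_id", "chrom", "n_peaks", "r") %in% names(block_spec)))
  }
  if (!is.null(trans_spec)) {
    trans_spec <- as_tibble(trans_spec)
    stopifnot(all(c("block_a", "block_b", "coupling") %in% names(trans_spec)))
  }
  with_mix <- methyl_size_mix
  stopifnot(with_mix$weight_small > 0, with_mix$weight_small < 1,
            with_mix$sigma_small > 0, with_mix$sigma_large > 0)
  structure(list(
    n_samples = n_samples, n_chrom = n_chrom, block_spec = block_spec,
    n_blocks = n_blocks, block_size_range = as.integer(block_size_range),
    block_r = block_r, background_peaks_per_chrom = background_peaks_per_chrom,
    background_r = background_r, peak_width = peak_width,
    peak_spacing = peak_spacing, qtl_var_frac = qtl_var_frac,
    gene_r2 = gene_r2, background_genes_per_chrom = background_genes_per_chrom,
    trans_spec = trans_spec, n_trans_pairs = n_trans_pairs,
    trans_coupling = trans_coupling,
    background_variants_per_chrom = background_variants_per_chrom,
    maf_range = maf_range, methyl_size_mix = with_mix, n_mcrds = n_mcrds,
    mcrd_r = mcrd_r, seed = as.integer(seed)
  ), class = "sim_config")
}

# standard normal matrix helper
rnorm_mat <- function(n, m) matrix(rnorm(n * m), n, m)

# dosage vector with guaranteed polymorphism (redraw up to 20 times)
sim_dosage <- function(n, maf_range) {
  for (i in 1:20) {
    f <- runif(1, maf_range[1], maf_range[2])
    g <- rbinom(n, 2, f)
    if (var(g) > 0) return(g)
  }
  g
}

#' Simulate a population multi-omics dataset with planted ground truth
#'
#' Peaks within a planted block are generated from a shared latent Gaussian
#' factor: `peak = sqrt(r) * factor + sqrt(1 - r) * noise`, which gives an
#' expected pairwise correlation of exactly `r`. The planted cis-QTL is mixed
#' into the block factor with a loading calibrated so that the variant
#' explains the configured fraction of block *activity* (mean of member
#' peaks) variance in expectation. Planted genes draw the configured fraction
#' of their variance from the realized (standardized) block activity;
#' trans-coupled blocks share their latent factors with the configured
#' coupling. CpG probes are laid out in methylation domains whose genomic
#' sizes are drawn from the configured two-component log10-normal mixture.
#'
#' @param config A [simulation_config()].
#' @return A list with elements `peaks`, `genes`, `cpgs` ([quant_matrix]),
#'   `genotypes` ([geno_matrix]), `tss` (gene TSS tibble) and `truth`, a list
#'   of tibbles (`blocks`, `membership`, `qtls`, `genes`, `trans`, `mcrds`).
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_samples
  samples <- sprintf("ind%03d", seq_len(n))
  chroms <- sprintf("chr%d", seq_len(config$n_chrom))

  blocks <- config$block_spec
  if (is.null(blocks)) {
    sizes <- sample(seq(config$block_size_range[1], config$block_size_range[2]),
                    config$n_blocks, replace = TRUE)
    blocks <- tibble(
      block_id = sprintf("block%02d", seq_len(config$n_blocks)),
      chrom = chroms[((seq_len(config$n_blocks) - 1) %% config$n_chrom) + 1],
      n_peaks = sizes, r = config$block_r
    )
  }
  bad_r <- blocks$r < 0 | blocks$r >= 1
  if (any(bad_r)) {
    abort(paste0("Infeasible correlation target (single-factor model needs r in [0,1)): ",
                 paste(blocks$block_id[bad_r], collapse = ", ")))
  }

  trans <- config$trans_spec
  if (is.null(trans) && config$n_trans_pairs > 0 && nrow(blocks) >= 2) {
    # pair blocks on distinct chromosomes, no block reused
    avail <- blocks[order(blocks$block_id), ]
    pairs <- list()
    used <- character(0)
    for (i in seq_len(nrow(avail))) {
      if (length(pairs) >= config$n_trans_pairs) break
      a <- avail$block_id[i]
      if (a %in% used) next
      j <- which(avail$chrom != avail$chrom[i] & !(avail$block_id %in% c(used, a)))
      if (!length(j)) next
      b <- avail$block_id[j[1]]
      pairs[[length(pairs) + 1]] <- tibble(block_a = a, block_b = b,
                                           coupling = config$trans_coupling)
      used <- c(used, a, b)
    }
    trans <- bind_rows(pairs)
  }
  if (is.null(trans)) trans <- tibble(block_a = character(), block_b = character(),
                                      coupling = numeric())

  # ---- genomic layout: blocks then background peaks per chromosome ----
  peak_rows <- list()
  membership <- list()
  for (ch in chroms) {
    ch_blocks <- blocks[blocks$chrom == ch, ]
    pos <- 10000
    idx <- 0L
    add_peak <- function(block_id) {
      idx <<- idx + 1L
      id <- sprintf("%s_peak%04d", ch, idx)
      peak_rows[[length(peak_rows) + 1]] <<- tibble(
        phenotype_id = id, chrom = ch, start = as.integer(pos),
        end = as.integer(pos + config$peak_width)
      )
      membership[[length(membership) + 1]] <<- tibble(
        phenotype_id = id, block_id = block_id
      )
      pos <<- pos + config$peak_spacing
    }
    n_bg <- config$background_peaks_per_chrom
    # interleave: a run of background, then each block, then more background
    bg_chunk <- if (nrow(ch_blocks)) max(1L, n_bg %/% (nrow(ch_blocks) + 1L)) else n_bg
    bg_left <- n_bg
    emit_bg <- function(k) {
      k <- min(k, bg_left)
      if (k > 0) for (z in seq_len(k)) add_peak(NA_character_)
      bg_left <<- bg_left - k
    }
    emit_bg(bg_chunk)
    if (nrow(ch_blocks)) for (b in seq_len(nrow(ch_blocks))) {
      for (z in seq_len(ch_blocks$n_peaks[b])) add_peak(ch_blocks$block_id[b])
      pos <- pos + 5 * config$peak_spacing  # gap between block and background
      emit_bg(bg_chunk)
    }
    emit_bg(bg_left)
  }
  peak_ann <- bind_rows(peak_rows)
  membership <- bind_rows(membership)

  # ---- genotypes: one QTL variant per block + background variants ----
  var_rows <- list()
  dosage_rows <- list()
  qtl_truth <- list()
  for (b in seq_len(nrow(blocks))) {
    bid <- blocks$block_id[b]
    span <- peak_ann[peak_ann$phenotype_id %in%
                       membership$phenotype_id[membership$block_id %in% bid], ]
    center <- as.integer((min(span$start) + max(span$end)) / 2)
    vid <- sprintf("var_%s", bid)
    var_rows[[length(var_rows) + 1]] <- tibble(
      variant_id = vid, chrom = blocks$chrom[b], pos = center, ref = "A", alt = "G"
    )
    dosage_rows[[vid]] <- sim_dosage(n, config$maf_range)
    qtl_truth[[length(qtl_truth) + 1]] <- tibble(
      block_id = bid, variant_id = vid, var_frac = config$qtl_var_frac
    )
  }
  for (ch in chroms) {
    span_max <- max(peak_ann$end[peak_ann$chrom == ch])
    for (k in seq_len(config$background_variants_per_chrom)) {
      vid <- sprintf("var_bg_%s_%02d", ch, k)
      var_rows[[length(var_rows) + 1]] <- tibble(
        variant_id = vid, chrom = ch,
        pos = as.integer(k * span_max / (config$background_variants_per_chrom + 1)),
        ref = "A", alt = "G"
      )
      dosage_rows[[vid]] <- sim_dosage(n, config$maf_range)
    }
  }
  variants <- bind_rows(var_rows)
  dosages <- do.call(rbind, dosage_rows[variants$variant_id])
  qtl_truth <- bind_rows(qtl_truth)

  # ---- latent block factors (QTL + trans coupling mixed in) ----
  # Var(activity) for a block of m peaks = r + (1 - r) / m (unit-variance
  # factor and noise); the QTL contributes r * v of it, so the loading v on
  # the factor is solved from the requested activity-variance fraction q.
  factor_of <- setNames(vector("list", nrow(blocks)), blocks$block_id)
  coupled_to <- setNames(trans$block_a, trans$block_b)
  build_factor <- function(bid) {
    if (!is.null(factor_of[[bid]])) return(factor_of[[bid]])
    b <- which(blocks$block_id == bid)
    m <- blocks$n_peaks[b]; r <- blocks$r[b]
    q <- config$qtl_var_frac
    v <- if (q > 0 && r > 0) min(q * (r + (1 - r) / m) / r, 0.9) else 0
    rho <- 0
    base <- NULL
    if (bid %in% names(coupled_to)) {
      rho <- trans$coupling[trans$block_b == bid][1]
      base <- build_factor(coupled_to[[bid]])
    }
    if (rho^2 + v > 0.99) v <- 0.99 - rho^2
    g <- dosage_rows[[paste0("var_", bid)]]
    gs <- as.numeric(scale(g))
    eps <- rnorm(n)
    f <- sqrt(v) * gs + (if (!is.null(base)) rho * base else 0) +
      sqrt(max(1 - v - rho^2, 0)) * eps
    factor_of[[bid]] <<- f
    f
  }
  for (bid in blocks$block_id) build_factor(bid)

  # ---- peak values ----
  chrom_bg_factor <- setNames(lapply(chroms, function(ch) rnorm(n)), chroms)
  values <- matrix(NA_real_, nrow(peak_ann), n)
  for (i in seq_len(nrow(peak_ann))) {
    bid <- membership$block_id[i]
    if (!is.na(bid)) {
      r <- blocks$r[blocks$block_id == bid]
      values[i, ] <- sqrt(r) * factor_of[[bid]] + sqrt(1 - r) * rnorm(n)
    } else if (config$background_r > 0) {
      rb <- config$background_r
      values[i, ] <- sqrt(rb) * chrom_bg_factor[[peak_ann$chrom[i]]] +
        sqrt(1 - rb) * rnorm(n)
    } else {
      values[i, ] <- rnorm(n)
    }
  }
  peaks <- quant_matrix(peak_ann, values, samples, "peak", quiet = TRUE)

  # ---- genes: one planted gene per block + background genes ----
  gene_rows <- list(); gene_vals <- list(); gene_truth <- list(); tss_rows <- list()
  for (b in seq_len(nrow(blocks))) {
    bid <- blocks$block_id[b]
    mem <- membership$phenotype_id[membership$block_id %in% bid]
    span <- peak_ann[peak_ann$phenotype_id %in% mem, ]
    gid <- sprintf("gene_%s", bid)
    gstart <- as.integer(max(span$end) + 50000)
    gene_rows[[length(gene_rows) + 1]] <- tibble(
      phenotype_id = gid, chrom = blocks$chrom[b],
      start = gstart, end = gstart + 2000L
    )
    act <- colMeans(values[peak_ann$phenotype_id %in% mem, , drop = FALSE])
    act <- as.numeric(scale(act))
    c2 <- config$gene_r2
    gene_vals[[gid]] <- sqrt(c2) * act + sqrt(1 - c2) * rnorm(n)
    gene_truth[[length(gene_truth) + 1]] <- tibble(
      gene_id = gid, block_id = bid, r2 = c2
    )
    tss_rows[[length(tss_rows) + 1]] <- tibble(
      gene_id = gid, chrom = blocks$chrom[b], tss = gstart + 1L, strand = "+"
    )
  }
  for (ch in chroms) {
    span_max <- max(peak_ann$end[peak_ann$chrom == ch])
    for (k in seq_len(config$background_genes_per_chrom)) {
      gid <- sprintf("gene_bg_%s_%02d", ch, k)
      gstart <- as.integer(span_max + 200000 + k * 30000)
      gene_rows[[length(gene_rows) + 1]] <- tibble(
        phenotype_id = gid, chrom = ch, start = gstart, end = gstart + 2000L
      )
      gene_vals[[gid]] <- rnorm(n)
      tss_rows[[length(tss_rows) + 1]] <- tibble(
        gene_id = gid, chrom = ch, tss = gstart + 1L, strand = "+"
      )
    }
  }
  gene_ann <- bind_rows(gene_rows)
  genes <- quant_matrix(gene_ann, do.call(rbind, gene_vals[gene_ann$phenotype_id]),
                        samples, "gene", quiet = TRUE)
  tss <- bind_rows(tss_rows)

  # ---- CpGs in methylation domains with mixture-drawn sizes ----
  mix <- config$methyl_size_mix
  n_m <- config$n_mcrds
  comp_small <- runif(n_m) < mix$weight_small
  log_size <- ifelse(comp_small,
                     rnorm(n_m, mix$mu_small, mix$sigma_small),
                     rnorm(n_m, mix$mu_large, mix$sigma_large))
  sizes <- pmax(10L, as.integer(round(10^log_size)))
  cpg_rows <- list(); cpg_vals <- list(); mcrd_truth <- list()
  cpg_idx <- 0L
  for (d in seq_len(n_m)) {
    ch <- chroms[((d - 1) %% config$n_chrom) + 1]
    offset <- 5e6 + (d - 1) %/% config$n_chrom * 3e6
    dstart <- as.integer(offset)
    dend <- dstart + sizes[d]
    n_cpg <- sample(3:8, 1)
    # first/last probe anchored at the domain ends so span == drawn size
    pos <- as.integer(round(seq(dstart, dend - 1L, length.out = n_cpg)))
    pos <- unique(pos)
    f_dom <- rnorm(n)
    ids <- character(0)
    for (p in pos) {
      cpg_idx <- cpg_idx + 1L
      id <- sprintf("cpg%05d", cpg_idx)
      ids <- c(ids, id)
      cpg_rows[[length(cpg_rows) + 1]] <- tibble(
        phenotype_id = id, chrom = ch, start = p, end = p + 1L
      )
      cpg_vals[[id]] <- sqrt(config$mcrd_r) * f_dom +
        sqrt(1 - config$mcrd_r) * rnorm(n)
    }
    mcrd_truth[[length(mcrd_truth) + 1]] <- tibble(
      mcrd_id = sprintf("mcrd%03d", d), chrom = ch, start = dstart, end = dend,
      size_bp = sizes[d], component = ifelse(comp_small[d], "small", "large"),
      members = list(ids)
    )
  }
  if (length(cpg_rows)) {
    cpg_ann <- bind_rows(cpg_rows)
    cpgs <- quant_matrix(cpg_ann, do.call(rbind, cpg_vals[cpg_ann$phenotype_id]),
                         samples, "cpg", quiet = TRUE)
  } else {
    cpgs <- quant_matrix(
      tibble(phenotype_id = character(), chrom = character(),
             start = integer(), end = integer()),
      matrix(numeric(0), 0, n), samples, "cpg", quiet = TRUE
    )
  }

  genotypes <- geno_matrix(variants, dosages, samples)

  truth <- list(
    blocks = blocks,
    membership = membership[!is.na(membership$block_id), ],
    qtls = qtl_truth,
    genes = bind_rows(gene_truth),
    trans = trans,
    mcrds = bind_rows(mcrd_truth)
  )
  list(peaks = peaks, genes = genes, cpgs = cpgs, genotypes = genotypes,
       tss = tss, truth = truth)
}

#' Simulate a promoter-capture interaction table enriched at planted links
#'
#' Fragment pairs spanning planted gene-block links receive a significant
#' score (>= 5) with probability `min(1, enrichment * noise_rate)`; random
#' same-chromosome fragment pairs with probability `noise_rate`.
#'
#' @param sim Output of [simulate_population()].
#' @param enrichment Fold enrichment of support at planted links (>= 1).
#' @param noise_rate Baseline support probability for random pairs.
#' @param n_random Number of random fragment pairs to emit.
#' @param seed Integer seed.
#' @return An interaction tibble (`chromA..endB`, `score`, `planted`).
#' @export
simulate_interactions <- function(sim, enrichment = 10, noise_rate = 0.05,
                                  n_random = 200, seed = 1L) {
  stopifnot(enrichment >= 1, noise_rate >= 0, noise_rate <= 1)
  set.seed(seed)
  truth <- sim$truth
  peak_ann <- sim$peaks$phenotypes
  rows <- list()
  p_hit <- min(1, enrichment * noise_rate)
  score_of <- function(hit) if (hit) 5 + rexp(1) else runif(1, 0, 5)
  for (i in seq_len(nrow(truth$genes))) {
    bid <- truth$genes$block_id[i]
    gid <- truth$genes$gene_id[i]
    mem <- truth$membership$phenotype_id[truth$membership$block_id == bid]
    span <- peak_ann[peak_ann$phenotype_id %in% mem, ]
    g <- sim$tss[sim$tss$gene_id == gid, ]
    rows[[length(rows) + 1]] <- tibble(
      chromA = g$chrom, startA = g$tss - 1000L, endA = g$tss + 1000L,
      chromB = g$chrom, startB = as.integer(min(span$start)),
      endB = as.integer(max(span$end)),
      score = score_of(runif(1) < p_hit), planted = TRUE
    )
  }
  chroms <- unique(peak_ann$chrom)
  for (k in seq_len(n_random)) {
    ch <- sample(chroms, 1)
    s1 <- sample.int(2e6, 1) + 3e6  # away from planted blocks
    s2 <- s1 + sample.int(5e5, 1) + 50000L
    rows[[length(rows) + 1]] <- tibble(
      chromA = ch, startA = as.integer(s1), endA = as.integer(s1 + 4000L),
      chromB = ch, startB = as.integer(s2), endB = as.integer(s2 + 4000L),
      score = score_of(runif(1) < noise_rate), planted = FALSE
    )
  }
  bind_rows(rows)
}

#' Simulate GWAS summary statistics over a genotype panel
#'
#' Null variants get Uniform(0,1) p-values (via standard-normal z scores);
#' causal variants get z-scores centered at `effect_z`, and any variant
#' correlated with a causal one inherits a proportionally deflated p-value
#' through its dosage correlation (an implicit LD proxy effect).
#'
#' @param genotypes A [geno_matrix].
#' @param causal Character vector of causal variant ids (subset of the panel).
#' @param effect_z Mean |z| at causal variants (7 gives p < 1e-5 with
#'   probability > 0.95).
#' @param seed Integer seed.
#' @return Tibble `variant_id`, `p`.
#' @export
simulate_gwas <- function(genotypes, causal = character(), effect_z = 7, seed = 1L) {
  set.seed(seed)
  ids <- genotypes$variants$variant_id
  stopifnot(all(causal %in% ids))
  mu <- numeric(length(ids))
  if (length(causal)) {
    cz <- genotypes$dosages[causal, , drop = FALSE]
    for (i in seq_along(ids)) {
      rho <- suppressWarnings(
        max(abs(cor(genotypes$dosages[i, ], t(cz))), na.rm = TRUE)
      )
      if (is.finite(rho)) mu[i] <- rho * effect_z
    }
  }
  z <- rnorm(length(ids), mean = mu)
  tibble(variant_id = ids, p = pchisq(z^2, df = 1, lower.tail = FALSE))
}
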