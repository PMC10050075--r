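#' Per-individual CRD activity
#'
#' Quantifies each CRD as the unweighted mean of its member phenotype rows,
#' giving one activity value per individual — the vector used in all CRD
#' association tests.
#'
#' @param x The source [quant_matrix].
#' @param crds CRD tibble from [call_crds()] (or [read_crds()]).
#' @return An object of class `activity_matrix` (CRD annotation + CRDs x
#'   samples matrix, sample order of `x`).
#' @export
crd_activity <- function(x, crds) {
  stopifnot(inherits(x, "quant_matrix"))
  ids <- x$phenotypes$phenotype_id
  vals <- matrix(NA_real_, nrow(crds), length(x$sample_id))
  for (i in seq_len(nrow(crds))) {
    mem <- crds$members[[i]]
    missing <- setdiff(mem, ids)
    if (length(missing)) {
      abort(paste0("CRD ", crds$crd_id[i], " has member(s) absent from the matrix: ",
                   paste(head(missing, 5), collapse = ", ")))
    }
    vals[i, ] <- colMeans(x$values[match(mem, ids), , drop = FALSE])
  }
  rownames(vals) <- crds$crd_id
  colnames(vals) <- x$sample_id
  structure(list(
    crds = select(crds, "crd_id", "chrom", "start", "end", "n_members", "class"),
    values = vals, sample_id = x$sample_id
  ), class = "activity_matrix")
}

#' @export
print.activity_matrix <- function(x, ...) {
  cat(sprintf("<activity_matrix> %d CRDs x %d samples\n",
              nrow(x$values), length(x$sample_id)))
  invisible(x)
}

#' @export
dim.activity_matrix <- function(x) dim(x$values)

#' A positioned feature set for cis scans
#'
#' Wraps a features x samples value matrix with per-feature point positions
#' (1-based), the common currency of [cis_scan()] and [map_cis()]. Use
#' [as_feature_set()] to build one from a [geno_matrix] (variants at their
#' positions) or from an expression [quant_matrix] plus a TSS table (genes at
#' their TSS).
#'
#' @param values Numeric matrix, features x samples.
#' @param info Tibble `feature_id`, `chrom`, `pos`.
#' @param sample_id Sample names.
#' @return An object of class `feature_set`.
#' @export
feature_set <- function(values, info, sample_id) {
  values <- as.matrix(values)
  info <- as_tibble(info)
  stopifnot(all(c("feature_id", "chrom", "pos") %in% names(info)),
            nrow(info) == nrow(values), length(sample_id) == ncol(values))
  rownames(values) <- info$feature_id
  structure(list(values = values, info = info, sample_id = as.character(sample_id)),
            class = "feature_set")
}

#' @param x Object to convert.
#' @param ... Passed on to methods.
#' @rdname feature_set
#' @export
as_feature_set <- function(x, ...) UseMethod("as_feature_set")

#' @rdname feature_set
#' @export
as_feature_set.geno_matrix <- function(x, ...) {
  feature_set(x$dosages,
              tibble(feature_id = x$variants$variant_id,
                     chrom = x$variants$chrom, pos = x$variants$pos),
              x$sample_id)
}

#' @param tss TSS tibble (`gene_id`, `chrom`, `tss`, `strand`) for gene
#'   features; genes without a TSS entry are dropped.
#' @rdname feature_set
#' @export
as_feature_set.quant_matrix <- function(x, tss, ...) {
  hit <- match(x$phenotypes$phenotype_id, tss$gene_id)
  keep <- !is.na(hit)
  feature_set(x$values[keep, , drop = FALSE],
              tibble(feature_id = x$phenotypes$phenotype_id[keep],
                     chrom = tss$chrom[hit[keep]], pos = tss$tss[hit[keep]]),
              x$sample_id)
}

#' @rdname feature_set
#' @export
as_feature_set.activity_matrix <- function(x, ...) {
  # CRDs anchored at their midpoint when used as features (e.g. gene ~ CRD)
  feature_set(x$values,
              tibble(feature_id = x$crds$crd_id, chrom = x$crds$chrom,
                     pos = as.integer((x$crds$start + x$crds$end) / 2)),
              x$sample_id)
}

# correlation, slope and t-test p of y against every row of X
assoc_stats <- function(y, X) {
  n <- length(y)
  sds <- unname(apply(X, 1, sd))
  r <- suppressWarnings(as.numeric(cor(y, t(X))))
  r[sds == 0] <- NA_real_
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  p[is.na(r)] <- NA_real_
  slope <- r * sd(y) / ifelse(sds == 0, NA_real_, sds)
  list(r = r, slope = slope, p = p)
}

# feature rows of fs within [start - window, end + window] on chrom
features_in_window <- function(fs, chrom, start, end, window_bp) {
  which(fs$info$chrom == chrom &
          fs$info$pos >= start - window_bp &
          fs$info$pos <= end + window_bp)
}

#' Best cis association of one phenotype
#'
#' Tests every feature whose position falls within `window_bp` of the anchor
#' interval with a simple linear regression (t-test p, n - 2 df) and returns
#' the smallest-p feature; ties break to the smallest genomic position.
#' Zero-variance features are skipped with a warning. With no feature in the
#' window an "untested" sentinel row (NA feature) is returned.
#'
#' @param y Numeric phenotype vector (one value per sample).
#' @param features A [feature_set] with matching sample order.
#' @param anchor List or one-row data frame with `chrom`, `start`, `end`.
#' @param window_bp Cis window in bp around the anchor boundaries (default
#'   1 Mb).
#' @return One-row tibble `feature_id`, `feature_pos`, `slope`, `nominal_p`,
#'   `n_features`.
#' @export
cis_scan <- function(y, features, anchor, window_bp = 1e6) {
  stopifnot(inherits(features, "feature_set"))
  idx <- features_in_window(features, anchor$chrom, anchor$start, anchor$end,
                            window_bp)
  if (!length(idx)) {
    return(tibble(feature_id = NA_character_, feature_pos = NA_integer_,
                  slope = NA_real_, nominal_p = NA_real_, n_features = 0L))
  }
  st <- assoc_stats(y, features$values[idx, , drop = FALSE])
  if (anyNA(st$p)) {
    warn(paste0("Skipped ", sum(is.na(st$p)), " zero-variance feature(s) in window."))
  }
  ok <- which(!is.na(st$p))
  if (!length(ok)) {
    return(tibble(feature_id = NA_character_, feature_pos = NA_integer_,
                  slope = NA_real_, nominal_p = NA_real_, n_features = 0L))
  }
  pos <- features$info$pos[idx]
  best <- ok[order(st$p[ok], pos[ok])][1]
  tibble(feature_id = features$info$feature_id[idx[best]],
         feature_pos = pos[best], slope = st$slope[best],
         nominal_p = st$p[best], n_features = length(ok))
}

#' Permutation-adjusted best-association p-value
#'
#' Shuffles the phenotype across samples `n_perm` times, records the best
#' association statistic per permutation over the same feature window, and
#' returns the add-one empirical p-value
#' `(1 + #(permutation best p <= observed best p)) / (1 + n_perm)`.
#'
#' @inheritParams cis_scan
#' @param n_perm Number of permutations (default 1000; below 100 a
#'   resolution warning is emitted).
#' @param seed Integer seed.
#' @return Scalar adjusted p (NA when no feature is in the window).
#' @export
permutation_adjust <- function(y, features, anchor, window_bp = 1e6,
                               n_perm = 1000, seed = 1L) {
  if (n_perm < 100) {
    warn(paste0("n_perm = ", n_perm, " limits adjusted-p resolution to ",
                signif(1 / (n_perm + 1), 3)))
  }
  idx <- features_in_window(features, anchor$chrom, anchor$start, anchor$end,
                            window_bp)
  if (!length(idx)) return(NA_real_)
  X <- features$values[idx, , drop = FALSE]
  keep <- apply(X, 1, sd) > 0
  if (!any(keep)) return(NA_real_)
  X <- X[keep, , drop = FALSE]
  n <- length(y)
  obs <- max(abs(suppressWarnings(cor(y, t(X)))), na.rm = TRUE)
  set.seed(seed)
  perm <- matrix(y[vapply(seq_len(n_perm), function(i) sample.int(n), integer(n))],
                 nrow = n)
  null_best <- apply(abs(suppressWarnings(cor(perm, t(X)))), 1, max, na.rm = TRUE)
  # larger |r| <=> smaller p at fixed df, so compare on |r|
  (1 + sum(null_best >= obs)) / (1 + n_perm)
}

# residualize y on the selected feature rows (plus intercept)
residual_on <- function(y, X_sel) {
  if (is.null(X_sel) || nrow(X_sel) == 0) return(y - mean(y))
  qr.resid(qr(cbind(1, t(X_sel))), y)
}

#' Forward-backward conditional scan for independent cis signals
#'
#' Forward pass: repeatedly residualize the phenotype on the already selected
#' features, rescan the window, and add the best feature while its
#' permutation-adjusted p passes `threshold`. Backward pass: re-test each
#' selected feature on the phenotype residualized on all the others, dropping
#' failures. Ranks are assigned in forward order (0 = primary signal).
#'
#' @inheritParams permutation_adjust
#' @param threshold Per-phenotype adjusted-p threshold (the adjusted p whose
#'   q-value equals the family FDR level).
#' @param max_signals Safety cap on the number of forward iterations.
#' @return Tibble of selected signals with `rank`, `feature_id`,
#'   `feature_pos`, `slope`, `nominal_p`, `adjusted_p` (empty if the primary
#'   signal fails `threshold`).
#' @export
conditional_scan <- function(y, features, anchor, threshold, window_bp = 1e6,
                             n_perm = 1000, seed = 1L, max_signals = 10L) {
  idx <- features_in_window(features, anchor$chrom, anchor$start, anchor$end,
                            window_bp)
  if (!length(idx)) return(conditional_empty())
  sel <- character(0)
  rows <- list()
  for (k in seq_len(max_signals)) {
    X_sel <- if (length(sel)) features$values[sel, , drop = FALSE] else NULL
    # guard against collinear selections
    if (!is.null(X_sel) && qr(cbind(1, t(X_sel)))$rank < length(sel) + 1) {
      inform("Dropping collinear selected feature from conditional model.")
      sel <- sel[-length(sel)]
      X_sel <- if (length(sel)) features$values[sel, , drop = FALSE] else NULL
    }
    y_res <- residual_on(y, X_sel)
    hit <- cis_scan(y_res, features, anchor, window_bp)
    if (is.na(hit$feature_id) || hit$feature_id %in% sel) break
    adj <- permutation_adjust(y_res, features, anchor, window_bp, n_perm,
                              seed = seed + k)
    if (is.na(adj) || adj > threshold) break
    rows[[k]] <- mutate(hit, adjusted_p = adj, rank = k - 1L)
    sel <- c(sel, hit$feature_id)
  }
  if (!length(rows)) return(conditional_empty())
  fwd <- bind_rows(rows)
  # backward: keep features that stay significant given all the others
  keep <- map_lgl(seq_len(nrow(fwd)), function(i) {
    if (nrow(fwd) == 1) return(TRUE)
    others <- fwd$feature_id[-i]
    y_res <- residual_on(y, features$values[others, , drop = FALSE])
    adj <- permutation_adjust(y_res, features, anchor, window_bp, n_perm,
                              seed = seed + 100 + i)
    !is.na(adj) && adj <= threshold
  })
  out <- fwd[keep, , drop = FALSE]
  out$rank <- seq_len(nrow(out)) - 1L
  select(out, "rank", "feature_id", "feature_pos", "slope", "nominal_p",
         "adjusted_p")
}

conditional_empty <- function() {
  tibble(rank = integer(), feature_id = character(), feature_pos = integer(),
         slope = numeric(), nominal_p = numeric(), adjusted_p = numeric())
}

# phenotype iterator shared by map_cis: rows with id/anchor/values
phenotype_rows <- function(phenotypes) {
  if (inherits(phenotypes, "activity_matrix")) {
    list(id = phenotypes$crds$crd_id, chrom = phenotypes$crds$chrom,
         start = phenotypes$crds$start, end = phenotypes$crds$end,
         values = phenotypes$values)
  } else if (inherits(phenotypes, "quant_matrix")) {
    list(id = phenotypes$phenotypes$phenotype_id,
         chrom = phenotypes$phenotypes$chrom,
         start = phenotypes$phenotypes$start, end = phenotypes$phenotypes$end,
         values = phenotypes$values)
  } else {
    abort("phenotypes must be an activity_matrix or quant_matrix.")
  }
}

#' Map cis associations for a set of phenotypes
#'
#' The full cis pipeline for CRD-gene, CRD-QTL or eQTL mapping: per
#' phenotype, scan the window for the best feature ([cis_scan()]), calibrate
#' it against `n_perm` phenotype permutations ([permutation_adjust()]), then
#' control the FDR across phenotypes ([fdr_qvalue()]); optionally follow up
#' significant phenotypes with the forward-backward [conditional_scan()].
#' Deterministic for a fixed `seed`.
#'
#' @param phenotypes An `activity_matrix` (CRD activities) or [quant_matrix]
#'   (e.g. gene expression).
#' @param features A [feature_set], [geno_matrix] or expression
#'   [quant_matrix] (the latter needs `tss`).
#' @param tss TSS table when `features` is an expression matrix.
#' @param window_bp Cis window (default 1 Mb).
#' @param n_perm Permutations per phenotype (default 1000).
#' @param fdr FDR level (default 0.05).
#' @param method Q-value method across phenotypes.
#' @param conditional Run the conditional scan on significant phenotypes.
#' @param seed Integer seed.
#' @return Tibble of association records: `phenotype_id`, `feature_id`,
#'   `feature_pos`, `slope`, `nominal_p`, `adjusted_p`, `q_value`,
#'   `significant`, `rank` (0 = primary; conditional signals have rank >= 1
#'   and inherit the primary's q_value).
#' @export
map_cis <- function(phenotypes, features, tss = NULL, window_bp = 1e6,
                    n_perm = 1000, fdr = 0.05, method = c("storey", "bh"),
                    conditional = FALSE, seed = 1L) {
  method <- match.arg(method)
  if (inherits(features, "geno_matrix")) features <- as_feature_set(features)
  if (inherits(features, "quant_matrix")) {
    if (is.null(tss)) abort("Gene features need a `tss` table.")
    features <- as_feature_set(features, tss)
  }
  ph <- phenotype_rows(phenotypes)
  n_ph <- length(ph$id)
  rows <- vector("list", n_ph)
  for (i in seq_len(n_ph)) {
    anchor <- list(chrom = ph$chrom[i], start = ph$start[i], end = ph$end[i])
    y <- ph$values[i, ]
    hit <- suppressWarnings(cis_scan(y, features, anchor, window_bp))
    adj <- if (hit$n_features > 0) {
      suppressWarnings(
        permutation_adjust(y, features, anchor, window_bp, n_perm,
                           seed = seed + i)
      )
    } else NA_real_
    rows[[i]] <- mutate(hit, phenotype_id = ph$id[i], adjusted_p = adj)
  }
  res <- bind_rows(rows)
  tested <- !is.na(res$adjusted_p)
  res$q_value <- NA_real_
  res$significant <- FALSE
  if (any(tested)) {
    fq <- fdr_qvalue(res$adjusted_p[tested], method = method, level = fdr)
    res$q_value[tested] <- fq$q_value
    res$significant[tested] <- fq$significant
  }
  res$rank <- 0L
  out <- select(res, "phenotype_id", "feature_id", "feature_pos", "slope",
                "nominal_p", "adjusted_p", "q_value", "significant",
                "n_features", "rank")
  if (conditional && any(out$significant)) {
    sig_adj <- out$adjusted_p[out$significant]
    threshold <- max(sig_adj, na.rm = TRUE)
    extra <- list()
    for (i in which(out$significant)) {
      j <- match(out$phenotype_id[i], ph$id)
      anchor <- list(chrom = ph$chrom[j], start = ph$start[j], end = ph$end[j])
      cond <- suppressWarnings(
        conditional_scan(ph$values[j, ], features, anchor, threshold,
                         window_bp, n_perm, seed = seed + 10000 + j)
      )
      if (nrow(cond) > 1) {
        add <- cond[cond$rank >= 1, , drop = FALSE]
        add$phenotype_id <- out$phenotype_id[i]
        add$q_value <- out$q_value[i]
        add$significant <- TRUE
        add$n_features <- out$n_features[i]
        extra[[length(extra) + 1]] <- select(add, names(out))
      }
    }
    if (length(extra)) out <- bind_rows(out, bind_rows(extra))
  }
  arrange(out, .data$phenotype_id, .data$rank)
}

#' Co-expressed gene pairs in cis
#'
#' Pearson correlation of expression for all same-chromosome gene pairs with
#' TSS distance at most `max_distance_bp`, t-test p-values, and Storey
#' q-values across all pairs at the given FDR (default 1%).
#'
#' @param expr Expression [quant_matrix].
#' @param tss TSS table.
#' @param max_distance_bp Maximum TSS distance (default 1 Mb).
#' @param fdr FDR level (default 0.01).
#' @return Tibble `gene_a`, `gene_b`, `distance`, `r`, `p`, `q_value`,
#'   `significant`.
#' @export
coexpression_pairs <- function(expr, tss, max_distance_bp = 1e6, fdr = 0.01) {
  stopifnot(inherits(expr, "quant_matrix"))
  info <- inner_join(expr$phenotypes, tss,
                     by = c(phenotype_id = "gene_id", chrom = "chrom"))
  rows <- list()
  n <- ncol(expr$values)
  for (ch in unique(info$chrom)) {
    g <- info[info$chrom == ch, ]
    if (nrow(g) < 2) next
    g <- arrange(g, .data$tss)
    cm <- cor(t(expr$values[match(g$phenotype_id, expr$phenotypes$phenotype_id), ,
                            drop = FALSE]))
    ij <- which(upper.tri(cm), arr.ind = TRUE)
    d <- abs(g$tss[ij[, 2]] - g$tss[ij[, 1]])
    keep <- d <= max_distance_bp
    if (!any(keep)) next
    rows[[ch]] <- tibble(
      gene_a = g$phenotype_id[ij[keep, 1]], gene_b = g$phenotype_id[ij[keep, 2]],
      distance = d[keep], r = cm[ij[keep, , drop = FALSE]]
    )
  }
  pairs <- bind_rows(rows)
  if (!nrow(pairs)) {
    return(tibble(gene_a = character(), gene_b = character(),
                  distance = integer(), r = numeric(), p = numeric(),
                  q_value = numeric(), significant = logical()))
  }
  tstat <- pairs$r * sqrt((n - 2) / pmax(1 - pairs$r^2, .Machine$double.eps))
  pairs$p <- 2 * pt(-abs(tstat), df = n - 2)
  fq <- fdr_qvalue(pairs$p, method = "storey", level = fdr)
  pairs$q_value <- fq$q_value
  pairs$significant <- fq$significant
  pairs
}

#' Same-CRD enrichment of co-expressed gene pairs by distance
#'
#' For each TSS-distance bin, the fraction of significantly co-expressed
#' pairs whose two genes are cis-associated with one common CRD, and the
#' odds ratio of the 2x2 table (co-expressed x same-CRD) over all candidate
#' pairs in the bin (Haldane 0.5 correction when a cell is zero).
#'
#' @param pairs Output of [coexpression_pairs()].
#' @param crd_gene CRD-gene association table ([map_cis()] with gene
#'   features); only significant records are used.
#' @param bins Distance bin edges in bp (sorted, length >= 2).
#' @return Tibble per bin: `bin_lo`, `bin_hi`, `n_coexpressed`,
#'   `n_same_crd`, `fraction_same_crd` (NA on empty bins), `odds_ratio`.
#' @export
same_crd_enrichment <- function(pairs, crd_gene, bins) {
  if (is.unsorted(bins, strictly = TRUE)) abort("bins must be strictly increasing.")
  sig <- crd_gene[crd_gene$significant, , drop = FALSE]
  crd_of <- split(sig$phenotype_id, sig$feature_id)  # gene -> CRDs
  same_crd <- map_lgl(seq_len(nrow(pairs)), function(i) {
    a <- crd_of[[pairs$gene_a[i]]]; b <- crd_of[[pairs$gene_b[i]]]
    !is.null(a) && !is.null(b) && length(intersect(a, b)) > 0
  })
  out <- list()
  for (k in seq_len(length(bins) - 1)) {
    in_bin <- pairs$distance >= bins[k] & pairs$distance < bins[k + 1]
    co <- pairs$significant & in_bin
    n_co <- sum(co)
    n_same <- sum(co & same_crd)
    a <- n_same; b <- n_co - n_same
    c_ <- sum(in_bin & !pairs$significant & same_crd)
    d <- sum(in_bin & !pairs$significant & !same_crd)
    or <- if (any(c(a, b, c_, d) == 0)) {
      ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
    } else (a * d) / (b * c_)
    out[[k]] <- tibble(
      bin_lo = bins[k], bin_hi = bins[k + 1],
      n_coexpressed = n_co, n_same_crd = n_same,
      fraction_same_crd = if (n_co > 0) n_same / n_co else NA_real_,
      odds_ratio = if (sum(in_bin) > 0) or else NA_real_
    )
  }
  bind_rows(out)
}
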