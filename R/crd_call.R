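#' Windowed inter-individual correlation map
#'
#' Computes the Pearson correlation between all same-chromosome phenotype
#' pairs whose index distance (in phenotypes, genomic order) is at most
#' `window`. Pairs beyond the window are untested: their correlation is
#' stored as `NA` and contributes nothing to any correlation average
#' downstream. The input should already be covariate-corrected and
#' rank-normalized.
#'
#' @param x A [quant_matrix] (>= 3 samples).
#' @param window Sliding-window size in phenotypes (default 250).
#' @return An object of class `correlation_map`: per-chromosome correlation
#'   matrices (NA outside the window) plus phenotype coordinates.
#' @export
correlation_map <- function(x, window = 250) {
  stopifnot(inherits(x, "quant_matrix"))
  if (window < 1) abort("window must be >= 1.")
  if (ncol(x$values) < 3) abort("Need >= 3 samples for correlation.")
  chrom_maps <- list()
  for (ch in unique(x$phenotypes$chrom)) {
    idx <- which(x$phenotypes$chrom == ch)
    n <- length(idx)
    r <- cor(t(x$values[idx, , drop = FALSE]))
    if (n > 1) {
      dist_idx <- abs(outer(seq_len(n), seq_len(n), `-`))
      r[dist_idx > window] <- NA_real_
    }
    diag(r) <- NA_real_
    chrom_maps[[ch]] <- list(
      phenotype_id = x$phenotypes$phenotype_id[idx],
      start = x$phenotypes$start[idx],
      end = x$phenotypes$end[idx],
      r = r
    )
  }
  structure(list(chrom_maps = chrom_maps, window = window,
                 phenotype_class = x$phenotype_class,
                 n_samples = ncol(x$values)),
            class = "correlation_map")
}

#' @export
print.correlation_map <- function(x, ...) {
  n <- sum(map_int(x$chrom_maps, ~ length(.x$phenotype_id)))
  cat(sprintf("<correlation_map> %d phenotypes on %d chromosome(s), window %d\n",
              n, length(x$chrom_maps), x$window))
  invisible(x)
}

#' Correlation map as a tidy pair table
#'
#' @param x A `correlation_map`.
#' @param ... Unused.
#' @return Tibble with one row per tested pair (`i < j`).
#' @export
as_tibble.correlation_map <- function(x, ...) {
  bind_rows(imap(x$chrom_maps, function(m, ch) {
    n <- length(m$phenotype_id)
    if (n < 2) return(tibble())
    ij <- which(upper.tri(m$r) & !is.na(m$r), arr.ind = TRUE)
    tibble(chrom = ch,
           phenotype_a = m$phenotype_id[ij[, 1]],
           phenotype_b = m$phenotype_id[ij[, 2]],
           r = m$r[ij])
  }))
}

#' Hierarchical clustering of the correlation map into binary trees
#'
#' One agglomerative tree per chromosome, average linkage on the distance
#' `d(i, j) = 1 - |r(i, j)|` (or `1 - r` with `use_abs = FALSE`); untested
#' pairs get distance 1. Single-phenotype chromosomes yield no tree (with a
#' warning).
#'
#' @param cmap A [correlation_map()].
#' @param use_abs Cluster on `|r|` (default) or signed `r`.
#' @return An object of class `crd_tree`: per chromosome, the
#'   [stats::hclust] merge structure plus member coordinates.
#' @export
build_tree <- function(cmap, use_abs = TRUE) {
  stopifnot(inherits(cmap, "correlation_map"))
  trees <- list()
  for (ch in names(cmap$chrom_maps)) {
    m <- cmap$chrom_maps[[ch]]
    n <- length(m$phenotype_id)
    if (n < 2) {
      warn(paste0("Chromosome ", ch, " has a single phenotype; no tree built."))
      next
    }
    r <- if (use_abs) abs(m$r) else m$r
    d <- 1 - r
    d[is.na(d)] <- 1
    diag(d) <- 0
    hc <- hclust(as.dist(d), method = "average")
    trees[[ch]] <- list(merge = hc$merge, height = hc$height,
                        phenotype_id = m$phenotype_id,
                        start = m$start, end = m$end)
  }
  structure(list(trees = trees, use_abs = use_abs), class = "crd_tree")
}

#' @export
print.crd_tree <- function(x, ...) {
  cat(sprintf("<crd_tree> %d chromosome tree(s)\n", length(x$trees)))
  invisible(x)
}

# member leaf indices for every internal node of an hclust merge matrix
node_members <- function(merge) {
  n_nodes <- nrow(merge)
  members <- vector("list", n_nodes)
  for (k in seq_len(n_nodes)) {
    mm <- lapply(merge[k, ], function(child) {
      if (child < 0) -child else members[[child]]
    })
    members[[k]] <- sort(c(mm[[1]], mm[[2]]))
  }
  members
}

# criteria evaluation shared by the recursive caller and (in tests) the
# exhaustive oracle; A is |r| with NA at untested pairs.
# Conditions: (i) within-node mean >= factor * chromosome mean and above the
# chance floor; (ii) mean over pairs involving the genomically first/last
# member >= factor * the chromosome's first/last-peak value; (iii) at least
# two non-overlapping member intervals; (iv) coherence: the between-children
# mean correlation of the merge clears the same bar as (i), so a node that
# joins two uncorrelated groups is split rather than emitted.
crd_criteria <- function(members, A, start, end, factor,
                         baseline_all, baseline_edge, r_floor = 0,
                         child_members = NULL) {
  if (length(members) < 2) return(list(pass = FALSE, mean_abs_r = NA_real_))
  sub <- A[members, members, drop = FALSE]
  vals <- sub[upper.tri(sub)]
  vals <- vals[!is.na(vals)]
  if (!length(vals)) return(list(pass = FALSE, mean_abs_r = NA_real_))
  mean_r <- mean(vals)
  bar <- max(factor * baseline_all, r_floor)
  c1 <- is.finite(baseline_all) && mean_r >= bar
  # members are in genomic order (peaks sorted by start), so the genomically
  # first/last member is the min/max index
  first <- min(members); last <- max(members)
  edge_vals <- c(A[first, setdiff(members, first)],
                 A[setdiff(members, c(first, last)), last])
  edge_vals <- edge_vals[!is.na(edge_vals)]
  c2 <- length(edge_vals) > 0 && is.finite(baseline_edge) &&
    mean(edge_vals) >= factor * baseline_edge
  c3 <- max(start[members]) >= min(end[members])
  c4 <- TRUE
  if (!is.null(child_members) && length(child_members) == 2) {
    cross <- A[child_members[[1]], child_members[[2]], drop = FALSE]
    cross <- cross[!is.na(cross)]
    c4 <- length(cross) > 0 && mean(cross) >= bar
  }
  list(pass = c1 && c2 && c3 && c4, mean_abs_r = mean_r)
}

# chromosome-level reference values for criteria i and ii
crd_baselines <- function(A, n) {
  vals <- A[upper.tri(A)]
  baseline_all <- mean(vals, na.rm = TRUE)
  edge_vals <- c(A[1, 2:n], if (n > 2) A[2:(n - 1), n])
  baseline_edge <- mean(edge_vals, na.rm = TRUE)
  list(all = baseline_all, edge = baseline_edge)
}

# Bonferroni bound on the largest null |r| among n_pairs tested pairs at
# n_samples individuals (Fisher z): any candidate domain must beat the
# correlation level that pure noise reaches somewhere on the chromosome
chance_floor <- function(n_pairs, n_samples, alpha = 0.001) {
  if (n_pairs < 1 || n_samples <= 3) return(0)
  tanh(qnorm(1 - alpha / n_pairs) / sqrt(n_samples - 3))
}

#' Call cis-regulatory domains from a clustering tree
#'
#' Walks each chromosome tree from the root and emits an internal node as a
#' CRD at the first (highest) node satisfying all three criteria: (i) the
#' mean absolute correlation over tested within-node pairs is at least
#' `factor` times the chromosome-wide mean over tested pairs; (ii) the mean
#' absolute correlation of within-node pairs involving the node's
#' genomically first or last member is at least `factor` times the analogous
#' chromosome value (pairs involving the chromosome's first or last peak);
#' (iii) the members cover at least two non-overlapping genomic intervals.
#' Children of an emitted node are not descended into, so CRDs from one tree
#' are membership-disjoint.
#'
#' @param tree A [build_tree()] result.
#' @param cmap The matching [correlation_map()].
#' @param factor Criteria multiplier (default 2).
#' @param crd_class `"hCRD"` or `"mCRD"`; by default inferred from the map's
#'   phenotype class (`cpg` gives mCRD).
#' @param min_abs_r Absolute floor on the within-node and between-children
#'   mean `|r|`. `NULL` (default) sets it per chromosome to the chance level:
#'   the Bonferroni bound on the largest null pair correlation given the
#'   number of tested pairs (`alpha = 0.001`). Set to 0 to disable.
#' @param alpha Family-wise level for the automatic chance floor.
#' @return Tibble with columns `crd_id`, `chrom`, `start`, `end`,
#'   `n_members`, `mean_internal_abs_r`, `members` (list column of phenotype
#'   ids), `class`.
#' @export
call_crds <- function(tree, cmap, factor = 2.0, crd_class = NULL,
                      min_abs_r = NULL, alpha = 0.001) {
  stopifnot(inherits(tree, "crd_tree"), inherits(cmap, "correlation_map"))
  if (factor <= 0) abort("factor must be > 0.")
  if (is.null(crd_class)) {
    crd_class <- if (cmap$phenotype_class == "cpg") "mCRD" else "hCRD"
  }
  out <- list()
  for (ch in names(tree$trees)) {
    tr <- tree$trees[[ch]]
    m <- cmap$chrom_maps[[ch]]
    if (is.null(m) || !identical(m$phenotype_id, tr$phenotype_id)) {
      abort(paste0("Tree and correlation map disagree on chromosome ", ch))
    }
    n <- length(tr$phenotype_id)
    A <- abs(m$r)
    base <- crd_baselines(A, n)
    n_tested <- sum(!is.na(A[upper.tri(A)]))
    r_floor <- if (is.null(min_abs_r)) {
      chance_floor(n_tested, cmap$n_samples %||% 0, alpha)
    } else min_abs_r
    members <- node_members(tr$merge)
    n_nodes <- nrow(tr$merge)
    child_sets <- function(k) {
      lapply(tr$merge[k, ], function(child) {
        if (child < 0) -child else members[[child]]
      })
    }
    hits <- integer(0)
    visit <- function(k) {  # k = internal node index
      cr <- crd_criteria(members[[k]], A, tr$start, tr$end, factor,
                         base$all, base$edge, r_floor, child_sets(k))
      if (cr$pass) {
        hits <<- c(hits, k)
        return(invisible())
      }
      for (child in tr$merge[k, ]) if (child > 0) visit(child)
    }
    visit(n_nodes)  # root is the last merge
    for (k in hits) {
      mem <- members[[k]]
      cr <- crd_criteria(mem, A, tr$start, tr$end, factor, base$all,
                         base$edge, r_floor, child_sets(k))
      out[[length(out) + 1]] <- tibble(
        chrom = ch,
        start = min(tr$start[mem]), end = max(tr$end[mem]),
        n_members = length(mem),
        mean_internal_abs_r = cr$mean_abs_r,
        members = list(tr$phenotype_id[mem]),
        class = crd_class
      )
    }
  }
  crds <- bind_rows(out)
  if (!nrow(crds)) {
    return(tibble(crd_id = character(), chrom = character(),
                  start = integer(), end = integer(), n_members = integer(),
                  mean_internal_abs_r = numeric(), members = list(),
                  class = character()))
  }
  crds <- arrange(crds, .data$chrom, .data$start)
  crds$crd_id <- sprintf("crd_%s_%03d", crds$chrom,
                         stats::ave(seq_len(nrow(crds)), crds$chrom, FUN = seq_along))
  select(crds, "crd_id", "chrom", "start", "end", "n_members",
         "mean_internal_abs_r", "members", "class")
}

#' Two-component Gaussian mixture on log10 domain sizes
#'
#' Fits small-domain / large-domain components to `log10(length)` by EM
#' (tolerance 1e-6 on the log-likelihood, at most 500 iterations).
#' Components are labeled by mean; the size threshold is the 0.95 quantile
#' of the small component, `10^(mu_small + 1.6449 * sigma_small)` bp. If the
#' EM degenerates (a component variance collapses), a single-component
#' fallback is returned with `converged = FALSE`.
#'
#' @param lengths Domain sizes in bp (>= 20 values).
#' @return An object of class `crd_size_mixture`.
#' @export
fit_size_mixture <- function(lengths) {
  if (length(lengths) < 20) abort("Need >= 20 lengths to fit the size mixture.")
  if (any(lengths <= 0)) abort("Lengths must be positive.")
  x <- log10(lengths)
  fallback <- function() {
    mu <- mean(x); s <- sd(x)
    structure(list(mu_small = mu, sigma_small = s, mu_large = mu,
                   sigma_large = s, weight_small = 1,
                   size_threshold_bp = 10^(mu + 1.6449 * s),
                   converged = FALSE,
                   loglik = sum(dnorm(x, mu, max(s, 1e-12), log = TRUE)),
                   n = length(x), log10_sizes = x),
              class = "crd_size_mixture")
  }
  if (sd(x) < 1e-12) {
    warn("All lengths identical; single-component fallback.")
    return(fallback())
  }
  # split-at-median initialization
  med <- median(x)
  lo <- x[x <= med]; hi <- x[x > med]
  mu <- c(mean(lo), mean(hi))
  sg <- pmax(c(sd(lo), sd(hi)), 0.05)
  w <- c(0.5, 0.5)
  ll_old <- -Inf
  converged <- FALSE
  for (it in 1:500) {
    d1 <- w[1] * dnorm(x, mu[1], sg[1])
    d2 <- w[2] * dnorm(x, mu[2], sg[2])
    tot <- d1 + d2
    if (any(tot == 0)) tot[tot == 0] <- .Machine$double.xmin
    g <- d1 / tot
    ll <- sum(log(tot))
    if (is.finite(ll) && abs(ll - ll_old) < 1e-6) { converged <- TRUE; break }
    ll_old <- ll
    w <- c(mean(g), 1 - mean(g))
    mu <- c(sum(g * x) / sum(g), sum((1 - g) * x) / sum(1 - g))
    sg <- sqrt(c(sum(g * (x - mu[1])^2) / sum(g),
                 sum((1 - g) * (x - mu[2])^2) / sum(1 - g)))
    if (any(!is.finite(sg)) || any(sg < 1e-6) || any(w < 1e-6)) {
      warn("EM degenerated; single-component fallback.")
      return(fallback())
    }
  }
  ord <- order(mu)  # label by mean: small first
  mu <- mu[ord]; sg <- sg[ord]; w <- w[ord]
  structure(list(mu_small = mu[1], sigma_small = sg[1],
                 mu_large = mu[2], sigma_large = sg[2],
                 weight_small = w[1],
                 size_threshold_bp = 10^(mu[1] + 1.6449 * sg[1]),
                 converged = converged, loglik = ll_old, n = length(x),
                 log10_sizes = x),
            class = "crd_size_mixture")
}

#' @export
print.crd_size_mixture <- function(x, ...) {
  cat(sprintf(paste0("<crd_size_mixture> small: N(%.3f, %.3f) w=%.2f | ",
                     "large: N(%.3f, %.3f) | threshold %.0f bp | converged: %s\n"),
              x$mu_small, x$sigma_small, x$weight_small,
              x$mu_large, x$sigma_large, x$size_threshold_bp, x$converged))
  invisible(x)
}

#' Size-select methylation CRDs above the small-domain threshold
#'
#' Keeps CRDs whose genomic span (`end - start`) strictly exceeds the 0.95
#' quantile of the fitted small-domain component, discarding the mode of
#' probe clusters that sit inside a single regulatory region.
#'
#' @param crds CRD tibble (class mCRD).
#' @param fit A [fit_size_mixture()] result.
#' @param fallback_threshold_bp Threshold to use when `fit` did not converge
#'   (error if the fit failed and no fallback is given).
#' @return The filtered CRD tibble.
#' @export
size_filter_mcrds <- function(crds, fit, fallback_threshold_bp = NULL) {
  stopifnot(inherits(fit, "crd_size_mixture"))
  thr <- if (fit$converged) fit$size_threshold_bp else fallback_threshold_bp
  if (is.null(thr)) {
    abort("Mixture fit did not converge and no fallback threshold was supplied.")
  }
  crds[(crds$end - crds$start) > thr, , drop = FALSE]
}
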