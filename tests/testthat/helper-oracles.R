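# Fixture builders and independent oracles used across the suite.
# Oracles deliberately use naive loop-based code paths distinct from the
# package implementation.

# quick quant_matrix on one or more synthetic chromosomes
toy_qm <- function(values, chrom = NULL, start = NULL, width = 600L,
                   spacing = 2000L, class = "peak") {
  values <- as.matrix(values)
  n <- nrow(values)
  if (is.null(chrom)) chrom <- rep("chr1", n)
  if (is.null(start)) {
    start <- integer(n)
    for (ch in unique(chrom)) {
      idx <- which(chrom == ch)
      start[idx] <- 10000L + (seq_along(idx) - 1L) * spacing
    }
  }
  quant_matrix(
    tibble::tibble(phenotype_id = sprintf("p%03d", seq_len(n)),
                   chrom = chrom, start = as.integer(start),
                   end = as.integer(start + width)),
    values,
    sprintf("s%02d", seq_len(ncol(values))),
    class, quiet = TRUE
  )
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# best Jaccard of each truth block against any called CRD
block_recovery <- function(truth_membership, crds) {
  mem <- split(truth_membership$phenotype_id, truth_membership$block_id)
  vapply(mem, function(m) {
    if (!nrow(crds)) return(0)
    max(vapply(crds$members, function(cm) jaccard(m, cm), numeric(1)))
  }, numeric(1))
}

# exhaustive CRD oracle: re-evaluates the node criteria on EVERY internal
# node with naive loops, then keeps nodes with no passing ancestor.
# Returns a list of member phenotype-id sets per chromosome tree.
exhaustive_crds <- function(tree, cmap, factor = 2.0, alpha = 0.001) {
  out <- list()
  for (ch in names(tree$trees)) {
    tr <- tree$trees[[ch]]
    m <- cmap$chrom_maps[[ch]]
    A <- abs(m$r)
    n <- length(tr$phenotype_id)
    n_tested <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (!is.na(A[i, j])) n_tested <- n_tested + 1
    }
    floor_r <- tanh(qnorm(1 - alpha / n_tested) / sqrt(cmap$n_samples - 3))
    # baselines by naive loops
    s_all <- 0; k_all <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (!is.na(A[i, j])) { s_all <- s_all + A[i, j]; k_all <- k_all + 1 }
    }
    base_all <- s_all / k_all
    ev <- c()
    for (j in 2:n) if (!is.na(A[1, j])) ev <- c(ev, A[1, j])
    for (i in 2:(n - 1)) if (!is.na(A[i, n])) ev <- c(ev, A[i, n])
    base_edge <- mean(ev)

    merge <- tr$merge
    n_nodes <- nrow(merge)
    memb <- vector("list", n_nodes)
    kids <- vector("list", n_nodes)
    for (k in seq_len(n_nodes)) {
      get <- function(child) if (child < 0) -child else memb[[child]]
      kids[[k]] <- list(get(merge[k, 1]), get(merge[k, 2]))
      memb[[k]] <- sort(c(kids[[k]][[1]], kids[[k]][[2]]))
    }
    mean_pairs <- function(set) {
      s <- 0; cnt <- 0
      for (a in seq_along(set)) for (b in seq_along(set)) {
        if (a < b && !is.na(A[set[a], set[b]])) {
          s <- s + A[set[a], set[b]]; cnt <- cnt + 1
        }
      }
      if (cnt == 0) NA_real_ else s / cnt
    }
    passes <- vapply(seq_len(n_nodes), function(k) {
      set <- memb[[k]]
      mn <- mean_pairs(set)
      bar <- max(factor * base_all, floor_r)
      if (is.na(mn) || mn < bar) return(FALSE)
      first <- min(set); last <- max(set)
      ev2 <- c()
      for (s2 in setdiff(set, first)) if (!is.na(A[first, s2])) ev2 <- c(ev2, A[first, s2])
      for (s2 in setdiff(set, c(first, last))) if (!is.na(A[s2, last])) ev2 <- c(ev2, A[s2, last])
      if (!length(ev2) || mean(ev2) < factor * base_edge) return(FALSE)
      if (max(tr$start[set]) < min(tr$end[set])) return(FALSE)
      cr <- c()
      for (a in kids[[k]][[1]]) for (b in kids[[k]][[2]]) {
        if (!is.na(A[a, b])) cr <- c(cr, A[a, b])
      }
      length(cr) > 0 && mean(cr) >= bar
    }, logical(1))
    # parent map: node k is a child of parent p if merge[p, ] contains k
    parent <- rep(NA_integer_, n_nodes)
    for (p in seq_len(n_nodes)) for (child in merge[p, ]) {
      if (child > 0) parent[child] <- p
    }
    has_passing_ancestor <- function(k) {
      p <- parent[k]
      while (!is.na(p)) {
        if (passes[p]) return(TRUE)
        p <- parent[p]
      }
      FALSE
    }
    sel <- which(passes & !vapply(seq_len(n_nodes), has_passing_ancestor, logical(1)))
    for (k in sel) out[[length(out) + 1]] <- sort(tr$phenotype_id[memb[[k]]])
  }
  out
}

# adjusted Rand index by the pair-counting formula
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  mx <- (si + sj) / 2
  if (mx == expected) return(1)
  (sij - expected) / (mx - expected)
}

# random small CRD tibble for IO round-trips
random_crds <- function(n, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    crd_id = sprintf("crd_chr1_%03d", seq_len(n)),
    chrom = "chr1",
    start = as.integer(sort(sample.int(1e6, n))),
    end = NA_integer_,
    n_members = sample(2:6, n, replace = TRUE),
    mean_internal_abs_r = round(runif(n), 6),
    members = lapply(seq_len(n), function(i)
      sprintf("pk%02d_%d", seq_len(sample(2:6, 1)), i)),
    class = sample(c("hCRD", "mCRD"), n, replace = TRUE)
  ) |>
    dplyr::mutate(end = start + as.integer(sample(1000:50000, n, replace = TRUE)),
                  n_members = lengths(members))
}

# row-standardize a matrix (used to inject planted effects)
scale_rows <- function(m) t(scale(t(m)))
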