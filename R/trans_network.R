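#' Inter-chromosomal CRD-CRD association scan
#'
#' Pearson correlation and t-test p-value for every pair of CRDs on distinct
#' autosomal chromosomes (same-chromosome pairs are never tested). The test
#' count is the sum over chromosome pairs of `nA * nB`.
#'
#' @param activities An `activity_matrix` from [crd_activity()].
#' @param autosomes Chromosome-name allowlist; CRDs elsewhere are dropped.
#'   Defaults to all chromosomes present (synthetic data), use
#'   `paste0("chr", 1:22)` for human input.
#' @return Tibble `crd_a`, `crd_b` (lexicographically `crd_a < crd_b`),
#'   `chrom_a`, `chrom_b`, `r`, `p`.
#' @export
trans_scan <- function(activities, autosomes = NULL) {
  stopifnot(inherits(activities, "activity_matrix"))
  crds <- activities$crds
  if (!is.null(autosomes)) crds <- crds[crds$chrom %in% autosomes, , drop = FALSE]
  if (length(unique(crds$chrom)) < 2) abort("Need CRDs on >= 2 chromosomes.")
  n <- length(activities$sample_id)
  if (n < 10) warn("Fewer than 10 samples; trans correlations will be unstable.")
  V <- activities$values[crds$crd_id, , drop = FALSE]
  cm <- cor(t(V))
  ij <- which(upper.tri(cm), arr.ind = TRUE)
  keep <- crds$chrom[ij[, 1]] != crds$chrom[ij[, 2]]
  ij <- ij[keep, , drop = FALSE]
  a <- crds$crd_id[ij[, 1]]; b <- crds$crd_id[ij[, 2]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  cha <- ifelse(swap, crds$chrom[ij[, 2]], crds$chrom[ij[, 1]])
  chb <- ifelse(swap, crds$chrom[ij[, 1]], crds$chrom[ij[, 2]])
  r <- cm[ij]
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  tibble(crd_a = a, crd_b = b, chrom_a = cha, chrom_b = chb, r = r,
         p = 2 * pt(-abs(tstat), df = n - 2))
}

#' Significant trans edges at an FDR cutoff
#'
#' Storey q-values over all scanned pairs; keeps `q <= fdr` (default 1%).
#' Idempotent: edges are already stored once with `crd_a < crd_b`.
#'
#' @param scan Output of [trans_scan()].
#' @param fdr FDR level (default 0.01).
#' @return The significant subset with a `q_value` column.
#' @export
trans_significant <- function(scan, fdr = 0.01) {
  if (!nrow(scan)) return(mutate(scan, q_value = numeric(0)))
  fq <- fdr_qvalue(scan$p, method = "storey", level = fdr)
  scan$q_value <- fq$q_value
  scan[fq$significant, , drop = FALSE]
}

#' Detect trans-regulatory hubs by greedy modularity
#'
#' Communities of the (unweighted) significant-edge graph via greedy
#' modularity agglomeration (Clauset-Newman-Moore, `igraph`). Non-edge CRDs
#' are absent by construction; single-member communities are excluded from
#' the output.
#'
#' @param edges Tibble of significant edges ([trans_significant()]).
#' @return Tibble `trh_id`, `crd_id` (one row per member CRD), with the
#'   community count and modularity as attributes `"n_communities"` and
#'   `"modularity"`. Empty edges give an empty tibble.
#' @export
detect_trhs <- function(edges) {
  if (!nrow(edges)) {
    out <- tibble(trh_id = character(), crd_id = character())
    attr(out, "n_communities") <- 0L
    attr(out, "modularity") <- NA_real_
    return(out)
  }
  g <- igraph::graph_from_data_frame(
    tibble(from = edges$crd_a, to = edges$crd_b), directed = FALSE
  )
  g <- igraph::simplify(g)
  comm <- igraph::cluster_fast_greedy(g)
  memb <- as.integer(igraph::membership(comm))
  names(memb) <- names(igraph::membership(comm))
  # tie pass: the greedy cut can leave a member of a clique in its own
  # community at zero modularity gain; keep merging while modularity does
  # not decrease (ties resolved toward the lexicographically smallest pair)
  repeat {
    q0 <- igraph::modularity(g, memb)
    ids <- sort(unique(memb))
    if (length(ids) < 2) break
    merged <- FALSE
    first_crd <- vapply(ids, function(cc) min(names(memb)[memb == cc]), "")
    ord <- ids[order(first_crd)]
    for (a_i in seq_len(length(ord) - 1)) {
      for (b_i in (a_i + 1):length(ord)) {
        trial <- memb
        trial[trial == ord[b_i]] <- ord[a_i]
        if (igraph::modularity(g, trial) >= q0 - 1e-12) {
          memb <- trial
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  out <- tibble(crd_id = names(memb), community = as.integer(memb))
  sizes <- count(out, .data$community)
  keep <- sizes$community[sizes$n >= 2]
  out <- out[out$community %in% keep, , drop = FALSE]
  # stable ids ordered by decreasing size then lexicographic first member
  ord <- out |>
    group_by(.data$community) |>
    summarise(size = n(), first_crd = min(.data$crd_id)) |>
    arrange(desc(.data$size), .data$first_crd)
  relab <- setNames(sprintf("trh%03d", seq_len(nrow(ord))), ord$community)
  res <- tibble(trh_id = relab[as.character(out$community)], crd_id = out$crd_id)
  res <- arrange(res, .data$trh_id, .data$crd_id)
  attr(res, "n_communities") <- nrow(ord)
  attr(res, "modularity") <- igraph::modularity(g, memb)
  res
}

#' Degree and TRH-size summaries of a trans network
#'
#' @param edges Significant edge tibble.
#' @param trhs TRH membership tibble ([detect_trhs()]).
#' @return List of tibbles `degrees` (`crd_id`, `degree`) and `trh_sizes`
#'   (`trh_id`, `size`).
#' @export
network_summary <- function(edges, trhs) {
  deg <- bind_rows(tibble(crd_id = edges$crd_a), tibble(crd_id = edges$crd_b)) |>
    count(.data$crd_id, name = "degree") |>
    arrange(desc(.data$degree), .data$crd_id)
  sizes <- count(trhs, .data$trh_id, name = "size")
  list(degrees = deg, trh_sizes = sizes)
}
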