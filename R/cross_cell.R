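#' CRD sharing between two cell types (50% membership rule)
#'
#' A query CRD is shared if at least `min_fraction` of its members also
#' belong to *any* CRD of the reference cell type. Membership is by
#' phenotype id (peaks are assumed called on a cross-cell consensus set).
#' The rule is asymmetric: swap the arguments for the other direction.
#'
#' @param query_crds,ref_crds CRD tibbles.
#' @param min_fraction Sharing threshold (default 0.5, boundary inclusive).
#' @return One-row tibble `n_query_crds`, `n_shared`, `fraction`, with a
#'   per-CRD tibble as attribute `"per_crd"`.
#' @export
crd_sharing <- function(query_crds, ref_crds, min_fraction = 0.5) {
  if (!nrow(query_crds)) abort("Empty query CRD list; sharing fraction undefined.")
  ref_members <- unique(unlist(ref_crds$members))
  per <- tibble(
    crd_id = query_crds$crd_id,
    n_members = map_int(query_crds$members, length),
    n_in_ref = map_int(query_crds$members, ~ sum(.x %in% ref_members))
  )
  per$fraction_in_ref <- per$n_in_ref / per$n_members
  per$shared <- per$fraction_in_ref >= min_fraction
  out <- tibble(n_query_crds = nrow(per), n_shared = sum(per$shared),
                fraction = sum(per$shared) / nrow(per))
  attr(out, "per_crd") <- per
  out
}

#' CRD activity on another cell type's data, fixed peak set
#'
#' Computes the activity of reference-defined CRD member sets on a different
#' cell type's quantification matrix ("same exact set of peaks"), so that
#' associations can be compared across cell types on a common definition.
#'
#' @param crds_ref Reference-cell CRD tibble.
#' @param matrix_other The other cell's [quant_matrix] (must quantify every
#'   member).
#' @return An `activity_matrix` on the other cell's samples.
#' @export
fixed_peakset_activity <- function(crds_ref, matrix_other) {
  crd_activity(matrix_other, crds_ref)
}

#' Fraction of reference-significant associations replicated in a query cell
#'
#' `|significant in both| / |significant in reference|`, with pairs keyed by
#' (phenotype, feature). Both tables must come from the same candidate
#' universe at the same FDR level.
#'
#' @param ref_assoc,query_assoc Association tibbles ([map_cis()]).
#' @return Scalar fraction.
#' @export
association_sharing <- function(ref_assoc, query_assoc) {
  key <- function(tab) {
    sig <- tab[tab$significant & !is.na(tab$feature_id), ]
    paste(sig$phenotype_id, sig$feature_id, sep = "\r")
  }
  ref <- key(ref_assoc)
  if (!length(ref)) abort("Reference has no significant associations.")
  length(intersect(ref, key(query_assoc))) / length(ref)
}

#' Storey's pi1 replication estimate
#'
#' The estimated proportion of true positives among replication p-values:
#' `1 - pi0`, with pi0 from [storey_pi0()], clipped to `[0, 1]`. Input
#' should be the p-values of reference-significant associations re-tested in
#' the query cell type.
#'
#' @param p Replication p-values (a warning is issued below 20 values).
#' @return Scalar pi1.
#' @export
pi1 <- function(p) {
  if (length(p) < 20) warn("Fewer than 20 p-values; pi1 estimate is unstable.")
  min(max(1 - storey_pi0(p), 0), 1)
}

#' All-pairs cell-type sharing matrices
#'
#' Applies [crd_sharing()] to every ordered (query, reference) pair of CRD
#' maps, returning a tidy table of sharing fractions in both directions.
#'
#' @param crd_maps Named list of CRD tibbles, one per cell type.
#' @param min_fraction Sharing threshold.
#' @return Tibble `query`, `reference`, `n_query_crds`, `n_shared`,
#'   `fraction`.
#' @export
compare_cells <- function(crd_maps, min_fraction = 0.5) {
  cells <- names(crd_maps)
  stopifnot(length(cells) >= 2)
  out <- list()
  for (q in cells) for (r in setdiff(cells, q)) {
    s <- crd_sharing(crd_maps[[q]], crd_maps[[r]], min_fraction)
    out[[length(out) + 1]] <- mutate(s, query = q, reference = r)
  }
  select(bind_rows(out), "query", "reference", "n_query_crds", "n_shared",
         "fraction")
}
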