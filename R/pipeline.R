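# canonical stage order and per-stage seed offsets (fixed, so toggling one
# stage never perturbs another stage's randomness)
PIPELINE_STAGES <- c(simulate = 0L, normalize = 1000L, call_crds = 2000L,
                     activity = 3000L, map_genes = 4000L, map_qtls = 5000L,
                     trans = 6000L, trhs = 7000L, report = 8000L)

stage_deps <- list(
  simulate = character(0),
  normalize = "simulate",
  call_crds = "normalize",
  activity = c("simulate", "call_crds"),
  map_genes = c("activity", "simulate"),
  map_qtls = c("activity", "simulate"),
  trans = "activity",
  trhs = "trans",
  report = c("map_genes", "call_crds")
)

#' Run the synthetic end-to-end CRD pipeline from a config
#'
#' Executes the enabled stages in order — simulate, normalize (residualize +
#' rank-normal), call_crds, activity, map_genes, map_qtls, trans, trhs,
#' report — writing each artifact as a plain TSV/BED under `out_dir`, plus a
#' `manifest.json` with the config hash, seed and per-file MD5 checksums.
#' Reruns with the same config are bit-identical. Before execution, stage
#' dependencies are validated (dry run): an enabled stage whose upstream
#' stage is disabled and whose artifact is absent from `out_dir` is an
#' error.
#'
#' @param config A named list or path to a YAML file. Recognized keys:
#'   `seed`, `out_dir`, `stages` (character vector), `simulate` (arguments
#'   for [simulation_config()]), `normalize` (`n_pcs`), `crd` (`window`,
#'   `factor`), `cis` (`window_bp`, `n_perm`, `fdr`), `trans` (`fdr`).
#' @return Named list of artifact file paths (invisibly), with the in-memory
#'   results as attribute `"results"`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$out_dir %||% abort("config$out_dir is required.")
  stages <- config$stages %||% names(PIPELINE_STAGES)
  unknown <- setdiff(stages, names(PIPELINE_STAGES))
  if (length(unknown)) abort(paste0("Unknown stage(s): ", paste(unknown, collapse = ", ")))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  artifact <- function(name) file.path(out_dir, name)
  stage_artifacts <- list(
    simulate = "peaks.bed", normalize = "peaks_normalized.bed",
    call_crds = "crds.tsv", activity = "activity.tsv",
    map_genes = "crd_gene.tsv", map_qtls = "crd_qtl.tsv",
    trans = "trans_edges.tsv", trhs = "trhs.tsv",
    report = "connectivity.tsv"
  )
  # dry-run dependency validation before anything executes
  for (st in stages) {
    for (dep in setdiff(stage_deps[[st]], stages)) {
      if (!file.exists(artifact(stage_artifacts[[dep]]))) {
        abort(paste0("Stage '", st, "' requires disabled stage '", dep,
                     "' and its artifact ", stage_artifacts[[dep]],
                     " is absent from out_dir."))
      }
    }
  }
  s_seed <- function(st) seed + PIPELINE_STAGES[[st]]

  res <- list()
  paths <- list()
  cfg_get <- function(key, default) {
    v <- config[[key]]
    if (is.null(v)) default else utils::modifyList(default, v)
  }
  cis_cfg <- cfg_get("cis", list(window_bp = 1e6, n_perm = 200, fdr = 0.05))
  crd_cfg <- cfg_get("crd", list(window = 250, factor = 2.0))
  norm_cfg <- cfg_get("normalize", list(n_pcs = 0))
  trans_cfg <- cfg_get("trans", list(fdr = 0.01))

  if ("simulate" %in% stages) {
    sim_args <- config$simulate %||% list()
    sim_args$seed <- s_seed("simulate")
    sc <- do.call(simulation_config, sim_args)
    res$sim <- simulate_population(sc)
    paths$peaks <- write_phenotype_bed(res$sim$peaks, artifact("peaks.bed"))
    paths$genes <- write_phenotype_bed(res$sim$genes, artifact("genes.bed"))
    paths$genotypes <- write_dosage_table(res$sim$genotypes, artifact("dosages.tsv"))
    readr::write_tsv(res$sim$truth$membership, artifact("truth_membership.tsv"),
                     progress = FALSE)
    readr::write_tsv(res$sim$tss, artifact("tss.tsv"), progress = FALSE)
  } else {
    res$sim <- list(
      peaks = read_phenotype_bed(artifact("peaks.bed")),
      genes = read_phenotype_bed(artifact("genes.bed"), phenotype_class = "gene"),
      genotypes = read_genotypes(artifact("dosages.tsv")),
      tss = readr::read_tsv(artifact("tss.tsv"), col_types = "ccic",
                            progress = FALSE)
    )
  }

  if ("normalize" %in% stages) {
    cov <- if (norm_cfg$n_pcs > 0) sample_pcs(res$sim$peaks, norm_cfg$n_pcs) else NULL
    res$peaks_norm <- rank_normal(residualize(res$sim$peaks, cov))
    paths$peaks_norm <- write_phenotype_bed(res$peaks_norm,
                                            artifact("peaks_normalized.bed"))
  }
  if ("call_crds" %in% stages) {
    cmap <- correlation_map(res$peaks_norm, window = crd_cfg$window)
    res$crds <- call_crds(build_tree(cmap), cmap, factor = crd_cfg$factor)
    paths$crds <- write_crds(res$crds, artifact("crds.tsv"))
  }
  if ("activity" %in% stages) {
    res$activity <- crd_activity(res$peaks_norm, res$crds)
    act_tab <- bind_cols_quiet(res$activity$crds,
                               as_tibble(res$activity$values))
    readr::write_tsv(act_tab, artifact("activity.tsv"), progress = FALSE)
    paths$activity <- artifact("activity.tsv")
  }
  if ("map_genes" %in% stages) {
    res$crd_gene <- map_cis(res$activity, res$sim$genes, tss = res$sim$tss,
                            window_bp = cis_cfg$window_bp,
                            n_perm = cis_cfg$n_perm, fdr = cis_cfg$fdr,
                            seed = s_seed("map_genes"))
    readr::write_tsv(res$crd_gene, artifact("crd_gene.tsv"), progress = FALSE)
    paths$crd_gene <- artifact("crd_gene.tsv")
  }
  if ("map_qtls" %in% stages) {
    res$crd_qtl <- map_cis(res$activity, res$sim$genotypes,
                           window_bp = cis_cfg$window_bp,
                           n_perm = cis_cfg$n_perm, fdr = cis_cfg$fdr,
                           seed = s_seed("map_qtls"))
    readr::write_tsv(res$crd_qtl, artifact("crd_qtl.tsv"), progress = FALSE)
    paths$crd_qtl <- artifact("crd_qtl.tsv")
  }
  if ("trans" %in% stages) {
    res$trans_edges <- trans_significant(trans_scan(res$activity),
                                         fdr = trans_cfg$fdr)
    readr::write_tsv(res$trans_edges, artifact("trans_edges.tsv"),
                     progress = FALSE)
    paths$trans_edges <- artifact("trans_edges.tsv")
  }
  if ("trhs" %in% stages) {
    res$trhs <- detect_trhs(res$trans_edges)
    readr::write_tsv(res$trhs, artifact("trhs.tsv"), progress = FALSE)
    paths$trhs <- artifact("trhs.tsv")
  }
  if ("report" %in% stages) {
    res$connectivity <- connectivity_report(res$crd_gene, res$crds,
                                            res$sim$genes)
    readr::write_tsv(res$connectivity, artifact("connectivity.tsv"),
                     progress = FALSE)
    paths$connectivity <- artifact("connectivity.tsv")
  }

  cfg_for_hash <- config[sort(names(config))]
  manifest <- list(
    config_hash = digest::digest(cfg_for_hash),
    seed = seed,
    stages = stages,
    checksums = lapply(paths, function(p) digest::digest(file = p))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  attr(paths, "results") <- res
  invisible(paths)
}

#' Subsample the columns (individuals) of a matrix container
#'
#' Uniform sample of `n` sample columns without replacement, seeded; matrices
#' subsampled with the same seed and the same original sample count select
#' identical columns, so co-subsampling across data types is consistent.
#' Column order is preserved; `n` equal to the sample count is the identity.
#'
#' @param x A [quant_matrix], [geno_matrix] or `activity_matrix`.
#' @param n Number of samples to keep.
#' @param seed Integer seed.
#' @return Object of the same class.
#' @export
subsample_samples <- function(x, n, seed = 1L) {
  n_avail <- length(x$sample_id)
  if (n > n_avail) abort(paste0("Requested ", n, " of ", n_avail, " samples."))
  set.seed(seed)
  idx <- sort(sample.int(n_avail, n))
  if (inherits(x, "quant_matrix")) {
    quant_matrix(x$phenotypes, x$values[, idx, drop = FALSE],
                 x$sample_id[idx], x$phenotype_class, quiet = TRUE)
  } else if (inherits(x, "geno_matrix")) {
    geno_matrix(x$variants[, c("variant_id", "chrom", "pos", "ref", "alt")],
                x$dosages[, idx, drop = FALSE], x$sample_id[idx])
  } else if (inherits(x, "activity_matrix")) {
    structure(list(crds = x$crds, values = x$values[, idx, drop = FALSE],
                   sample_id = x$sample_id[idx]), class = "activity_matrix")
  } else {
    abort("Unsupported container for subsampling.")
  }
}

#' Connectivity summary of CRD-gene associations
#'
#' Fractions of CRDs associated with at least one / at least two distinct
#' genes, and of genes associated with at least one / at least two distinct
#' CRDs (significant records only, conditional ranks included).
#'
#' @param crd_gene CRD-gene association table ([map_cis()] with gene
#'   features).
#' @param crds CRD tibble (the CRD universe).
#' @param genes Gene [quant_matrix] or tibble with `phenotype_id` (the gene
#'   universe).
#' @return One-row tibble with the four fractions and the underlying counts.
#' @export
connectivity_report <- function(crd_gene, crds, genes) {
  gene_ids <- if (inherits(genes, "quant_matrix")) {
    genes$phenotypes$phenotype_id
  } else genes$phenotype_id
  sig <- crd_gene[crd_gene$significant & !is.na(crd_gene$feature_id), ]
  per_crd <- sig |> distinct(.data$phenotype_id, .data$feature_id) |>
    count(.data$phenotype_id)
  per_gene <- sig |> distinct(.data$phenotype_id, .data$feature_id) |>
    count(.data$feature_id)
  n_crd <- nrow(crds); n_gene <- length(gene_ids)
  tibble(
    n_crds = n_crd, n_genes = n_gene,
    frac_crds_ge1 = if (n_crd) sum(per_crd$n >= 1) / n_crd else 0,
    frac_crds_ge2 = if (n_crd) sum(per_crd$n >= 2) / n_crd else 0,
    frac_genes_ge1 = if (n_gene) sum(per_gene$n >= 1) / n_gene else 0,
    frac_genes_ge2 = if (n_gene) sum(per_gene$n >= 2) / n_gene else 0
  )
}
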