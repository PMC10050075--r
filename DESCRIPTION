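Package: crdomics
Title: Cis-Regulatory Domain Mapping from Population Epigenomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Calls cis-regulatory domains (CRDs) from population-scale
    chromatin and methylation quantification matrices by hierarchical
    clustering of inter-individual correlation, quantifies per-individual
    CRD activity, maps cis CRD-gene and CRD-QTL associations with
    permutation-adjusted p-values and false discovery rate control, builds
    inter-chromosomal CRD association networks and detects trans-regulatory
    hubs by community detection, compares CRD maps and associations across
    cell types (sharing fractions and Storey's pi1), integrates external
    evidence (promoter-capture Hi-C support, transcription-factor binding
    site enrichment, GWAS overlap through local linkage disequilibrium),
    and chains cis and trans maps into candidate trans-eQTLs. Includes a
    synthetic-data generator with planted ground truth so that every stage
    is testable without controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stats,
    utils,
    igraph,
    ggplot2,
    readr,
    yaml,
    jsonlite,
    digest,
    generics
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
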