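---
title: "Mapping cis-regulatory domains from population epigenomics: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping cis-regulatory domains from population epigenomics: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crdomics)
```

This vignette explains the statistical models behind `crdomics`, the
parameters that matter and their defaults, what the synthetic-data
generator does and does not emulate, and the design choices made where the
method description left the design genuinely open.

## The correlation model of a regulatory domain

Across a population, regulatory elements under shared control co-vary: a
cis-regulatory domain (CRD) is a set of nearby elements whose
quantifications are correlated across individuals. The pipeline assumes
phenotype matrices have been depth-normalized, residualized on technical
covariates, and rank-normal transformed (`library_size_normalize()`,
`residualize()`, `rank_normal()`), so that Pearson correlation is a
meaningful and outlier-robust measure and every downstream test is on
normal scores. The transform uses the quantile `qnorm((rank - 0.5)/n)`
with average ranks for ties: the half-offset avoids infinities and is the
common convention in QTL pipelines; ties are handled deterministically and
symmetrically. Constant phenotypes have no rank order and are rejected
rather than silently imputed.

The number of principal components to residualize away is selected by QTL
yield (`select_n_pcs()`): the matrix is corrected with an increasing
number of its own sample PCs, QTLs are mapped at each grid point, and the
smallest count maximizing the yield wins. PCs are computed once on the
uncorrected matrix rather than re-derived per grid point — the sweep then
compares nested corrections of the same rotation, which is what
"progressively corrected" means operationally.

## Domain calling

`correlation_map()` computes Pearson correlations for all same-chromosome
phenotype pairs within a 250-phenotype sliding window (index distance, not
bp). Pairs beyond the window are *untested*: they carry no correlation
value and contribute nothing to any average. `build_tree()` clusters each
chromosome with average linkage on `d = 1 - |r|` (untested pairs at
distance 1). Average linkage is robust to unbalanced block sizes; the
choice of `|r|` over signed `r` treats strong negative co-regulation as
structure rather than distance, and both are configurable (`use_abs`).

`call_crds()` walks each tree from the root and emits the first node
satisfying all of:

1. **high internal correlation** — mean `|r|` over tested within-node
   pairs at least `factor` (default 2) times the chromosome-wide mean over
   tested pairs;
2. **well-defined boundaries** — mean `|r|` over within-node pairs
   involving the genomically first or last member at least `factor` times
   the same quantity computed for the chromosome's first and last peaks;
3. **at least two distinct regions** — two members with non-overlapping
   genomic intervals (CpG probes are width-1 intervals, so a probe cluster
   inside one regulatory region fails this);
4. **coherence** — the mean `|r|` between the two child clusters the node
   merges clears the same bar as (1).

Bars (1) and (4) are floored at the *chance level*: the Fisher-z
Bonferroni bound on the largest null pair correlation given the number of
tested pairs on the chromosome (`alpha = 0.001` per chromosome,
`min_abs_r` to override). The floor and the coherence condition are this
package's operational form of requiring domains to capture genuine
correlation mass: ratio criteria alone are scale-free, so a lucky pair
among thousands of null pairs would qualify, and a node gluing two
unrelated but internally-tight blocks would pass on its pooled mean. The
floor removes the first failure mode (pure noise yields zero domains, by
construction at family-wise level alpha per chromosome); coherence removes
the second (the walk descends through incoherent merges and stops at the
blocks themselves). Both are evaluated identically by the exhaustive
all-nodes oracle in the test suite, so the recursion is tested as a
traversal, not trusted.

The chance floor assumes the sample size is large enough that real domain
correlations clear it: at `n = 500` and ~5,000 tested pairs the floor is
`|r| ~ 0.22`. Studies with far fewer individuals and weak domains should
lower `alpha` pressure by setting `min_abs_r` explicitly; the limitation
is documented rather than hidden.

**Methylation domain sizes.** CpG-based domains show a bimodal size
distribution: probe clusters within a single regulatory region (mode near
300 bp) and genuine multi-region domains (mode near 40 kb).
`fit_size_mixture()` fits a two-component Gaussian mixture on log10 span
by EM (tolerance 1e-6 on the log-likelihood, at most 500 iterations,
components labeled by mean; a collapsing variance triggers a labeled
single-component fallback with `converged = FALSE`).
`size_filter_mcrds()` keeps domains whose span strictly exceeds the 0.95
quantile of the small component, `10^(mu_small + 1.6449 sigma_small)`.

## The association engine

`crd_activity()` averages member rows per individual — a deliberate
dimensionality reduction: one test per domain instead of one per element.
`map_cis()` then runs, per phenotype: best-feature scan in a +/- 1 Mb
window (`cis_scan()`, ties to the smallest position), permutation
calibration (`permutation_adjust()`), and family-wide FDR
(`fdr_qvalue()`).

The permutation-adjusted p-value is the add-one empirical tail
`(1 + #{permutation best <= observed best}) / (1 + n_perm)` with
`n_perm = 1000`: exact at this scale, with resolution `1/(n_perm + 1)` —
the beta-approximation shortcut used by genome-scale engines is
unnecessary here and was not implemented. A consequence worth knowing:
with `m` phenotypes in a family, the smallest attainable q-value is about
`m/(n_perm + 1)`, so very large families need more permutations to call
anything at stringent FDR.

Storey q-values use the lambda-grid smoother (0.05 to 0.95 in steps of
0.05, cubic smoothing spline evaluated at 0.95). The estimator is written
in-package; `method = "bh"` gives Benjamini-Hochberg. **Family size
matters**: on families of only a handful of p-values the pi0 smoother is
unstable and can be strongly anticonservative. For this reason
`test_candidates()` — whose nominated trans-eQTL families are typically
tens of pairs — defaults to BH, while the genome-scale cis and trans
families keep Storey. `pi1()` (replication: `1 - pi0`) likewise warns
below 20 p-values.

The conditional scan (`conditional_scan()`) is the standard
forward-backward procedure: forward, add the best remaining feature while
its permutation-adjusted p on the residualized phenotype passes the
per-phenotype threshold (the largest adjusted p among FDR-significant
primaries); backward, re-test each selected feature conditioning on the
others and drop failures. Collinear selections are dropped with a message.

Slope conventions: CRD activity is the response for QTL scans, expression
is the response for gene scans; p-values are symmetric in the exchange.

## Trans networks and trans-eQTL chaining

`trans_scan()` tests all CRD pairs on distinct (autosomal) chromosomes by
correlation t-test; `trans_significant()` applies Storey FDR at 1%.
`detect_trhs()` finds communities by greedy modularity agglomeration
(Clauset-Newman-Moore via igraph) on the unweighted significant-edge
graph, with a final tie pass that keeps merging while modularity does not
decrease — without it, a member of a perfect clique can be left stranded
at zero modularity gain. Singleton communities are not hubs and are
dropped.

`enumerate_candidates()` implements the two chain scenarios (variant ->
CRD_A -> trans -> CRD_B -> gene; and variant -> eGene -> CRD_A -> trans ->
CRD_B -> gene), requiring each link significant in its source map and the
variant and gene on different chromosomes. Duplicate (variant, gene)
nominations are tested once, chains retained — testing a pair once keeps
the FDR bookkeeping honest. `test_candidates()` never tests a pair outside
the nominated set: the reduction of the search space is the method's
point. FDR is computed per scenario.

A calibration note from the package's own validation: with links at
realistic strengths (QTL explaining 20% of activity variance, trans
coupling 0.6, gene drawing 25% of its variance from the partner domain)
the induced variant-to-gene correlation is the product of the link
loadings, `sqrt(0.2) * 0.6 * sqrt(0.25) ~ 0.13` — at 200 individuals the
direct test has modest power (~0.5 nominal), so chain-based discovery at
this scale is about search-space reduction, not about guaranteed recovery
of every wired chain. The validation suite measures this honestly rather
than overstating it.

## Cross-cell-type comparison

`crd_sharing()` implements the 50% membership rule per *query* CRD against
the union of *reference* memberships, boundary inclusive. The method
description uses reversed query/reference wording in different places;
rather than guessing a single intent, the direction is explicit in the
report and `compare_cells()` emits both directions for every pair.
Sharing is by consensus phenotype id, since peaks are assumed called on a
cross-cell consensus set. `fixed_peakset_activity()` recomputes
reference-defined activities on another cell type's data so association
replication (`association_sharing()`, `pi1()`) compares like with like.

## External evidence

`pchic_support()` marks an interval pair supported when an interaction
whose fragments overlap both intervals (either orientation) has score >= 5
(`aggregate = "any"`), or mean score >= 5 over matching interactions
(`aggregate = "mean"`, used for co-expressed-pair analyses). Pairs closer
than 20 kb are excluded: short-range capture signal is dominated by
genomic-distance effects. Fragment matching is any-overlap (>= 1 bp);
promoters should be supplied as TSS +/- 2.5 kb intervals by the caller.
`tfbs_enrichment()` ranks TFBS sets by CRD-peak overlap, keeps the top 50,
and tests 2x2 tables with Fisher's exact test (Haldane 0.5 correction for
odds ratios with empty cells). `ld_matrix()` is squared dosage correlation
within 500 kb; `gwas_overlap()` accepts a QTL as GWAS-overlapping when it
or an LD proxy at r² > 0.9 has GWAS p < 1e-5. `inflation_lambda()` is the
median association chi-square over its null expectation.

## What the generator emulates — and what it does not

`simulate_population()` plants: blocks of peaks sharing a latent Gaussian
factor (`peak = sqrt(r) * factor + sqrt(1-r) * noise`, exact expected
pairwise correlation `r`); a cis-QTL per block whose loading is calibrated
so the variant explains the configured fraction of block *activity*
variance; one cis gene per block drawing the configured variance fraction
from realized activity; latent-factor couplings between blocks on
different chromosomes; and CpG domains with sizes drawn from the
two-component log10-normal mixture. Genotypes are binomial(2, f) with
f ~ Uniform(0.1, 0.5) and no LD by default. Defaults: 500 individuals, 20
blocks of 8-20 peaks at r = 0.7 on a zero-correlation background, QTL
fraction 0.2, gene fraction 0.25, coupling 0.6 across 5 block pairs —
these are the study conditions under which every validation statistic in
the test suite and the acceptance script is computed.

Real data differ in ways the generator deliberately ignores: linkage
disequilibrium (an optional proxy test uses duplicated variants instead of
haplotype structure), heavy-tailed and count-valued signal (the pipeline
rank-normalizes it away), overlapping and nested domains, batch structure
beyond linear factors, and trans effects mediated by anything other than a
shared latent factor. Green tests therefore demonstrate that the
implementation is correct under the stated model, not that the model
captures every property of population epigenomes.

Validation problem sizes (20 planted blocks at n = 500 for recovery; 50
instances of up to 64 peaks for the exhaustive-oracle equivalence; 200
null phenotypes x 1000 permutations for calibration; 50 replicates at
n = 100 for QTL power; 25 replicates at n = 200 for the trans-eQTL chain;
20 planted-partition draws for TRH recovery) were chosen as the package's
own balance between statistical resolution and a test suite that runs in
minutes.

## Numerical and degenerate-input conventions

Coordinates are 0-based half-open internally (variant positions 1-based,
VCF convention), conversions localized in the readers. Missing genotypes
are mean-imputed with a reported count — the regression engine needs
complete dosages. Zero-variance features are skipped with a warning;
zero-variance dosages drop a candidate with a message; all-zero sample
columns, constant phenotype rows, rank-deficient covariates, empty query
CRD lists and unresolvable ids are errors that name the offender. Ties:
smallest genomic position wins a best-hit tie; average ranks in the rank
transform; lexicographically smallest pair in community-merge ties. Seeds
are explicit everywhere randomness exists, and the pipeline derives
per-stage seeds from the master seed with fixed offsets so toggling one
stage never perturbs another's stream.

## Known limitations

The chance floor presumes hundreds of samples (see above). The empirical
permutation p floors at `1/(n_perm+1)`, limiting attainable q-values in
very large families. Storey's pi0 needs family sizes in the hundreds to be
trustworthy. Community detection is unweighted by default (edge weights
are retained in the output for a weighted variant). The generator's
methylation domains are used for size-distribution and domain-calling
tests, not for a full methylation QTL analysis. No colocalization,
fine-mapping, or read-level simulation is attempted.
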