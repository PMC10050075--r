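#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the domain-size mixture fit
#'
#' One row per component with mean, standard deviation (log10 bp) and
#' mixing weight.
#'
#' @param x A [fit_size_mixture()] result.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.crd_size_mixture <- function(x, ...) {
  tibble(
    component = c("small", "large"),
    mean_log10 = c(x$mu_small, x$mu_large),
    sd_log10 = c(x$sigma_small, x$sigma_large),
    weight = c(x$weight_small, 1 - x$weight_small)
  )
}

#' Glance at the domain-size mixture fit
#'
#' @param x A [fit_size_mixture()] result.
#' @param ... Unused.
#' @return One-row tibble with log-likelihood, convergence flag, sample size
#'   and the size threshold in bp.
#' @export
glance.crd_size_mixture <- function(x, ...) {
  tibble(logLik = x$loglik, converged = x$converged, nobs = x$n,
         size_threshold_bp = x$size_threshold_bp)
}

#' Tidy a CRD table into one row per member phenotype
#'
#' @param x CRD tibble from [call_crds()].
#' @param ... Unused.
#' @return A tibble with one row per (crd_id, phenotype_id).
#' @export
tidy_crd_members <- function(x, ...) {
  tibble(crd_id = rep(x$crd_id, lengths(x$members)),
         phenotype_id = unlist(x$members))
}
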