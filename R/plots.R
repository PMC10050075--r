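#' @importFrom ggplot2 ggplot aes geom_histogram geom_line geom_point
#'   geom_abline geom_col labs theme_minimal after_stat stat_function
#'   scale_x_log10 facet_wrap autoplot
NULL

#' @export
ggplot2::autoplot

#' Plot the fitted domain-size mixture over the size histogram
#'
#' @param object A [fit_size_mixture()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.crd_size_mixture <- function(object, ...) {
  df <- tibble(log10_size = object$log10_sizes)
  p <- ggplot(df, aes(x = .data$log10_size)) +
    geom_histogram(aes(y = after_stat(.data$density)), bins = 40,
                   fill = "grey80", colour = "grey50") +
    stat_function(fun = function(x) {
      object$weight_small * dnorm(x, object$mu_small, object$sigma_small) +
        (1 - object$weight_small) * dnorm(x, object$mu_large, object$sigma_large)
    }, colour = "firebrick", linewidth = 1) +
    ggplot2::geom_vline(xintercept = log10(object$size_threshold_bp),
                        linetype = "dashed") +
    labs(x = "log10 domain size (bp)", y = "density",
         title = "Domain size mixture",
         subtitle = sprintf("size threshold = %.0f bp (0.95 quantile of small component)",
                            object$size_threshold_bp)) +
    theme_minimal()
  p
}

#' QQ plot of association p-values with the genomic inflation factor
#'
#' @param p P-values in `(0, 1]`.
#' @return A ggplot of -log10 expected vs observed quantiles, annotated with
#'   lambda.
#' @export
plot_qq <- function(p) {
  lambda <- inflation_lambda(p)
  qq <- attr(lambda, "qq")
  ggplot(qq, aes(x = .data$expected, y = .data$observed)) +
    geom_point(size = 0.8, alpha = 0.6) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    labs(x = expression(-log[10] * " expected p"),
         y = expression(-log[10] * " observed p"),
         title = sprintf("QQ plot (lambda = %.3f)", as.numeric(lambda))) +
    theme_minimal()
}

#' Plot a PCHi-C support curve over distance bins
#'
#' @param curve Output of [pchic_support()] (optionally row-bound over
#'   several association classes with a `class` column).
#' @return A ggplot of support fraction per distance bin.
#' @export
plot_support_curve <- function(curve) {
  curve$bin_mid <- sqrt(curve$bin_lo * curve$bin_hi)
  p <- ggplot(curve, aes(x = .data$bin_mid, y = .data$fraction)) +
    geom_line() + geom_point() +
    scale_x_log10(labels = function(x) paste0(x / 1000, " kb")) +
    labs(x = "pair distance", y = "fraction supported (score >= 5)",
         title = "PCHi-C support by distance") +
    theme_minimal()
  if ("class" %in% names(curve)) p <- p + aes(colour = .data$class)
  p
}

#' Plot the degree distribution of a trans CRD network
#'
#' @param edges Significant trans edge tibble.
#' @param trhs TRH membership tibble.
#' @return A ggplot histogram of per-CRD trans degrees.
#' @export
plot_trans_degrees <- function(edges, trhs) {
  ns <- network_summary(edges, trhs)
  ggplot(ns$degrees, aes(x = .data$degree)) +
    geom_histogram(binwidth = 1, fill = "grey70", colour = "grey40") +
    labs(x = "trans associations per CRD", y = "CRDs",
         title = "Trans network degree distribution") +
    theme_minimal()
}
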