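#' Storey's pi0 estimate
#'
#' The proportion of true nulls, estimated on the lambda grid
#' 0.05, 0.10, ..., 0.95 with a cubic smoothing spline evaluated at the
#' largest lambda, clipped to (0, 1].
#'
#' @param p P-values in `[0, 1]`.
#' @param lambda Tuning grid.
#' @return Scalar pi0.
#' @export
storey_pi0 <- function(p, lambda = seq(0.05, 0.95, by = 0.05)) {
  stopifnot(all(p >= 0 & p <= 1))
  pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  if (length(lambda) >= 4) {
    fit <- smooth.spline(lambda, pi0_l, df = 3)
    pi0 <- predict(fit, x = max(lambda))$y
  } else {
    pi0 <- min(pi0_l)
  }
  min(max(pi0, 1e-8), 1)
}

#' Q-values and significance calls for a family of p-values
#'
#' `method = "storey"` computes q-values with the smoother pi0 estimate
#' ([storey_pi0()]); `method = "bh"` is Benjamini-Hochberg (pi0 fixed at 1).
#' Q-values are monotone in the p-values.
#'
#' @param p P-values.
#' @param method `"storey"` or `"bh"`.
#' @param level FDR level for the significance flags.
#' @return Tibble `p`, `q_value`, `significant`, with the pi0 estimate as
#'   attribute `"pi0"` (rows in input order). Empty input gives an empty
#'   tibble.
#' @export
fdr_qvalue <- function(p, method = c("storey", "bh"), level = 0.05) {
  method <- match.arg(method)
  if (!length(p)) {
    out <- tibble(p = numeric(), q_value = numeric(), significant = logical())
    attr(out, "pi0") <- NA_real_
    return(out)
  }
  stopifnot(all(p >= 0 & p <= 1))
  m <- length(p)
  pi0 <- if (method == "storey") storey_pi0(p) else 1
  ord <- order(p)
  q_sorted <- pi0 * m * p[ord] / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[ord] <- q_sorted
  out <- tibble(p = p, q_value = q, significant = q <= level)
  attr(out, "pi0") <- pi0
  out
}
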