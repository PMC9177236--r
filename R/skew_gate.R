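# Per-subject non-Gaussianity gate: the pairwise orientation stage is only
# valid on skewed data, so each subject's parcel skewness is compared to
# Gaussian surrogates before orientation is allowed.

#' Sample skewness (moment form)
#'
#' `m3 / m2^(3/2)` with biased central sample moments. The gate compares
#' skewness magnitudes of equal-length series by rank, so the shared
#' small-sample bias factor cancels and the plain moment estimator is used.
#'
#' @param series numeric vector, length >= 3, non-constant.
#' @return Scalar skewness.
#' @export
#' @examples
#' sample_skewness(c(1, -1, 1, -1, 1, -1)) # symmetric: 0
sample_skewness <- function(series) {
  n <- length(series)
  if (n < 3) stopf("need at least 3 observations, got %d", n)
  d <- series - mean(series)
  m2 <- mean(d^2)
  if (m2 == 0) stopf("constant series: skewness undefined")
  mean(d^3) / m2^1.5
}

#' Gate a subject's data on significant skewness
#'
#' Computes |skewness| for each of the `p` observed parcel series and for
#' `p` freshly drawn Gaussian surrogate series of identical length, then
#' applies a one-tailed Wilcoxon rank-sum test of observed > surrogate.
#' The subject passes the gate (and may proceed to skew-based orientation)
#' when the test rejects at `alpha`. Absolute values are used because both
#' signs of skewness carry orientation information.
#'
#' Parcels with zero variance cannot contribute a skewness value; they are
#' excluded from the test with a warning (their surrogate partners are kept,
#' keeping the surrogate sample at `p`).
#'
#' @param ts samples x parcels numeric matrix.
#' @param alpha significance level (default 0.05).
#' @param seed integer seed for the surrogate draw.
#' @return An object of class `gango_gate`: list with
#'   `per_parcel_abs_skewness`, `surrogate_abs_skewness`, `statistic`
#'   (rank-sum W), `p_value`, `passed`, `alpha`, `n_excluded`.
#' @export
gate_subject <- function(ts, alpha = 0.05, seed = 1L) {
  ts <- as.matrix(ts)
  p <- ncol(ts)
  n <- nrow(ts)
  if (p < 2) stopf("need at least 2 parcels, got %d", p)
  degenerate <- apply(ts, 2, function(col) var(col) == 0)
  if (any(degenerate)) {
    warnf("excluding %d zero-variance parcel(s) from the skewness gate: %s",
          sum(degenerate), paste(which(degenerate), collapse = ", "))
  }
  obs <- abs(apply(ts[, !degenerate, drop = FALSE], 2, sample_skewness))
  surr_mat <- gaussian_surrogates(p, n, seed = seed)
  surr <- abs(apply(surr_mat, 2, sample_skewness))
  wt <- wilcox.test(obs, surr, alternative = "greater", exact = FALSE)
  structure(
    list(per_parcel_abs_skewness = obs,
         surrogate_abs_skewness = surr,
         statistic = unname(wt$statistic),
         p_value = wt$p.value,
         passed = wt$p.value < alpha,
         alpha = alpha,
         n_excluded = sum(degenerate)),
    class = "gango_gate")
}

#' @export
print.gango_gate <- function(x, ...) {
  cat(sprintf(
    "Non-Gaussianity gate: W = %.1f, p = %.3g, %s (alpha = %g, %d parcel(s) excluded)\n",
    x$statistic, x$p_value, if (x$passed) "PASSED" else "FAILED",
    x$alpha, x$n_excluded))
  invisible(x)
}
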