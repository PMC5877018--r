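#' OLS-based AIC from a residual sum of squares
#'
#' The profiled Gaussian AIC used to compare active sets along a selection
#' path: `n * log(rss / n) + 2 * (k + 1)`, where `k` is the number of
#' regression coefficients and the residual variance counts as one further
#' parameter. Additive constants (`n log(2*pi) + n`) that do not depend on
#' the active set are omitted; this matches `stats::AIC` on the same fit up
#' to that constant. All within-path and between-path comparisons in this
#' package use the same convention, so the constant never matters.
#'
#' @param rss residual sum of squares.
#' @param n number of observations.
#' @param k number of estimated regression coefficients (excluding the
#'   residual variance; including the intercept if one is fit).
#' @return AIC value; `-Inf` with a warning when `rss == 0`.
#' @export
ols_aic <- function(rss, n, k) {
  stopifnot(n > k, rss >= 0)
  if (rss == 0) {
    warning("zero residual sum of squares; AIC is -Inf")
    return(-Inf)
  }
  n * log(rss / n) + 2 * (k + 1)
}

# Full-likelihood Gaussian AIC on the same fit, comparable with lme4 ML AIC.
full_gaussian_aic <- function(rss, n, k) {
  ols_aic(rss, n, k) + n * (log(2 * pi) + 1)
}
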