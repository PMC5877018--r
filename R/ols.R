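#' Refit a selected set of columns by ordinary least squares
#'
#' Used both for the OLS refits that attach approximate p-values and AIC to a
#' path-selected covariate set, and for arbitrary term sets. On fully
#' standardized inputs the model has no intercept (`intercept = FALSE`, the
#' default); interaction models on the raw outcome keep one.
#'
#' @param design a `candidate_design` (standardized or not).
#' @param outcome numeric outcome vector.
#' @param terms character vector of design column names to fit.
#' @param intercept logical; include an intercept term.
#' @return Object of class `ss_fit`: coefficient table (`term`, `concept`,
#'   `scale`, `estimate`, `se`, `p`, `mark`), with `aic` in the [ols_aic()]
#'   convention, `rss`, `n`, `k` (number of coefficients incl. intercept),
#'   and `residuals`.
#' @export
refit_ols <- function(design, outcome, terms, intercept = FALSE) {
  stopifnot(inherits(design, "candidate_design"),
            length(outcome) == nrow(design$X))
  miss <- setdiff(terms, colnames(design$X))
  if (length(miss)) stop("unknown term(s): ", paste(miss, collapse = ", "))
  X <- design$X[, terms, drop = FALSE]
  if (intercept) X <- cbind(`(Intercept)` = 1, X)
  n <- nrow(X); k <- ncol(X)
  if (n <= k) stop("more coefficients than observations")
  qx <- qr(X)
  if (qx$rank < k) {
    dep <- colnames(X)[qx$pivot[(qx$rank + 1L):k]]
    stop("collinear term(s): ", paste(dep, collapse = ", "))
  }
  b <- qr.coef(qx, outcome)
  res <- outcome - drop(X %*% b)
  rss <- sum(res^2)
  df <- n - k
  sigma2 <- rss / df
  XtX_inv <- chol2inv(qr.R(qx))[order(qx$pivot), order(qx$pivot), drop = FALSE]
  se <- sqrt(sigma2 * diag(XtX_inv))
  tval <- b / se
  pval <- 2 * stats::pt(-abs(tval), df)
  idx <- match(colnames(X), design$info$column)
  tab <- data.frame(term = colnames(X),
                    concept = ifelse(is.na(idx), colnames(X),
                                     design$info$concept[idx]),
                    scale = ifelse(is.na(idx), NA_character_,
                                   design$info$scale[idx]),
                    estimate = unname(b), se = unname(se), p = unname(pval),
                    mark = p_mark(pval), row.names = NULL)
  structure(list(coefficients = tab, rss = rss, n = n, k = k,
                 aic = suppressWarnings(ols_aic(rss, n, k)),
                 intercept = intercept, residuals = res,
                 terms = terms), class = "ss_fit")
}

# significance marks used throughout the report tables
p_mark <- function(p) ifelse(p < 0.05, "*", ifelse(p < 0.1, "+", ""))

#' @export
print.ss_fit <- function(x, digits = 4, ...) {
  cat("OLS fit: n = ", x$n, ", k = ", x$k,
      ", AIC = ", format(x$aic, digits = 8), "\n", sep = "")
  tab <- x$coefficients
  tab$estimate <- round(tab$estimate, digits)
  tab$se <- round(tab$se, digits)
  tab$p <- signif(tab$p, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.ss_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
summary.ss_fit <- function(object, ...) object

#' Refit a selected model with all area-level terms at one scale
#'
#' The single-scale comparison fits: every area-level term of a selected
#' model is swapped to its sibling column at the requested scale (individual
#' terms are unchanged) and the model refit by OLS. Comparing the AIC of the
#' CBG-constrained, CT-constrained, and model-selected fits measures what
#' scale selection buys.
#'
#' @param selected an `ss_model` (see [selected_model()]).
#' @param design the standardized `candidate_design` used for selection.
#' @param outcome the standardized outcome.
#' @param scale `"CBG"` or `"CT"`, or `NULL` to keep the model-selected
#'   scales.
#' @param intercept passed to [refit_ols()].
#' @return An `ss_fit`.
#' @export
constrained_scale_refit <- function(selected, design, outcome, scale = NULL,
                                    intercept = FALSE) {
  stopifnot(inherits(selected, "ss_model"))
  info <- design$info
  terms <- selected$columns
  if (!is.null(scale)) {
    scale <- match.arg(scale, c("CBK", "CBG", "CT"))
    i <- match(terms, info$column)
    terms <- vapply(seq_along(terms), function(j) {
      sc <- info$scale[i[j]]
      if (sc == "individual") return(terms[j])
      cn <- info$concept[i[j]]
      sib <- info$column[info$concept == cn & info$scale == scale]
      if (!length(sib))
        stop("concept '", cn, "' has no column at scale ", scale)
      sib
    }, character(1))
  }
  refit_ols(design, outcome, terms, intercept = intercept)
}

#' Percent change between two effect magnitudes
#'
#' The effect-comparison statistic reported between single-scale and
#' scale-selected models: `100 * (|b| - |a|) / |a|`, rounded to the nearest
#' integer percent.
#'
#' @param coef_a reference coefficient (must be nonzero).
#' @param coef_b comparison coefficient.
#' @return integer percent; `NA` when `coef_a` is zero.
#' @export
percent_change <- function(coef_a, coef_b) {
  if (coef_a == 0) return(NA_integer_)
  as.integer(round(100 * (abs(coef_b) - abs(coef_a)) / abs(coef_a)))
}
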