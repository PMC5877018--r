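#' Random-intercept linear mixed model at census scales
#'
#' Fits the selected fixed effects together with a Gaussian random intercept
#' at the block-group level, the tract level, or both (block groups nested in
#' tracts), by maximum likelihood (ML, not REML) so that AIC values are
#' comparable across fixed-effect sets. Fixed-effect p-values are Wald z
#' tests; group intercepts are the conditional modes (EBLUPs).
#'
#' @param design a `candidate_design` carrying `cbg_id` / `ct_id` in its
#'   `ids` element.
#' @param outcome numeric outcome vector.
#' @param terms design columns to use as fixed effects.
#' @param re one of `"CBG"`, `"CT"`, `"both"`.
#' @param intercept logical; include a fixed intercept.
#' @return Object of class `ss_mixed`: coefficient table as in [refit_ols()],
#'   `varcomp` (named vector: `sigma2_CBG` and/or `sigma2_CT`,
#'   `sigma2_resid`), `loglik`, `aic` (full-likelihood,
#'   `-2 logLik + 2 npar`), `ranef` (data.frame unit, scale, intercept), and
#'   the underlying `lme4` fit.
#' @export
fit_random_intercept <- function(design, outcome, terms,
                                 re = c("CBG", "CT", "both"),
                                 intercept = FALSE) {
  re <- match.arg(re)
  stopifnot(inherits(design, "candidate_design"))
  ids <- design$ids
  if (re %in% c("CBG", "both") && is.null(ids$cbg_id))
    stop("design carries no cbg_id")
  if (re %in% c("CT", "both") && is.null(ids$ct_id))
    stop("design carries no ct_id")
  if (re == "both") {
    tab <- unique(data.frame(cbg = ids$cbg_id, ct = ids$ct_id))
    if (anyDuplicated(tab$cbg))
      stop("block groups are not nested within tracts; ",
           "nested random intercepts require a strict hierarchy")
  }
  miss <- setdiff(terms, colnames(design$X))
  if (length(miss)) stop("unknown term(s): ", paste(miss, collapse = ", "))
  dat <- as.data.frame(design$X[, terms, drop = FALSE])
  names(dat) <- paste0("x", seq_along(terms))  # safe names
  dat$.y <- outcome
  if (!is.null(ids$cbg_id)) dat$.cbg <- factor(ids$cbg_id)
  if (!is.null(ids$ct_id)) dat$.ct <- factor(ids$ct_id)
  fe <- paste(c(if (!intercept) "0", names(dat)[seq_along(terms)]),
              collapse = " + ")
  re_part <- switch(re,
                    CBG = "(1 | .cbg)",
                    CT = "(1 | .ct)",
                    both = "(1 | .cbg) + (1 | .ct)")
  form <- stats::as.formula(paste(".y ~", fe, "+", re_part))
  fit <- lme4::lmer(form, data = dat, REML = FALSE,
                    control = lme4::lmerControl(calc.derivs = FALSE,
                                                check.conv.singular = "ignore"))
  b <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- b / se
  p <- 2 * stats::pnorm(-abs(z))
  term_names <- c(if (intercept) "(Intercept)", terms)
  idx <- match(term_names, design$info$column)
  tab <- data.frame(term = term_names,
                    concept = ifelse(is.na(idx), term_names,
                                     design$info$concept[idx]),
                    scale = ifelse(is.na(idx), NA_character_,
                                   design$info$scale[idx]),
                    estimate = unname(b), se = unname(se), p = unname(p),
                    mark = p_mark(p), row.names = NULL)
  vc <- as.data.frame(lme4::VarCorr(fit))
  varcomp <- c(
    if (re %in% c("CBG", "both"))
      stats::setNames(vc$vcov[vc$grp == ".cbg"], "sigma2_CBG"),
    if (re %in% c("CT", "both"))
      stats::setNames(vc$vcov[vc$grp == ".ct"], "sigma2_CT"),
    stats::setNames(vc$vcov[vc$grp == "Residual"], "sigma2_resid"))
  rf <- lme4::ranef(fit)
  ranef_tab <- do.call(rbind, lapply(names(rf), function(g) {
    data.frame(unit = rownames(rf[[g]]),
               scale = if (g == ".cbg") "CBG" else "CT",
               intercept = rf[[g]][["(Intercept)"]])
  }))
  structure(list(coefficients = tab, varcomp = varcomp,
                 loglik = as.numeric(stats::logLik(fit)),
                 aic = stats::AIC(fit), re = re, n = nrow(dat),
                 ranef = ranef_tab, fit = fit), class = "ss_mixed")
}

#' @export
print.ss_mixed <- function(x, digits = 4, ...) {
  cat("Random-intercept model (ML), RE at ", x$re,
      ": n = ", x$n, ", AIC = ", format(x$aic, digits = 8), "\n", sep = "")
  cat("Variance components:\n")
  print(round(x$varcomp, 5))
  tab <- x$coefficients
  tab$estimate <- round(tab$estimate, digits)
  tab$se <- round(tab$se, digits)
  tab$p <- signif(tab$p, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.ss_mixed <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' Compare random-effect placements by AIC
#'
#' Fits the same fixed-effect set under four specifications — no random
#' effect, a random intercept at the block group, at the tract, and at both
#' (nested) — and tabulates full-likelihood AIC values. The no-RE row is an
#' OLS fit; all AICs share the `-2 logLik + 2 npar` convention so the four
#' rows are directly comparable.
#'
#' @inheritParams fit_random_intercept
#' @return list with `table` (data.frame: `re`, `aic`, `loglik`, `npar`) and
#'   `fits` (named list of the four fitted objects).
#' @export
compare_re_specs <- function(design, outcome, terms, intercept = FALSE) {
  ols <- refit_ols(design, outcome, terms, intercept = intercept)
  fits <- list(none = ols)
  rows <- data.frame(re = "none",
                     aic = full_gaussian_aic(ols$rss, ols$n, ols$k),
                     loglik = -(full_gaussian_aic(ols$rss, ols$n, ols$k) -
                                  2 * (ols$k + 1)) / 2,
                     npar = ols$k + 1)
  for (re in c("CBG", "CT", "both")) {
    m <- fit_random_intercept(design, outcome, terms, re = re,
                              intercept = intercept)
    fits[[re]] <- m
    npar <- length(m$coefficients$term) + length(m$varcomp)
    rows <- rbind(rows, data.frame(re = re, aic = m$aic, loglik = m$loglik,
                                   npar = npar))
  }
  list(table = rows, fits = fits)
}
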