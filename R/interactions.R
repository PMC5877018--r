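#' Clinician-specified interaction pairs
#'
#' The default specification is the nine pairs examined in the pediatric BMI
#' analysis: sex (male) crossed with population density, median household
#' income, park density, and exercise-equipment expenditures; race (black)
#' crossed with the same four; and distance to the medical center crossed
#' with median household income. Pairs are declared at the concept level and
#' resolved to concrete design columns (at each concept's present scale) by
#' [resolve_interactions()].
#'
#' @param modifier,base character vectors (recycled pairwise) of concept
#'   names.
#' @return data.frame of class `interaction_spec` with columns `modifier`,
#'   `base`.
#' @export
interaction_spec <- function(
    modifier = c(rep("male", 4), rep("black", 4), "mcvdist"),
    base = c(rep(c("popdens", "medhinc", "parkdens", "ex_eq"), 2),
             "medhinc")) {
  out <- data.frame(modifier = modifier, base = base)
  class(out) <- c("interaction_spec", "data.frame")
  out
}

#' Resolve concept-level interaction pairs to design columns
#'
#' Each pair's concepts are mapped to the columns present in the working
#' design. If a concept appears at several scales in the design, `fallback`
#' decides which is used (default the tract scale, the largest).
#'
#' @param design a `candidate_design`.
#' @param spec an [interaction_spec()].
#' @param fallback scale preference order when a concept has several columns.
#' @return data.frame with columns `modifier`, `base`, `modifier_col`,
#'   `base_col`.
#' @export
resolve_interactions <- function(design, spec = interaction_spec(),
                                 fallback = c("CT", "CBG", "CBK")) {
  info <- design$info
  pick <- function(concept) {
    cols <- info[info$concept == concept, , drop = FALSE]
    if (!nrow(cols)) stop("concept '", concept, "' absent from design")
    if (nrow(cols) == 1L) return(cols$column)
    for (sc in c("individual", fallback))
      if (sc %in% cols$scale) return(cols$column[cols$scale == sc][1L])
    cols$column[1L]
  }
  spec$modifier_col <- vapply(spec$modifier, pick, character(1))
  spec$base_col <- vapply(spec$base, pick, character(1))
  spec
}

#' Append product columns for interaction terms
#'
#' Builds interaction columns as elementwise products of already-rescaled
#' parent columns. The design must be on the Gelman scale (binaries centered,
#' continuous columns divided by two SDs) so products are comparable across
#' pairs; the products themselves are not re-rescaled, and parent columns are
#' left untouched.
#'
#' @param design a Gelman-rescaled `candidate_design`.
#' @param resolved output of [resolve_interactions()] (or a data.frame with
#'   `modifier_col`, `base_col`).
#' @return A `candidate_design` with one extra column per pair, named
#'   `modifier:base`.
#' @export
build_interaction_design <- function(design, resolved) {
  stopifnot(inherits(design, "candidate_design"))
  if (!identical(attr(design, "standardized"), "gelman"))
    stop("interaction designs are built on Gelman-rescaled inputs; ",
         "call standardize_gelman() first")
  miss <- setdiff(unique(c(resolved$modifier_col, resolved$base_col)),
                  colnames(design$X))
  if (length(miss))
    stop("interaction parent(s) absent from design: ",
         paste(miss, collapse = ", "))
  out <- design
  base_scale <- design$info$scale[match(resolved$base_col,
                                        design$info$column)]
  for (i in seq_len(nrow(resolved))) {
    nm <- paste(resolved$modifier_col[i], resolved$base_col[i], sep = ":")
    prod_col <- design$X[, resolved$modifier_col[i]] *
      design$X[, resolved$base_col[i]]
    out$X <- cbind(out$X, prod_col)
    colnames(out$X)[ncol(out$X)] <- nm
    out$info <- rbind(out$info, data.frame(
      column = nm, concept = nm, scale = base_scale[i],
      number = max(design$info$number) + i))
  }
  out
}

#' Keep only the significant interaction terms
#'
#' A single pruning pass: interaction pairs whose product-term p-value in the
#' full fit is below `alpha` are retained; main effects are never pruned.
#'
#' @param fit an `ss_fit` containing all the spec's product terms.
#' @param resolved the resolved interaction spec the fit was built from.
#' @param alpha significance threshold (default 0.05).
#' @return The rows of `resolved` whose product term is significant.
#' @export
prune_to_significant <- function(fit, resolved, alpha = 0.05) {
  stopifnot(inherits(fit, "ss_fit"))
  nm <- paste(resolved$modifier_col, resolved$base_col, sep = ":")
  i <- match(nm, fit$coefficients$term)
  if (anyNA(i))
    stop("fit lacks interaction term(s): ",
         paste(nm[is.na(i)], collapse = ", "))
  resolved[fit$coefficients$p[i] < alpha, , drop = FALSE]
}

#' Fit the final interaction models, with and without random effects
#'
#' Builds the interaction design from the retained pairs, fits an OLS model
#' (raw outcome, with intercept) and the three random-intercept variants, and
#' tabulates their AIC values.
#'
#' @param design a Gelman-rescaled `candidate_design` restricted to the main
#'   effects of interest.
#' @param outcome raw (unstandardized) outcome vector.
#' @param resolved retained interaction pairs (see [prune_to_significant()]).
#' @param re_specs which random-effect placements to fit besides `"none"`.
#' @return list with `fits` (named by RE spec), `aic_table` (data.frame
#'   `re`, `aic`), and the extended `design`.
#' @export
final_interaction_models <- function(design, outcome, resolved,
                                     re_specs = c("CBG", "CT", "both")) {
  ext <- if (nrow(resolved)) build_interaction_design(design, resolved)
  else design
  terms <- colnames(ext$X)
  cmp <- compare_re_specs(ext, outcome, terms, intercept = TRUE)
  keep <- cmp$table$re %in% c("none", re_specs)
  list(fits = cmp$fits[keep], aic_table = cmp$table[keep, c("re", "aic")],
       design = ext)
}
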