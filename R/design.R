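#' Declare which covariate concepts are available at which scales
#'
#' A variable specification lists every candidate column for scale selection:
#' one row per (concept, scale) pair. Individual-level covariates carry scale
#' `"individual"`; area-level concepts list each census scale at which the
#' concept is observed. Variable numbers give a deterministic column order and
#' are used to break ties in the selection algorithms.
#'
#' @param individual character vector of individual-level covariate names
#'   (columns of the cohort table).
#' @param area named list: concept name -> character vector of scales, each in
#'   `c("CBK", "CBG", "CT")`.
#'
#' @return data.frame with columns `number`, `concept`, `scale`, `column`,
#'   class `c("variable_spec", "data.frame")`. `column` is the design column
#'   name: the concept itself for individual variables, `concept_scale`
#'   otherwise.
#' @export
variable_spec <- function(individual = character(), area = list()) {
  rows <- list()
  for (v in individual)
    rows[[length(rows) + 1L]] <- data.frame(concept = v, scale = "individual",
                                            column = v)
  for (cn in names(area)) {
    sc <- match.arg(area[[cn]], c("CBK", "CBG", "CT"), several.ok = TRUE)
    for (s in sc)
      rows[[length(rows) + 1L]] <- data.frame(concept = cn, scale = s,
                                              column = paste(cn, s, sep = "_"))
  }
  out <- do.call(rbind, rows)
  if (anyDuplicated(out[, c("concept", "scale")]))
    stop("a (concept, scale) pair is declared more than once")
  out <- cbind(number = seq_len(nrow(out)), out)
  class(out) <- c("variable_spec", "data.frame")
  out
}

#' The full 31-column candidate pool of the pediatric BMI study
#'
#' Four individual-level covariates plus thirteen area-level concepts:
#' population density at three census scales (block, block group, tract) and
#' twelve further concepts at block-group and tract scales, for 31 candidate
#' columns spanning 17 concepts.
#'
#' @return A [variable_spec()] with 31 rows.
#' @export
table1_spec <- function() {
  two <- c("CBG", "CT")
  variable_spec(
    individual = c("visitage", "male", "black", "mcvdist"),
    area = list(
      popdens = c("CBK", "CBG", "CT"),
      pblack = two, phwhite = two, phblack = two,
      medhinc = two, prenter = two, pvacant = two,
      crmcytotc = two, crmcyperc = two, crmcyproc = two,
      parkdens = two, restdens = two, ex_eq = two))
}

#' Assemble the multi-scale candidate design matrix
#'
#' Joins each cohort row to its area unit's covariate value at every declared
#' scale, producing the expanded predictor matrix on which the scale-selection
#' algorithms run. Column metadata records the concept and scale of every
#' column, so that sibling columns (same concept, different scale) can be
#' recognised by the selection constraint.
#'
#' @param cohort cohort data.frame (see [generate_cohort()] for the expected
#'   columns); must carry `cbk_id`, `cbg_id`, `ct_id`.
#' @param area_tables named list of per-scale covariate tables
#'   (`list(CBK = , CBG = , CT = )`, any subset); each a data.frame with a
#'   `unit_id` column and one numeric column per concept.
#' @param spec a [variable_spec()].
#'
#' @return Object of class `candidate_design`: list with elements
#'   `X` (n x p numeric matrix), `info` (per-column metadata: `column`,
#'   `concept`, `scale`, `number`), and `ids` (the cohort's geography
#'   identifier columns, kept for mixed-model grouping).
#' @export
build_candidate_design <- function(cohort, area_tables, spec) {
  stopifnot(inherits(spec, "variable_spec"), nrow(cohort) > 0L)
  id_col <- c(CBK = "cbk_id", CBG = "cbg_id", CT = "ct_id")
  need <- setdiff(unique(spec$scale), "individual")
  miss <- setdiff(need, names(area_tables))
  if (length(miss))
    stop("no area covariate table for scale(s): ", paste(miss, collapse = ", "))

  X <- matrix(NA_real_, nrow(cohort), nrow(spec),
              dimnames = list(NULL, spec$column))
  for (i in seq_len(nrow(spec))) {
    cn <- spec$concept[i]; sc <- spec$scale[i]
    if (sc == "individual") {
      if (is.null(cohort[[cn]]))
        stop("individual variable '", cn, "' absent from cohort")
      X[, i] <- as.numeric(cohort[[cn]])
    } else {
      tab <- area_tables[[sc]]
      if (is.null(tab$unit_id)) stop("area table for ", sc, " lacks unit_id")
      if (is.null(tab[[cn]]))
        stop("concept '", cn, "' absent from the ", sc, " area table")
      idx <- match(as.character(cohort[[id_col[[sc]]]]),
                   as.character(tab$unit_id))
      if (anyNA(idx)) {
        missing_unit <- unique(cohort[[id_col[[sc]]]][is.na(idx)])
        stop("unit(s) missing from the ", sc, " area table: ",
             paste(utils::head(missing_unit, 5L), collapse = ", "))
      }
      X[, i] <- tab[[cn]][idx]
    }
  }
  structure(list(X = X,
                 info = as.data.frame(spec)[, c("column", "concept", "scale",
                                                "number")],
                 ids = cohort[intersect(names(cohort),
                                        c("cbk_id", "cbg_id", "ct_id"))]),
            class = "candidate_design")
}

#' @export
print.candidate_design <- function(x, ...) {
  cat("Candidate design:", nrow(x$X), "rows x", ncol(x$X), "columns\n")
  cat("  concepts:", length(unique(x$info$concept)), "\n")
  tab <- table(x$info$scale)
  cat("  columns per scale:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  if (!is.null(attr(x, "standardized")))
    cat("  standardization:", attr(x, "standardized"), "\n")
  invisible(x)
}

#' @export
dim.candidate_design <- function(x) dim(x$X)

sample_sd <- function(x) stats::sd(x)  # denominator n - 1 throughout

#' Standardize design and outcome to mean zero, unit SD
#'
#' Both the outcome and every predictor column are centered and divided by
#' their sample standard deviation (denominator n - 1). With all variables on
#' this scale the regression has no intercept term, which is the form the
#' path algorithms (in particular the lasso) operate on.
#'
#' @param design a `candidate_design`.
#' @param outcome numeric outcome vector, length `nrow(design$X)`.
#' @return list with `design` (standardized copy), `outcome` (standardized),
#'   and `recipe` (a `std_recipe` sufficient to invert the transform).
#' @export
standardize_full <- function(design, outcome) {
  stopifnot(inherits(design, "candidate_design"),
            length(outcome) == nrow(design$X))
  ctr <- colMeans(design$X)
  sds <- apply(design$X, 2L, sample_sd)
  zero <- which(sds == 0 | !is.finite(sds))
  if (length(zero))
    stop("zero-variance column(s): ",
         paste(colnames(design$X)[zero], collapse = ", "))
  out <- design
  out$X <- sweep(sweep(design$X, 2L, ctr), 2L, sds, "/")
  attr(out, "standardized") <- "full"
  y_ctr <- mean(outcome); y_sd <- sample_sd(outcome)
  if (y_sd == 0) stop("outcome has zero variance")
  recipe <- structure(list(
    columns = data.frame(column = colnames(design$X), center = ctr,
                         divisor = sds, row.names = NULL),
    outcome = list(center = y_ctr, divisor = y_sd),
    scheme = "full"), class = "std_recipe")
  list(design = out, outcome = (outcome - y_ctr) / y_sd, recipe = recipe)
}

#' Rescale predictors by centering and two standard deviations
#'
#' The rescaling used for interaction models: dummy (binary 0/1) predictors
#' are centered only, and continuous predictors are centered and divided by
#' two standard deviations, so that binary and continuous coefficients are on
#' a comparable "low value to high value" scale. The outcome is left raw and
#' the model keeps its intercept.
#'
#' @param design a `candidate_design`.
#' @param binary character vector of column names to treat as dummies;
#'   `NULL` (default) auto-detects columns whose values are exactly {0, 1}.
#' @return list with `design` (rescaled copy) and `recipe`.
#' @export
standardize_gelman <- function(design, binary = NULL) {
  stopifnot(inherits(design, "candidate_design"))
  X <- design$X
  if (is.null(binary)) {
    is_bin <- apply(X, 2L, function(v) all(v %in% c(0, 1)) &&
                      length(unique(v)) == 2L)
    binary <- colnames(X)[is_bin]
  } else {
    for (b in binary) {
      v <- X[, b]
      if (length(unique(v)) > 2L)
        stop("column '", b, "' flagged binary but has more than two levels")
    }
  }
  ctr <- colMeans(X)
  div <- rep(1, ncol(X))
  cont <- setdiff(colnames(X), binary)
  sds <- apply(X[, cont, drop = FALSE], 2L, sample_sd)
  zero <- which(sds == 0 | !is.finite(sds))
  if (length(zero)) stop("zero-variance column(s): ",
                         paste(cont[zero], collapse = ", "))
  div[match(cont, colnames(X))] <- 2 * sds
  out <- design
  out$X <- sweep(sweep(X, 2L, ctr), 2L, div, "/")
  attr(out, "standardized") <- "gelman"
  recipe <- structure(list(
    columns = data.frame(column = colnames(X), center = ctr, divisor = div,
                         row.names = NULL),
    outcome = list(center = 0, divisor = 1),
    scheme = "gelman"), class = "std_recipe")
  list(design = out, recipe = recipe)
}

#' Invert a standardization recipe
#'
#' @param design a standardized `candidate_design` (or plain matrix with the
#'   recipe's columns).
#' @param recipe a `std_recipe` from [standardize_full()] or
#'   [standardize_gelman()].
#' @return The design (or matrix) on the raw scale.
#' @export
unstandardize <- function(design, recipe) {
  stopifnot(inherits(recipe, "std_recipe"))
  X <- if (inherits(design, "candidate_design")) design$X else as.matrix(design)
  i <- match(colnames(X), recipe$columns$column)
  if (anyNA(i)) stop("recipe does not cover all columns")
  X <- sweep(sweep(X, 2L, recipe$columns$divisor[i], "*"), 2L,
             recipe$columns$center[i], "+")
  if (inherits(design, "candidate_design")) {
    design$X <- X
    attr(design, "standardized") <- NULL
    design
  } else X
}

#' @export
print.std_recipe <- function(x, ...) {
  cat("Standardization recipe (", x$scheme, " scheme), ",
      nrow(x$columns), " columns\n", sep = "")
  invisible(x)
}

# Restrict a candidate_design to a set of columns (keeps metadata and ids).
design_subset <- function(design, columns) {
  keep <- match(columns, design$info$column)
  if (anyNA(keep)) stop("unknown design column(s): ",
                        paste(columns[is.na(keep)], collapse = ", "))
  out <- design
  out$X <- design$X[, keep, drop = FALSE]
  out$info <- design$info[keep, , drop = FALSE]
  out
}
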