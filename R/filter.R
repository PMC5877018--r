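#' Flag clinically underweight visits
#'
#' Underweight is defined as a BMI-for-age below the fifth percentile. Since
#' the outcome is already an age/sex-standardized z-score, the flag is a
#' strict threshold on the z-scale: `bmiz < z_cutoff`, with the cutoff
#' defaulting to the standard-normal fifth percentile `qnorm(0.05)`.
#'
#' @param cohort cohort data.frame with a `bmiz` column.
#' @param z_cutoff underweight threshold on the z-score scale.
#' @return logical vector; `NA` bmiz gives `FALSE` (handled by the
#'   missing-value rule instead).
#' @export
flag_underweight <- function(cohort, z_cutoff = stats::qnorm(0.05)) {
  z <- cohort$bmiz
  !is.na(z) & z < z_cutoff
}

#' Apply the study exclusion rules
#'
#' Rules are applied sequentially — underweight, then race restriction, then
#' missing values — and each excluded row is attributed to the first rule it
#' trips, so the per-rule counts always sum to the number of rows removed.
#' The race rule keeps only white and black patients; any unrecognised race
#' code is excluded under that rule.
#'
#' @param cohort raw cohort data.frame with columns `bmiz`, `race`, and the
#'   modeled covariates.
#' @param z_cutoff underweight threshold, see [flag_underweight()].
#' @param keep_races race codes retained by the race rule.
#' @param model_columns columns checked for missingness; defaults to the
#'   outcome and the four individual covariates plus geography identifiers,
#'   intersected with what the cohort actually has.
#'
#' @return list with `cohort` (the retained rows) and `report`, an
#'   `exclusion_report` carrying `n_input`, `n_underweight`,
#'   `n_race_excluded`, `n_missing`, `n_retained` and per-rule row indices.
#' @export
apply_exclusions <- function(cohort,
                             z_cutoff = stats::qnorm(0.05),
                             keep_races = c("white", "black"),
                             model_columns = NULL) {
  n <- nrow(cohort)
  if (is.null(model_columns))
    model_columns <- intersect(
      c("bmiz", "visitage", "male", "black", "mcvdist",
        "cbk_id", "cbg_id", "ct_id"),
      names(cohort))

  under <- flag_underweight(cohort, z_cutoff)
  race_bad <- if (is.null(cohort$race)) rep(FALSE, n) else
    !(as.character(cohort$race) %in% keep_races) | is.na(cohort$race)
  miss <- Reduce(`|`, lapply(cohort[model_columns], is.na), rep(FALSE, n))

  idx_under <- which(under)
  idx_race <- which(race_bad & !under)
  idx_miss <- which(miss & !under & !race_bad)
  drop <- c(idx_under, idx_race, idx_miss)
  kept <- if (length(drop)) cohort[-drop, , drop = FALSE] else cohort

  report <- structure(list(
    n_input = n,
    n_underweight = length(idx_under),
    n_race_excluded = length(idx_race),
    n_missing = length(idx_miss),
    n_retained = nrow(kept),
    rows = list(underweight = idx_under, race = idx_race,
                missing = idx_miss),
    z_cutoff = z_cutoff), class = "exclusion_report")
  list(cohort = kept, report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("Cohort exclusion report\n")
  cat(sprintf("  input observations:  %d\n", x$n_input))
  cat(sprintf("  underweight (z < %.4f): %d\n", x$z_cutoff, x$n_underweight))
  cat(sprintf("  race-excluded:       %d\n", x$n_race_excluded))
  cat(sprintf("  missing values:      %d\n", x$n_missing))
  cat(sprintf("  retained for analysis: %d\n", x$n_retained))
  invisible(x)
}
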