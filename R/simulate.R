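#' Configure a synthetic nested-geography cohort
#'
#' A scenario fixes everything the generator needs: the geography (tracts,
#' block groups per tract, blocks per block group), the cohort size, the
#' cross-scale correlation of area covariates, the true effects and their
#' scales, the random-intercept and residual SDs, exclusion-rule injection
#' counts, and the seed. Defaults describe a mid-sized registry extract:
#' 5,000 visits over 150 tracts, area measures correlated 0.7 across
#' neighbouring scales, a handful of standardized effects between 0.1 and
#' 0.25 split between tract- and block-group-level truth, weak group
#' intercepts, and near-unit residual SD (the outcome is a z-score).
#'
#' @param n_ct,cbg_per_ct,cbk_per_cbg geography sizes.
#' @param n number of cohort rows (visits), assigned to blocks uniformly at
#'   random.
#' @param rho cross-scale correlation in `[0, 1]`: a child unit's covariate
#'   is `rho` times its parent's value plus independent noise.
#' @param concepts named list: area concept -> scales at which it is
#'   observed.
#' @param effects data.frame (`concept`, `scale`, `beta`) of true
#'   standardized effects; concepts/scales must be declared. Individual
#'   covariates use scale `"individual"`.
#' @param sigma_cbg,sigma_ct random-intercept SDs at each grouping.
#' @param sigma_eps residual SD.
#' @param p_black Bernoulli probability for the race indicator.
#' @param exclusions named integer vector `c(underweight=, race=, missing=)`
#'   of rows to be marked by [inject_exclusions()].
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return list of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(n_ct = 150L, cbg_per_ct = 3L, cbk_per_cbg = 2L,
                               n = 5000L, rho = 0.7,
                               concepts = list(
                                 popdens = c("CBK", "CBG", "CT"),
                                 phwhite = c("CBG", "CT"),
                                 medhinc = c("CBG", "CT"),
                                 pvacant = c("CBG", "CT"),
                                 parkdens = c("CBG", "CT"),
                                 ex_eq = c("CBG", "CT")),
                               effects = data.frame(
                                 concept = c("visitage", "black", "mcvdist",
                                             "medhinc", "popdens", "phwhite",
                                             "ex_eq"),
                                 scale = c("individual", "individual",
                                           "individual", "CT", "CT", "CBG",
                                           "CBG"),
                                 beta = c(0.10, 0.10, 0.05,
                                          -0.25, -0.20, 0.20, -0.15)),
                               sigma_cbg = 0.1, sigma_ct = 0.1,
                               sigma_eps = 0.9, p_black = 0.5,
                               exclusions = c(underweight = 0L, race = 0L,
                                              missing = 0L),
                               seed = NULL) {
  stopifnot(rho >= 0, rho <= 1, sigma_cbg >= 0, sigma_ct >= 0,
            sigma_eps >= 0, n_ct >= 1, cbg_per_ct >= 1, cbk_per_cbg >= 1,
            n >= 1)
  for (i in seq_len(nrow(effects))) {
    cn <- effects$concept[i]; sc <- effects$scale[i]
    if (sc == "individual") {
      if (!cn %in% c("visitage", "male", "black", "mcvdist"))
        stop("unknown individual concept: ", cn)
    } else if (!cn %in% names(concepts) || !sc %in% concepts[[cn]])
      stop("effect declared at an unavailable (concept, scale): ",
           cn, " @ ", sc)
  }
  structure(list(n_ct = as.integer(n_ct), cbg_per_ct = as.integer(cbg_per_ct),
                 cbk_per_cbg = as.integer(cbk_per_cbg), n = as.integer(n),
                 rho = rho, concepts = concepts, effects = effects,
                 sigma_cbg = sigma_cbg, sigma_ct = sigma_ct,
                 sigma_eps = sigma_eps, p_black = p_black,
                 exclusions = exclusions, seed = seed),
            class = "synthetic_scenario")
}

#' The candidate variable specification implied by a scenario
#'
#' @param scenario a [synthetic_scenario()].
#' @return A [variable_spec()] covering the four individual covariates and
#'   every declared (concept, scale) pair.
#' @export
scenario_spec <- function(scenario) {
  variable_spec(individual = c("visitage", "male", "black", "mcvdist"),
                area = scenario$concepts)
}

.maybe_seed <- function(scenario, offset) {
  if (!is.null(scenario$seed)) set.seed(scenario$seed + offset)
}

#' Generate a strictly nested geography
#'
#' @param scenario a [synthetic_scenario()].
#' @return A [geo_hierarchy()] with `n_ct * cbg_per_ct` block groups and
#'   `n_ct * cbg_per_ct * cbk_per_cbg` blocks, with opaque synthetic IDs.
#' @export
generate_geography <- function(scenario) {
  ct <- sprintf("T%03d", seq_len(scenario$n_ct))
  cbg <- as.vector(outer(seq_len(scenario$cbg_per_ct), ct,
                         function(g, t) paste0(t, ".G", g)))
  cbg_map <- data.frame(cbg_id = cbg, ct_id = substr(cbg, 1L, 4L))
  cbk <- as.vector(outer(seq_len(scenario$cbk_per_cbg), cbg,
                         function(b, g) paste0(g, ".B", b)))
  cbk_map <- data.frame(cbk_id = cbk,
                        cbg_id = sub("\\.B[0-9]+$", "", cbk))
  geo_hierarchy(cbk_map, cbg_map)
}

#' Generate area covariates with controlled cross-scale correlation
#'
#' For each concept, the tract-level value is standard normal; each block
#' group's value is `rho` times its parent tract's value plus
#' `sqrt(1 - rho^2)` independent noise, and analogously for blocks within
#' block groups. Covariates are therefore standard normal at every scale
#' with cross-scale correlation `rho` between a unit and its parent.
#'
#' @param geo a [geo_hierarchy()].
#' @param scenario a [synthetic_scenario()].
#' @return named list of per-scale data.frames (`CBK`, `CBG`, `CT`), each
#'   with a `unit_id` column and one column per concept.
#' @export
generate_area_covariates <- function(geo, scenario) {
  .maybe_seed(scenario, 1L)
  rho <- scenario$rho
  ct_ids <- unique(geo$cbg$ct_id)
  cbg_ids <- geo$cbg$cbg_id
  cbk_ids <- geo$cbk$cbk_id
  ct_tab <- data.frame(unit_id = ct_ids)
  cbg_tab <- data.frame(unit_id = cbg_ids)
  cbk_tab <- data.frame(unit_id = cbk_ids)
  parent_ct <- match(geo$cbg$ct_id, ct_ids)
  parent_cbg <- match(geo$cbk$cbg_id, cbg_ids)
  for (cn in names(scenario$concepts)) {
    u_ct <- stats::rnorm(length(ct_ids))
    u_cbg <- rho * u_ct[parent_ct] +
      sqrt(1 - rho^2) * stats::rnorm(length(cbg_ids))
    u_cbk <- rho * u_cbg[parent_cbg] +
      sqrt(1 - rho^2) * stats::rnorm(length(cbk_ids))
    ct_tab[[cn]] <- u_ct
    cbg_tab[[cn]] <- u_cbg
    cbk_tab[[cn]] <- u_cbk
  }
  list(CBK = cbk_tab, CBG = cbg_tab, CT = ct_tab)
}

# population-standardized versions of the individual covariates, so that
# scenario effects are on the standardized scale by construction
.std_individual <- function(cohort, p_black) {
  list(
    visitage = (cohort$visitage - 9.5) / (15 / sqrt(12)),  # U(2,17)
    male = (cohort$male - 0.5) / 0.5,
    black = (cohort$black - p_black) / sqrt(p_black * (1 - p_black)),
    # mcvdist = 5|Z|: mean 5*sqrt(2/pi), sd 5*sqrt(1 - 2/pi)
    mcvdist = (cohort$mcvdist - 5 * sqrt(2 / pi)) /
      (5 * sqrt(1 - 2 / pi)))
}

#' Generate a cohort with known truth
#'
#' Rows are assigned to census blocks uniformly at random. The outcome is
#' linear in the population-standardized covariates at their declared true
#' scales, plus Gaussian random intercepts at the block group and tract and
#' residual noise:
#' `bmiz = sum(beta * x_std) + b_CBG + b_CT + eps`.
#'
#' @param geo a [geo_hierarchy()].
#' @param area_tables output of [generate_area_covariates()].
#' @param scenario a [synthetic_scenario()].
#' @return list with `cohort` (data.frame: `bmiz`, `visitage`, `male`,
#'   `black`, `mcvdist`, `race`, geography IDs) and `truth` (the effects
#'   table, variance components, per-unit random intercepts, and the linear
#'   predictor).
#' @export
generate_cohort <- function(geo, area_tables, scenario) {
  .maybe_seed(scenario, 2L)
  n <- scenario$n
  cbk <- sample(geo$cbk$cbk_id, n, replace = TRUE)
  cbg <- geo$cbk$cbg_id[match(cbk, geo$cbk$cbk_id)]
  ct <- geo$cbg$ct_id[match(cbg, geo$cbg$cbg_id)]
  cohort <- data.frame(
    visitage = stats::runif(n, 2, 17),
    male = stats::rbinom(n, 1L, 0.5),
    black = stats::rbinom(n, 1L, scenario$p_black),
    mcvdist = 5 * abs(stats::rnorm(n)),
    cbk_id = cbk, cbg_id = cbg, ct_id = ct)
  cohort$race <- ifelse(cohort$black == 1L, "black", "white")

  xs <- .std_individual(cohort, scenario$p_black)
  id_col <- c(CBK = "cbk_id", CBG = "cbg_id", CT = "ct_id")
  eta <- numeric(n)
  for (i in seq_len(nrow(scenario$effects))) {
    cn <- scenario$effects$concept[i]
    sc <- scenario$effects$scale[i]
    b <- scenario$effects$beta[i]
    x <- if (sc == "individual") xs[[cn]] else {
      tab <- area_tables[[sc]]
      tab[[cn]][match(cohort[[id_col[[sc]]]], tab$unit_id)]
    }
    eta <- eta + b * x
  }
  b_cbg <- stats::rnorm(nrow(geo$cbg), 0, scenario$sigma_cbg)
  names(b_cbg) <- geo$cbg$cbg_id
  ct_ids <- unique(geo$cbg$ct_id)
  b_ct <- stats::rnorm(length(ct_ids), 0, scenario$sigma_ct)
  names(b_ct) <- ct_ids
  eps <- stats::rnorm(n, 0, scenario$sigma_eps)
  cohort$bmiz <- eta + b_cbg[cohort$cbg_id] + b_ct[cohort$ct_id] + eps
  cohort <- cohort[, c("bmiz", "visitage", "male", "black", "mcvdist",
                       "race", "cbk_id", "cbg_id", "ct_id")]
  rownames(cohort) <- NULL
  truth <- list(effects = scenario$effects,
                sigma_cbg = scenario$sigma_cbg,
                sigma_ct = scenario$sigma_ct,
                sigma_eps = scenario$sigma_eps,
                b_cbg = b_cbg, b_ct = b_ct, eta = eta,
                seed = scenario$seed)
  list(cohort = cohort, truth = truth)
}

#' Mark rows so that the exclusion rules trip in configured numbers
#'
#' Produces a "raw" cohort on which [apply_exclusions()] removes exactly the
#' configured counts: disjoint random rows get a below-cutoff z-score, a
#' race code outside {white, black}, or a blanked covariate. Any other row
#' whose simulated z-score happens to fall below the underweight cutoff is
#' reflected just above it, so the rule counts are exact by construction;
#' the returned table is for testing the filtering workflow, not for model
#' fitting (use the pre-injection cohort for that).
#'
#' @param cohort a cohort data.frame.
#' @param scenario a [synthetic_scenario()] whose `exclusions` counts are
#'   used.
#' @param z_cutoff underweight threshold, as in [flag_underweight()].
#' @return The cohort with an extra `injected` column naming the rule each
#'   marked row should trip (`""` otherwise).
#' @export
inject_exclusions <- function(cohort, scenario,
                              z_cutoff = stats::qnorm(0.05)) {
  .maybe_seed(scenario, 3L)
  cnt <- scenario$exclusions
  for (nm in c("underweight", "race", "missing"))
    if (is.na(cnt[nm])) cnt[nm] <- 0L
  total <- sum(cnt)
  if (total > nrow(cohort))
    stop("requested exclusion counts exceed the cohort size")
  out <- cohort
  low <- out$bmiz < z_cutoff
  out$bmiz[low] <- 2 * z_cutoff - out$bmiz[low]  # reflect above the cutoff
  picks <- sample(nrow(out), total)
  i_u <- picks[seq_len(cnt["underweight"])]
  i_r <- picks[cnt["underweight"] + seq_len(cnt["race"])]
  i_m <- picks[cnt["underweight"] + cnt["race"] + seq_len(cnt["missing"])]
  out$injected <- ""
  if (length(i_u)) {
    out$bmiz[i_u] <- z_cutoff - stats::runif(length(i_u), 0.05, 2)
    out$injected[i_u] <- "underweight"
  }
  if (length(i_r)) {
    out$race[i_r] <- sample(c("hispanic", "asian", "other"),
                            length(i_r), replace = TRUE)
    out$injected[i_r] <- "race"
  }
  if (length(i_m)) {
    out$visitage[i_m] <- NA_real_
    out$injected[i_m] <- "missing"
  }
  out
}

#' Simulate a full study dataset
#'
#' Convenience wrapper running geography, area-covariate, and cohort
#' generation (plus exclusion injection when the scenario requests it) and
#' assembling the candidate design inputs.
#'
#' @param scenario a [synthetic_scenario()].
#' @return list with `geo`, `area_tables`, `cohort` (clean), `raw_cohort`
#'   (with injected exclusions; identical to `cohort` plus the `injected`
#'   column when no counts are configured), `truth`, and `spec` (the
#'   [scenario_spec()]).
#' @export
simulate_study <- function(scenario = synthetic_scenario()) {
  .maybe_seed(scenario, 0L)
  geo <- generate_geography(scenario)
  area <- generate_area_covariates(geo, scenario)
  gen <- generate_cohort(geo, area, scenario)
  raw <- inject_exclusions(gen$cohort, scenario)
  list(geo = geo, area_tables = area, cohort = gen$cohort,
       raw_cohort = raw, truth = gen$truth, spec = scenario_spec(scenario))
}
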