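#' Load a pipeline configuration
#'
#' Configurations are YAML with three sections: `scenario` (passed to
#' [synthetic_scenario()]), `ss` (passed to [ss_control()]; defaults are the
#' study tuning: `epsilon` 1, `step_size` 0.001, `tolerance` 0.01, `alpha`
#' 0.05), and top-level `algorithms`, `seed`, `outdir`. Unknown fields are an
#' error, named by their path. Note that the scenario's cohort-size key must
#' be written `"n"` (quoted) in YAML, since a bare `n` is YAML shorthand for
#' a boolean.
#'
#' @param path YAML file path, or a list already parsed.
#' @return list of class `pipeline_config` with `scenario`, `control`,
#'   `algorithms`, `seed`, `outdir`.
#' @export
load_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  known_top <- c("scenario", "ss", "algorithms", "seed", "outdir")
  bad <- setdiff(names(cfg), known_top)
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  sc_args <- cfg$scenario
  if (!is.null(sc_args)) {
    bad <- setdiff(names(sc_args), names(formals(synthetic_scenario)))
    if (length(bad))
      stop("unknown config field(s): ",
           paste(paste0("scenario.", bad), collapse = ", "))
    if (!is.null(sc_args$effects))
      sc_args$effects <- as.data.frame(do.call(rbind, lapply(
        sc_args$effects, as.data.frame)))
    if (!is.null(sc_args$exclusions))
      sc_args$exclusions <- unlist(sc_args$exclusions)
  }
  ss_args <- cfg$ss
  if (!is.null(ss_args)) {
    bad <- setdiff(names(ss_args), names(formals(ss_control)))
    if (length(bad))
      stop("unknown config field(s): ",
           paste(paste0("ss.", bad), collapse = ", "))
  }
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  sc_args$seed <- seed
  algorithms <- cfg$algorithms
  if (is.null(algorithms))
    algorithms <- c("stepwise", "stagewise", "lars", "lasso")
  algorithms <- match.arg(algorithms,
                          c("stepwise", "stagewise", "lars", "lasso"),
                          several.ok = TRUE)
  structure(list(scenario = do.call(synthetic_scenario, as.list(sc_args)),
                 control = do.call(ss_control, as.list(ss_args)),
                 algorithms = algorithms, seed = seed,
                 outdir = if (is.null(cfg$outdir)) NULL else cfg$outdir),
            class = "pipeline_config")
}

#' Write a report table as CSV
#'
#' Numeric columns are formatted to 6 significant digits; column order is
#' preserved. Reading the file back reproduces the table at that precision.
#'
#' @param table data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(table, path) {
  out <- as.data.frame(table)
  for (j in seq_along(out))
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- signif(out[[j]], 6)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# stable text checksum of the configuration, recorded in the manifest
.config_hash <- function(cfg) {
  txt <- paste(utils::capture.output(utils::str(cfg, digits.d = 12)),
               collapse = "\n")
  sprintf("%08x", sum(as.integer(charToRaw(txt)) *
                        (seq_along(charToRaw(txt)) %% 97 + 1)) %% .Machine$integer.max)
}

#' Run the full analysis pipeline on a synthetic study
#'
#' Simulate, filter, standardize, run the requested scale-selection
#' algorithms, refit by OLS, compare single-scale constrained fits, compare
#' random-effect placements, and run the interaction workflow; write every
#' report as CSV into the output directory. Reports carry the seed, and
#' reruns with the same configuration are reproducible.
#'
#' @param config a `pipeline_config` (see [load_config()]), or a path to one.
#' @param outdir output directory (overrides the config's); created if
#'   needed.
#' @return Invisibly, a list of the in-memory results (`filter`, per-method
#'   `paths`, `fits`, `scale_aic`, `re_aic`, `interactions`); side effect is
#'   the report files.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (is.character(config) || !inherits(config, "pipeline_config"))
    config <- load_config(config)
  outdir <- if (!is.null(outdir)) outdir else config$outdir
  if (is.null(outdir)) stop("no output directory configured")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()

  stage <- "simulate"
  res <- tryCatch({
    sim <- simulate_study(config$scenario)

    stage <- "filter"
    filt <- apply_exclusions(sim$raw_cohort)
    cohort <- filt$cohort

    stage <- "design"
    viol <- validate_hierarchy(cohort, sim$geo)
    if (nrow(viol)) stop("geography inconsistencies in ", nrow(viol), " rows")
    design <- build_candidate_design(cohort, sim$area_tables, sim$spec)

    stage <- "standardize"
    std <- standardize_full(design, cohort$bmiz)

    out <- list(filter = filt$report, paths = list(), fits = list(),
                scale_aic = NULL, re_aic = NULL, interactions = list())
    scale_rows <- list(); re_rows <- list(); int_rows <- list()
    for (alg in config$algorithms) {
      stage <- paste0("select:", alg)
      path <- ss_select(std$design, std$outcome, method = alg,
                        control = config$control, standardize = FALSE)
      out$paths[[alg]] <- path
      write_report(path$steps, file.path(outdir, paste0("path_", alg, ".csv")))
      sel <- selected_model(path)

      stage <- paste0("refit:", alg)
      fit_ss <- constrained_scale_refit(sel, std$design, std$outcome)
      out$fits[[alg]] <- fit_ss
      write_report(fit_ss$coefficients,
                   file.path(outdir, paste0("selected_", alg, ".csv")))

      stage <- paste0("compare-scales:", alg)
      fit_cbg <- constrained_scale_refit(sel, std$design, std$outcome, "CBG")
      fit_ct <- constrained_scale_refit(sel, std$design, std$outcome, "CT")
      scale_rows[[alg]] <- data.frame(
        method = alg, model = c("CBG", "CT", "SS"),
        aic = c(fit_cbg$aic, fit_ct$aic, fit_ss$aic))

      stage <- paste0("mixed:", alg)
      cmp <- compare_re_specs(std$design, std$outcome, sel$columns)
      re_rows[[alg]] <- cbind(method = alg, cmp$table[, c("re", "aic")])
      ranefs <- do.call(rbind, lapply(cmp$fits[c("CBG", "CT")],
                                      function(f) f$ranef))
      write_report(ranefs,
                   file.path(outdir, paste0("ranef_", alg, ".csv")))

      stage <- paste0("interactions:", alg)
      ia <- run_interaction_workflow(design, cohort$bmiz, sel,
                                     alpha = config$control$alpha)
      out$interactions[[alg]] <- ia
      write_report(ia$fit_final$coefficients,
                   file.path(outdir, paste0("interaction_", alg, ".csv")))
      int_rows[[alg]] <- cbind(method = alg, ia$aic_table)
    }
    out$scale_aic <- do.call(rbind, scale_rows)
    out$re_aic <- do.call(rbind, re_rows)
    write_report(out$scale_aic, file.path(outdir, "scale_aic.csv"))
    write_report(out$re_aic, file.path(outdir, "re_aic.csv"))
    write_report(do.call(rbind, int_rows),
                 file.path(outdir, "interaction_aic.csv"))
    rep <- filt$report
    write_report(data.frame(rule = c("input", "underweight", "race",
                                     "missing", "retained"),
                            n = c(rep$n_input, rep$n_underweight,
                                  rep$n_race_excluded, rep$n_missing,
                                  rep$n_retained)),
                 file.path(outdir, "exclusions.csv"))
    out
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  manifest <- c(
    paste0("package: spscale ",
           as.character(utils::packageVersion("spscale"))),
    paste0("r_version: ", R.version.string),
    paste0("seed: ", config$seed),
    paste0("config_hash: ", .config_hash(config)),
    paste0("algorithms: ", paste(config$algorithms, collapse = ",")),
    paste0("elapsed_sec: ",
           round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2)))
  writeLines(manifest, file.path(outdir, "manifest.txt"))
  invisible(res)
}

#' Interaction workflow for one selected model
#'
#' Resolves the nine clinician-specified pairs against the selected
#' covariates (parents not selected fall back to the tract scale; the male
#' indicator is force-included), rescales on the Gelman scheme, fits the
#' full interaction model on the raw outcome, prunes to significant pairs,
#' and refits the final models with and without random intercepts.
#'
#' @param design the raw (unstandardized) `candidate_design`.
#' @param outcome raw outcome vector.
#' @param selected an `ss_model`.
#' @param spec an [interaction_spec()].
#' @param alpha pruning threshold.
#' @return list: `fit_full`, `kept` (retained pairs), `fit_final`,
#'   `aic_table`, `main_terms`.
#' @export
run_interaction_workflow <- function(design, outcome, selected,
                                     spec = interaction_spec(),
                                     alpha = 0.05) {
  info <- design$info
  have <- unique(info$concept)
  spec <- spec[spec$modifier %in% have & spec$base %in% have, , drop = FALSE]
  sel_cols <- selected$columns
  pick <- function(concept) {
    hit <- sel_cols[info$concept[match(sel_cols, info$column)] == concept]
    if (length(hit)) return(hit[1L])
    cols <- info[info$concept == concept, , drop = FALSE]
    for (sc in c("individual", "CT", "CBG", "CBK"))
      if (sc %in% cols$scale) return(cols$column[cols$scale == sc][1L])
    cols$column[1L]
  }
  parents <- unique(vapply(unique(c(spec$modifier, spec$base)), pick,
                           character(1)))
  main_cols <- union(sel_cols, union(parents, pick("male")))
  main_cols <- main_cols[order(info$number[match(main_cols, info$column)])]
  gdesign <- standardize_gelman(design_subset(design, main_cols))$design
  resolved <- spec
  resolved$modifier_col <- vapply(resolved$modifier, pick, character(1))
  resolved$base_col <- vapply(resolved$base, pick, character(1))
  ext <- build_interaction_design(gdesign, resolved)
  fit_full <- refit_ols(ext, outcome, colnames(ext$X), intercept = TRUE)
  kept <- prune_to_significant(fit_full, resolved, alpha = alpha)
  final <- final_interaction_models(gdesign, outcome, kept)
  list(fit_full = fit_full, kept = kept,
       fit_final = final$fits$none, aic_table = final$aic_table,
       main_terms = main_cols)
}
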