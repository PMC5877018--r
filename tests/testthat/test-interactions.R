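gelman_study <- function(seed, n = 2000, n_ct = 60) {
  sim <- simulate_study(synthetic_scenario(n_ct = n_ct, n = n, seed = seed))
  d <- build_candidate_design(sim$cohort, sim$area_tables, sim$spec)
  list(sim = sim, design = d,
       gdesign = standardize_gelman(d)$design, y = sim$cohort$bmiz)
}

test_that("the default specification resolves to nine product columns", {
  st <- gelman_study(seed = 1, n = 500, n_ct = 20)
  spec <- interaction_spec()
  expect_equal(nrow(spec), 9L)
  resolved <- resolve_interactions(st$gdesign, spec)
  ext <- build_interaction_design(st$gdesign, resolved)
  expect_equal(ncol(ext$X), ncol(st$gdesign$X) + 9L)
  # parent columns are untouched (no re-centering leakage)
  expect_identical(ext$X[, colnames(st$gdesign$X)], st$gdesign$X)

  # products are elementwise, checked by hand on a few rows
  nm <- paste(resolved$modifier_col[1], resolved$base_col[1], sep = ":")
  expect_equal(ext$X[1:5, nm],
               st$gdesign$X[1:5, resolved$modifier_col[1]] *
                 st$gdesign$X[1:5, resolved$base_col[1]])

  # centered independent binaries: product column has near-zero mean
  set.seed(2)
  B <- cbind(a = rbinom(4000, 1, 0.5), b = rbinom(4000, 1, 0.5))
  gb <- standardize_gelman(wrap_design(B))$design
  pr <- gb$X[, "a"] * gb$X[, "b"]
  expect_lt(abs(mean(pr)), 0.03)

  # building on an unrescaled design is refused
  expect_error(build_interaction_design(st$design, resolved), "Gelman")
  # a missing parent is an error
  bad <- resolved
  bad$base_col[1] <- "nonexistent"
  expect_error(build_interaction_design(st$gdesign, bad), "absent")
})

test_that("pruning keeps significant pairs, is single-pass stable, and honours alpha", {
  # truth: two real interactions among nine candidates
  set.seed(30)
  n <- 8000
  st <- gelman_study(seed = 30, n = n, n_ct = 80)
  g <- st$gdesign
  resolved <- resolve_interactions(g)
  ytrue <- st$y +
    0.5 * g$X[, "male"] * g$X[, "medhinc_CT"] +
    0.6 * g$X[, "black"] * g$X[, "popdens_CT"]
  ext <- build_interaction_design(g, resolved)
  fit <- refit_ols(ext, ytrue, colnames(ext$X), intercept = TRUE)
  kept <- prune_to_significant(fit, resolved, alpha = 0.05)
  expect_true(all(c("medhinc", "popdens") %in% kept$base))
  expect_true("male" %in% kept$modifier & "black" %in% kept$modifier)

  # stability: refitting the reduced model and pruning again changes nothing
  ext2 <- build_interaction_design(g, kept)
  fit2 <- refit_ols(ext2, ytrue, colnames(ext2$X), intercept = TRUE)
  kept2 <- prune_to_significant(fit2, kept, alpha = 0.05)
  expect_equal(kept2[, c("modifier", "base")], kept[, c("modifier", "base")],
               ignore_attr = TRUE)

  # alpha = 0 removes everything; alpha = 1 keeps everything
  expect_equal(nrow(prune_to_significant(fit, resolved, alpha = 0)), 0L)
  expect_equal(nrow(prune_to_significant(fit, resolved, alpha = 1)), 9L)
})

test_that("final interaction models beat main-effects fits only when interactions are real", {
  st <- gelman_study(seed = 31, n = 4000, n_ct = 60)
  g <- st$gdesign
  resolved <- resolve_interactions(g)
  main_cmp <- compare_re_specs(g, st$y, colnames(g$X), intercept = TRUE)
  aic_main <- main_cmp$table$aic[main_cmp$table$re == "none"]

  # no-interaction truth: keeping all nine pairs costs at most the penalty
  final_null <- final_interaction_models(g, st$y, resolved)
  aic_null <- final_null$aic_table$aic[final_null$aic_table$re == "none"]
  expect_gt(aic_null, aic_main - 1)
  expect_lt(aic_null, aic_main + 2 * nrow(resolved) + 1)

  # real interaction truth: AIC drops well below the main-effects model
  yint <- st$y + 0.6 * g$X[, "black"] * g$X[, "ex_eq_CT"]
  main_int <- refit_ols(g, yint, colnames(g$X), intercept = TRUE)
  final_int <- final_interaction_models(
    g, yint, resolved[resolved$base == "ex_eq" &
                        resolved$modifier == "black", ])
  aic_int <- final_int$aic_table$aic[final_int$aic_table$re == "none"]
  expect_lt(aic_int,
            spscale:::full_gaussian_aic(main_int$rss, main_int$n,
                                        main_int$k) - 10)
  expect_setequal(final_int$aic_table$re, c("none", "CBG", "CT", "both"))
})
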