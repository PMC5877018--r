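test_that("the full candidate pool yields 31 columns over 17 concepts", {
  spec <- table1_spec()
  expect_equal(nrow(spec), 31L)
  expect_equal(length(unique(spec$concept)), 17L)
  expect_equal(sum(spec$scale == "individual"), 4L)
  expect_equal(sum(spec$concept == "popdens"), 3L)
  # column count identity: 4 individual + 3 popdens + 12 concepts x 2 scales
  expect_equal(4L + 3L + 12L * 2L, 31L)

  sc <- synthetic_scenario(
    n_ct = 10L, n = 200L, seed = 2,
    concepts = stats::setNames(
      lapply(unique(spec$concept[spec$scale != "individual"]),
             function(cn) spec$scale[spec$concept == cn]),
      unique(spec$concept[spec$scale != "individual"])),
    effects = data.frame(concept = "visitage", scale = "individual",
                         beta = 0.1))
  sim <- simulate_study(sc)
  d <- build_candidate_design(sim$cohort, sim$area_tables, spec)
  expect_equal(ncol(d$X), 31L)
  expect_equal(d$info$number, 1:31)
})

test_that("design assembly joins unit values correctly on a toy geography", {
  geo <- geo_hierarchy(
    data.frame(cbk_id = paste0("b", 1:3), cbg_id = paste0("g", 1:3)),
    data.frame(cbg_id = paste0("g", 1:3), ct_id = c("t1", "t1", "t2")))
  area <- list(
    CBG = data.frame(unit_id = paste0("g", 1:3), inc = c(10, 20, 30)),
    CT = data.frame(unit_id = c("t1", "t2"), inc = c(1, 2)))
  cohort <- data.frame(age = c(5, 6, 7, 8, 9, 10),
                       cbk_id = c("b1", "b1", "b2", "b3", "b3", "b2"),
                       cbg_id = c("g1", "g1", "g2", "g3", "g3", "g2"),
                       ct_id = c("t1", "t1", "t1", "t2", "t2", "t1"))
  spec <- variable_spec(individual = "age",
                        area = list(inc = c("CBG", "CT")))
  d <- build_candidate_design(cohort, area, spec)
  expect_equal(ncol(d$X), 3L)
  expect_equal(d$X[, "age"], cohort$age)
  expect_equal(d$X[, "inc_CBG"], c(10, 10, 20, 30, 30, 20))
  expect_equal(d$X[, "inc_CT"], c(1, 1, 1, 2, 2, 1))

  # individual-only spec reduces to the cohort columns
  d2 <- build_candidate_design(cohort, list(),
                               variable_spec(individual = "age"))
  expect_equal(ncol(d2$X), 1L)

  # join determinism: permuting rows permutes the design identically
  perm <- c(4, 2, 6, 1, 3, 5)
  d3 <- build_candidate_design(cohort[perm, ], area, spec)
  expect_equal(d3$X, d$X[perm, ], ignore_attr = TRUE)

  # missing unit is an error naming unit and scale
  area_bad <- area
  area_bad$CT <- area_bad$CT[1, , drop = FALSE]
  expect_error(build_candidate_design(cohort, area_bad, spec), "CT.*t2")
})

test_that("full standardization gives exact zero mean and unit SD and inverts", {
  d <- wrap_design(cbind(a = c(1, 2, 3), b = c(2, 4, 9)))
  std <- standardize_full(d, c(0, 1, 5))
  expect_equal(std$design$X[, "a"], c(-1, 0, 1), ignore_attr = TRUE)

  set.seed(1)
  X <- matrix(rnorm(500), 100, 5) * rep(c(1, 10, 0.1, 3, 7), each = 100)
  y <- rnorm(100, 5, 2)
  std <- standardize_full(wrap_design(X), y)
  expect_lt(max(abs(colMeans(std$design$X))), 1e-12)
  expect_lt(max(abs(apply(std$design$X, 2, sd) - 1)), 1e-12)
  expect_lt(abs(mean(std$outcome)), 1e-12)
  expect_equal(sd(std$outcome), 1)

  # idempotence
  std2 <- standardize_full(std$design, std$outcome)
  expect_lt(max(abs(std2$design$X - std$design$X)), 1e-12)

  # recipe round trip
  back <- unstandardize(std$design, std$recipe)
  expect_lt(max(abs(back$X - X)), 1e-10)

  # zero-variance column is an error naming the column
  colnames(X) <- paste0("v", 1:5)
  Xz <- cbind(X, konst = 1)
  expect_error(standardize_full(wrap_design(Xz), y), "konst")
})

test_that("two-SD rescaling centers binaries and halves continuous SDs", {
  set.seed(2)
  n <- 500
  X <- cbind(male = rbinom(n, 1, 0.6), inc = rnorm(n, 50, 2),
             dens = rexp(n), black = rbinom(n, 1, 0.3))
  g <- standardize_gelman(wrap_design(X))
  Xg <- g$design$X
  expect_lt(max(abs(colMeans(Xg))), 1e-12)
  expect_setequal(round(unique(Xg[, "male"]), 10),
                  round(c(-mean(X[, "male"]), 1 - mean(X[, "male"])), 10))
  expect_true(all(Xg[, c("male", "black")] > -1 & Xg[, c("male", "black")] < 1))
  expect_equal(sd(Xg[, "inc"]), 0.5, tolerance = 1e-12)
  expect_equal(sd(Xg[, "dens"]), 0.5, tolerance = 1e-12)

  # recipe inverts
  back <- unstandardize(g$design, g$recipe)
  expect_lt(max(abs(back$X - X)), 1e-10)

  # flagged binary with more than two levels is an error
  expect_error(standardize_gelman(wrap_design(X), binary = "inc"),
               "more than two levels")
})
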