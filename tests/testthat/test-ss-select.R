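test_that("eligibility blocks active siblings and frees them after a drop", {
  X <- matrix(rnorm(60), 10)
  d <- meta_design(X, concept = c("popdens", "popdens", "popdens",
                                  "inc", "inc", "age"),
                   scale = c("CBK", "CBG", "CT", "CBG", "CT", "individual"))
  expect_setequal(eligible_columns(d), d$info$column)
  e <- eligible_columns(d, active = "popdens_CT")
  expect_false(any(c("popdens_CBK", "popdens_CBG", "popdens_CT") %in% e))
  expect_setequal(e, c("inc_CBG", "inc_CT", "age"))
  # after a drop the concept's columns are all eligible again
  expect_true(all(c("popdens_CBK", "popdens_CBG", "popdens_CT") %in%
                    eligible_columns(d, active = "inc_CT")))
  expect_error(eligible_columns(d, active = "age", excluded = "age"),
               "overlap")
})

test_that("ols_aic follows the profiled Gaussian formula and matches stats::AIC up to a constant", {
  expect_equal(ols_aic(100, 100, 0), 2)
  expect_equal(ols_aic(50, 80, 3) + 2, ols_aic(50, 80, 4))
  expect_warning(expect_identical(ols_aic(0, 10, 1), -Inf), "-Inf")
  offs <- sapply(1:5, function(s) {
    set.seed(s)
    n <- 50; k <- sample(1:4, 1)
    X <- matrix(rnorm(n * k), n)
    y <- rnorm(n)
    fit <- lm(y ~ X - 1)
    AIC(fit) - ols_aic(sum(resid(fit)^2), n, k)
  })
  # offset n(log(2 pi) + 1) is independent of k
  expect_lt(diff(range(offs)), 1e-8)
  expect_equal(offs[1], 50 * (log(2 * pi) + 1))
})

test_that("forward stepwise adds the AIC-best candidate and stops at epsilon", {
  set.seed(42)
  n <- 200
  X <- matrix(rnorm(n * 5), n, 5)
  colnames(X) <- paste0("v", 1:5)
  y <- 2 * X[, 1]
  std <- standardize_full(wrap_design(X), y + rnorm(n, 0, 0.5))
  path <- ss_select(std$design, std$outcome, "stepwise", standardize = FALSE)
  # oracle: exhaustive single-candidate OLS scan
  aic1 <- sapply(1:5, function(j) {
    r <- resid(lm(std$outcome ~ std$design$X[, j] - 1))
    ols_aic(sum(r^2), n, 1)
  })
  expect_equal(path$steps$column[1], paste0("v", which.min(aic1)))
  expect_equal(path$steps$column[1], "v1")
  expect_equal(path$steps$aic[1], min(aic1))
  # subsequent steps only accepted on an epsilon improvement
  if (nrow(path$steps) > 1)
    expect_true(all(diff(path$steps$aic) <= -1))

  # epsilon too large to ever trigger: empty model
  p0 <- ss_select(std$design, std$outcome, "stepwise",
                  control = ss_control(epsilon = 1e9), standardize = FALSE)
  expect_equal(nrow(p0$steps), 0L)
  expect_length(selected_model(p0)$columns, 0L)
})

test_that("identical sibling columns: exactly one enters, ties break by variable number", {
  set.seed(3)
  n <- 150
  x <- rnorm(n)
  z <- rnorm(n)
  X <- cbind(x, x, z)  # two identical siblings of one concept
  d <- meta_design(X, concept = c("inc", "inc", "age"),
                   scale = c("CBG", "CT", "individual"))
  y <- 2 * x + rnorm(n, 0, 0.3)
  std <- standardize_full(d, y)
  for (m in c("stepwise", "stagewise", "lars", "lasso")) {
    sel <- selected_model(ss_select(std$design, std$outcome, m,
                                    standardize = FALSE))
    expect_true("inc_CBG" %in% sel$columns, info = m)   # lower number wins
    expect_false("inc_CT" %in% sel$columns, info = m)
  }
})

test_that("stagewise converges to the soft-thresholded solution on orthogonal designs", {
  X <- orthogonal_design(seed = 10, n = 100, p = 5)
  set.seed(11)
  y <- drop(X %*% c(0.8, -0.4, 0.2, 0, 0)) + rnorm(100, 0, 0.2)
  y <- (y - mean(y)) / sd(y)
  d <- wrap_design(X)
  ctl <- ss_control(step_size = 0.001, tolerance = 0.01)
  path <- ss_select(d, y, "stagewise", control = ctl, standardize = FALSE)
  bet <- coef(path)
  # orthogonal case: terminal coefficient within one step of the
  # tolerance-level soft threshold of the OLS solution
  target <- oracle_soft_threshold(X, y, lambda = ctl$tolerance * (100 - 1))
  expect_lt(max(abs(bet - target)), ctl$step_size + 1e-10)

  # tolerance above every starting correlation: empty path
  p0 <- ss_select(d, y, "stagewise",
                  control = ss_control(tolerance = 0.999),
                  standardize = FALSE)
  expect_equal(nrow(p0$steps), 0L)
})

test_that("stagewise only ever increments the more correlated sibling", {
  set.seed(21)
  n <- 300
  u <- rnorm(n)
  x1 <- u + rnorm(n, 0, 0.30)   # stronger sibling
  x2 <- u + rnorm(n, 0, 0.45)   # weaker sibling
  X <- cbind(x1, x2, rnorm(n))
  d <- meta_design(X, concept = c("inc", "inc", "age"),
                   scale = c("CBG", "CT", "individual"))
  y <- u + rnorm(n, 0, 0.5)
  std <- standardize_full(d, y)
  stopifnot(abs(cor(std$design$X[, 1], std$outcome)) >
              abs(cor(std$design$X[, 2], std$outcome)))
  path <- ss_select(std$design, std$outcome, "stagewise", standardize = FALSE)
  expect_gt(abs(coef(path)["inc_CBG"]), 0)
  expect_identical(unname(coef(path)["inc_CT"]), 0)
  expect_false("inc_CT" %in% path$steps$column)
  # hand-run the first iterations of the update rule as an oracle
  Xs <- std$design$X; ys <- std$outcome
  b <- numeric(3); r <- ys
  for (it in 1:10) {
    ch <- drop(crossprod(Xs, r)) / (n - 1)
    j <- which.max(abs(ch))
    b[j] <- b[j] + 0.001 * sign(ch[j])
    r <- r - 0.001 * sign(ch[j]) * Xs[, j]
  }
  expect_equal(unname(path$beta[1, ]), c(0.001, 0, 0))
  expect_equal(which(b != 0), 1L)
})

test_that("constrained LARS reduces to textbook LARS when every concept has one scale", {
  for (s in c(4, 5, 6)) {
    prob <- random_single_scale(seed = s, n = 150, p = 7)
    path <- ss_select(prob$design, prob$outcome, "lars", standardize = FALSE)
    okn <- oracle_lars(prob$design$X, prob$outcome)
    expect_equal(nrow(path$beta), nrow(okn))
    expect_lt(max(abs(path$beta - okn)), 1e-8)
  }
  # p = 1: entry knot then the full OLS solution
  set.seed(8)
  x <- scale(rnorm(30)); y <- drop(scale(x + rnorm(30)))
  d <- wrap_design(matrix(x, dimnames = list(NULL, "v1")))
  p1 <- ss_select(d, y, "lars", standardize = FALSE)
  expect_equal(p1$steps$event, c("enter", "terminal"))
  expect_equal(unname(p1$beta[2, 1]), unname(coef(lm(y ~ x - 1))),
               tolerance = 1e-10)
})

test_that("lasso knots equal soft-thresholded OLS on orthogonal designs", {
  X <- orthogonal_design(seed = 12, n = 120, p = 5)
  set.seed(13)
  y <- drop(X %*% c(1, -0.6, 0.3, 0.1, 0)) + rnorm(120, 0, 0.3)
  y <- (y - mean(y)) / sd(y)
  path <- ss_select(wrap_design(X), y, "lasso", standardize = FALSE)
  for (k in seq_len(nrow(path$steps))) {
    bet <- path$beta[k, ]
    C <- max(abs(crossprod(X, y - X %*% bet)))
    expect_lt(max(abs(bet - oracle_soft_threshold(X, y, C))), 1e-8)
  }
})

test_that("lasso equals LARS when no drop occurs, and drops restore eligibility", {
  prob <- random_single_scale(seed = 5, n = 150, p = 7)
  la <- ss_select(prob$design, prob$outcome, "lars", standardize = FALSE)
  lo <- ss_select(prob$design, prob$outcome, "lasso", standardize = FALSE)
  if (!"drop" %in% lo$steps$event) {
    expect_equal(la$steps, lo$steps)
    expect_equal(la$beta, lo$beta)
  }

  # seeded construction known to produce a drop event
  set.seed(2)
  n <- 50; p <- 5
  A <- matrix(rnorm(p * p), p)
  S <- cov2cor(crossprod(A) + 0.1 * diag(p))
  X <- matrix(rnorm(n * p), n, p) %*% chol(S)
  colnames(X) <- paste0("v", 1:p)
  y <- drop(X %*% rnorm(p, 0, 2)) + rnorm(n)
  std <- standardize_full(wrap_design(X), y)
  path <- ss_select(std$design, std$outcome, "lasso", standardize = FALSE)
  expect_true("drop" %in% path$steps$event)
  kdrop <- which(path$steps$event == "drop")[1]
  dropped <- path$steps$column[kdrop]
  expect_identical(unname(path$beta[kdrop, dropped]), 0)
  expect_false(dropped %in% path$active[[kdrop]])
  # KKT throughout, including around the drop
  for (k in seq_len(nrow(path$steps)))
    expect_lt(kkt_violation(std$design$X, std$outcome, path$beta[k, ],
                            path$active[[k]]), 1e-8)
})

test_that("min-AIC knot choice refits every knot and breaks ties early", {
  prob <- random_single_scale(seed = 30, n = 120, p = 6)
  path <- ss_select(prob$design, prob$outcome, "lars", standardize = FALSE)
  sel <- choose_min_aic(path)
  expect_equal(sel$aic, min(path$steps$aic))
  expect_equal(sel$step, which.min(path$steps$aic))

  # pure-noise candidates past the truth: a later knot must not win
  set.seed(31)
  n <- 300
  X <- cbind(sig = rnorm(n), matrix(rnorm(n * 4), n, 4))
  colnames(X)[2:5] <- paste0("noise", 1:4)
  y <- 1.5 * X[, "sig"] + rnorm(n)
  std <- standardize_full(wrap_design(X), y)
  path2 <- ss_select(std$design, std$outcome, "lars", standardize = FALSE)
  sel2 <- choose_min_aic(path2)
  expect_true("sig" %in% sel2$columns)
  expect_lt(sel2$step, nrow(path2$steps))

  # single-knot path chooses that knot
  d1 <- wrap_design(matrix(scale(rnorm(40)), dimnames = list(NULL, "v1")))
  y1 <- drop(scale(d1$X[, 1] + rnorm(40, 0, 0.2)))
  pal <- ss_select(d1, y1, "stepwise", standardize = FALSE)
  expect_equal(choose_min_aic(pal)$step, nrow(pal$steps))
})

test_that("the one-scale-per-concept invariant holds at every recorded step", {
  for (s in 1:6) {
    st <- standardized_study(small_scenario(seed = 100 + s))
    for (m in c("stepwise", "stagewise", "lars", "lasso")) {
      path <- ss_select(st$design, st$outcome, m, standardize = FALSE)
      for (k in seq_len(nrow(path$steps))) {
        act <- path$active[[k]]
        cns <- path$info$concept[match(act, path$info$column)]
        expect_false(anyDuplicated(cns) > 0,
                     label = paste(m, "step", k, "duplicated concept"))
      }
    }
  }
})

test_that("path objects support coef, predict, residuals and summaries", {
  st <- standardized_study(small_scenario(seed = 77))
  path <- ss_select(st$design, st$outcome, "lars", standardize = FALSE)
  b <- coef(path)
  expect_named(b, colnames(st$design$X))
  expect_equal(residuals(path), st$outcome - drop(st$design$X %*% b))
  s <- summary(path)
  expect_s3_class(s, "summary.ss_path")
  expect_equal(sum(s$scale_counts), length(selected_model(path)$columns))
  expect_output(print(path), "selection path")

  # predictions on raw-scale data go through the stored recipe
  raw <- build_candidate_design(st$sim$cohort, st$sim$area_tables,
                                st$sim$spec)
  path_raw <- ss_select(raw, st$sim$cohort$bmiz, "lars")
  pred <- predict(path_raw, raw)
  expect_equal(cor(pred, st$sim$cohort$bmiz) > 0.3, TRUE)
})
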