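# Independent textbook LARS, written in the homotopy-to-OLS form: at every
# step the active coefficients move toward their joint OLS value until an
# inactive predictor ties the active absolute correlation. Returns one knot
# row per variable entry plus the terminal (full OLS) knot. Kept deliberately
# separate from the package's path code: no eligibility logic, different
# direction parameterization.
oracle_lars <- function(X, y, max_steps = 50L) {
  p <- ncol(X)
  beta <- numeric(p)
  active <- integer(0)
  knots <- list()
  for (step in seq_len(max_steps)) {
    r <- y - drop(X %*% beta)
    cvec <- drop(crossprod(X, r))
    if (!length(active)) {
      active <- which.max(abs(cvec))
      knots[[length(knots) + 1L]] <- beta
      next
    }
    bols <- qr.coef(qr(X[, active, drop = FALSE]), y)
    d <- numeric(p)
    d[active] <- bols - beta[active]
    C <- max(abs(cvec[active]))
    a <- drop(crossprod(X, drop(X %*% d)))
    gam <- 1
    j_in <- NA_integer_
    for (j in setdiff(seq_len(p), active)) {
      for (g in c((C - cvec[j]) / (C - a[j]), (C + cvec[j]) / (C + a[j]))) {
        if (is.finite(g) && g > 1e-12 && g < gam - 1e-12) {
          gam <- g
          j_in <- j
        }
      }
    }
    beta <- beta + gam * d
    knots[[length(knots) + 1L]] <- beta
    if (is.na(j_in)) break
    active <- c(active, j_in)
  }
  do.call(rbind, knots)
}

# Soft-thresholded OLS for an orthogonal design with X'X = (n-1) I:
# beta_j(lambda) = soft(x_j'y / (n-1), lambda / (n-1)).
oracle_soft_threshold <- function(X, y, lambda) {
  n <- nrow(X)
  b <- drop(crossprod(X, y)) / (n - 1)
  sign(b) * pmax(abs(b) - lambda / (n - 1), 0)
}

# Lasso solution from glmnet at the penalty implied by a path knot
# (objective (1/2n)||y - Xb||^2 + lambda ||b||_1, so lambda = max|X'r| / n).
oracle_glmnet_at_knot <- function(X, y, beta_knot) {
  r <- y - drop(X %*% beta_knot)
  C <- max(abs(crossprod(X, r)))
  if (C < 1e-10) return(NULL)  # terminal OLS knot: penalty is zero
  fit <- glmnet::glmnet(X, y, lambda = C / nrow(X), standardize = FALSE,
                        intercept = FALSE, thresh = 1e-16)
  as.numeric(stats::coef(fit))[-1]
}

# KKT residual of a lasso knot: active columns must share the maximal
# absolute inner product with the residual; no eligible inactive column may
# exceed it. Returns the worst violation.
kkt_violation <- function(X, y, beta, active_cols) {
  r <- y - drop(X %*% beta)
  cv <- abs(drop(crossprod(X, r)))
  names(cv) <- colnames(X)
  if (!length(active_cols)) return(0)
  spread <- diff(range(cv[active_cols]))
  inact <- setdiff(colnames(X), active_cols)
  excess <- if (length(inact)) max(cv[inact]) - max(cv[active_cols]) else 0
  max(spread, excess, 0)
}

# Fraction of effect-bearing area concepts whose true-scale column is in the
# selected model.
scale_recovery <- function(selected, scenario) {
  eff <- scenario$effects[scenario$effects$scale != "individual", ]
  mean(paste(eff$concept, eff$scale, sep = "_") %in% selected$columns)
}
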