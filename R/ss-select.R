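#' Tuning parameters for the scale-selection algorithms
#'
#' @param epsilon minimum AIC improvement (in AIC units) required for forward
#'   stepwise to accept another variable. The default of 1 is conservative
#'   relative to the usual reading that an AIC difference of 4--7 is
#'   substantial.
#' @param step_size coefficient increment used by incremental forward
#'   stagewise.
#' @param tolerance stagewise stopping threshold on the largest absolute
#'   sample covariance between an eligible column and the current residual
#'   (equal to the correlation with the residual up to the residual's SD,
#'   since columns are standardized).
#' @param alpha significance level used for reporting and pruning.
#' @param max_steps cap on algorithm iterations (stagewise increments or
#'   path knots); exceeding it returns a truncated path, flagged as such.
#' @param thin stagewise paths record every `thin`-th increment besides all
#'   first-entry events and the terminal state.
#' @return list of class `ss_control`.
#' @export
ss_control <- function(epsilon = 1, step_size = 0.001, tolerance = 0.01,
                       alpha = 0.05, max_steps = 100000L, thin = 100L) {
  stopifnot(epsilon > 0, step_size > 0, tolerance > 0, tolerance < 1,
            alpha > 0, alpha < 1, max_steps >= 1)
  structure(list(epsilon = epsilon, step_size = step_size,
                 tolerance = tolerance, alpha = alpha,
                 max_steps = as.integer(max_steps), thin = as.integer(thin)),
            class = "ss_control")
}

#' Columns still allowed to enter the model
#'
#' The scale-selection constraint: once any column of a concept is active,
#' that concept's other scales (its "siblings") may not enter. Eligible
#' columns are those that are not active, not explicitly excluded, and whose
#' concept has no active column.
#'
#' @param design a `candidate_design` (only its column metadata is used).
#' @param active character vector of active column names.
#' @param excluded character vector of additionally excluded column names.
#' @return character vector of eligible column names, in variable-number
#'   order.
#' @export
eligible_columns <- function(design, active = character(),
                             excluded = character()) {
  info <- if (inherits(design, "candidate_design")) design$info else design
  if (length(intersect(active, excluded)))
    stop("active and excluded sets overlap")
  blocked_concepts <- info$concept[info$column %in% active]
  ok <- !(info$column %in% active) & !(info$column %in% excluded) &
    !(info$concept %in% blocked_concepts)
  info$column[ok][order(info$number[ok])]
}

# integer-index version used inside the algorithms: returns eligible column
# indices in number order, given logical active vector
.eligible_idx <- function(info, active_idx) {
  blocked <- info$concept %in% info$concept[active_idx]
  ok <- which(!blocked)               # active columns are blocked too
  ok[order(info$number[ok])]
}

#' Fit a spatial-scale selection path
#'
#' The central fitting function. Runs one of four variable-selection path
#' algorithms — forward stepwise, incremental forward stagewise, least angle
#' regression (LARS), or the lasso — under the constraint that each
#' conceptual covariate may be active at exactly one spatial scale at any
#' point along the path. Inputs are standardized (outcome and predictors to
#' mean 0, SD 1) so the model has no intercept; by default this is done
#' internally and the recipe stored for back-transformation.
#'
#' The final model differs by algorithm, following how each is tuned:
#' stepwise stops when no candidate improves AIC by at least `epsilon` and
#' its last accepted step is the model; stagewise runs until the largest
#' residual covariance falls below `tolerance` and its terminal nonzero set
#' is the model; for LARS and the lasso the model is the path knot with the
#' minimum OLS-based AIC (see [choose_min_aic()]).
#'
#' @param design a `candidate_design` from [build_candidate_design()].
#' @param outcome numeric outcome vector.
#' @param method one of `"stepwise"`, `"stagewise"`, `"lars"`, `"lasso"`.
#' @param control an [ss_control()].
#' @param standardize if `TRUE` (default) standardize design and outcome
#'   internally; set `FALSE` when inputs are already standardized.
#' @return Object of class `ss_path`: a list with `steps` (one row per
#'   recorded knot: step, event, column, concept, scale, aic), `beta`
#'   (knots x p coefficient matrix on the standardized scale), `active`
#'   (active-column list per knot), `method`, `control`, `recipe`, and the
#'   standardized `X`, `y` used for refits.
#' @seealso [selected_model()], [choose_min_aic()], [refit_ols()]
#' @export
ss_select <- function(design, outcome,
                      method = c("stepwise", "stagewise", "lars", "lasso"),
                      control = ss_control(), standardize = TRUE) {
  method <- match.arg(method)
  stopifnot(inherits(design, "candidate_design"),
            length(outcome) == nrow(design$X))
  recipe <- NULL
  if (standardize) {
    std <- standardize_full(design, outcome)
    X <- std$design$X; y <- std$outcome; recipe <- std$recipe
  } else {
    X <- design$X; y <- as.numeric(outcome)
    mu <- max(abs(colMeans(X)), abs(mean(y)))
    if (mu > 1e-6)
      stop("standardize = FALSE but inputs are not centered; ",
           "use standardize_full() first")
  }
  info <- design$info
  path <- switch(method,
                 stepwise = .path_stepwise(X, y, info, control),
                 stagewise = .path_stagewise(X, y, info, control),
                 lars = .path_lars(X, y, info, control, lasso = FALSE),
                 lasso = .path_lars(X, y, info, control, lasso = TRUE))
  structure(c(path,
              list(method = method, control = control, recipe = recipe,
                   info = info, X = X, y = y, ids = design$ids,
                   call = match.call())),
            class = "ss_path")
}

# rss and coefficients of a no-intercept OLS on selected columns
.ols <- function(X, y, idx) {
  if (!length(idx)) return(list(coef = numeric(0), rss = sum(y^2), rank = 0L))
  fit <- stats::lm.fit(X[, idx, drop = FALSE], y)
  list(coef = fit$coefficients, rss = sum(fit$residuals^2), rank = fit$rank)
}

.knot_aic <- function(X, y, idx) {
  f <- .ols(X, y, idx)
  if (f$rank < length(idx)) return(NA_real_)
  suppressWarnings(ols_aic(f$rss, nrow(X), length(idx)))
}

.path_stepwise <- function(X, y, info, ctl) {
  n <- nrow(X); p <- ncol(X)
  active <- integer(0)
  aic_cur <- ols_aic(sum(y^2), n, 0L)
  steps <- list(); beta <- list(); act <- list()
  repeat {
    elig <- .eligible_idx(info, active)
    if (!length(elig) || length(steps) >= ctl$max_steps) break
    cand_aic <- rep(Inf, length(elig))
    for (i in seq_along(elig)) {
      f <- .ols(X, y, c(active, elig[i]))
      if (f$rank == length(active) + 1L)
        cand_aic[i] <- suppressWarnings(ols_aic(f$rss, n, f$rank))
    }
    best <- which.min(cand_aic)  # elig is in number order: earliest wins ties
    if (!(aic_cur - cand_aic[best] >= ctl$epsilon)) break
    active <- c(active, elig[best])
    aic_cur <- cand_aic[best]
    b <- numeric(p); f <- .ols(X, y, active); b[active] <- f$coef
    steps[[length(steps) + 1L]] <- data.frame(
      step = length(steps) + 1L, event = "enter",
      column = info$column[elig[best]], aic = aic_cur)
    beta[[length(beta) + 1L]] <- b
    act[[length(act) + 1L]] <- info$column[active]
  }
  .assemble_path(steps, beta, act, info, p, truncated = FALSE)
}

.path_stagewise <- function(X, y, info, ctl) {
  n <- nrow(X); p <- ncol(X)
  G <- crossprod(X)
  cvec <- drop(crossprod(X, y))
  denom <- n - 1
  betav <- numeric(p)
  claimed_concept <- character(0)      # concepts with a designated column
  rep_col <- integer(0)                # the designated column per concept
  steps <- list(); beta <- list(); act <- list()
  ord <- order(info$number)
  record <- function(event, col_idx) {
    a <- sort(rep_col)
    steps[[length(steps) + 1L]] <<- data.frame(
      step = length(steps) + 1L, event = event,
      column = if (is.na(col_idx)) NA_character_ else info$column[col_idx],
      aic = .knot_aic(X, y, a))
    beta[[length(beta) + 1L]] <<- betav
    act[[length(act) + 1L]] <<- info$column[a]
  }
  it <- 0L; truncated <- FALSE
  repeat {
    if (it >= ctl$max_steps) { truncated <- TRUE; break }
    chat <- cvec / denom
    elig <- ord[!(info$concept[ord] %in% claimed_concept) |
                  ord %in% rep_col]
    if (!length(elig)) break
    j <- elig[which.max(abs(chat[elig]))]
    if (abs(chat[j]) < ctl$tolerance) break
    it <- it + 1L
    s <- sign(chat[j])
    new_entry <- !(j %in% rep_col)
    if (new_entry) {
      claimed_concept <- c(claimed_concept, info$concept[j])
      rep_col <- c(rep_col, j)
    }
    betav[j] <- betav[j] + ctl$step_size * s
    cvec <- cvec - ctl$step_size * s * G[, j]
    if (new_entry) record("enter", j)
    else if (it %% ctl$thin == 0L) record("increment", j)
  }
  if (length(steps)) record("terminal", NA_integer_)
  .assemble_path(steps, beta, act, info, p, truncated = truncated)
}

.path_lars <- function(X, y, info, ctl, lasso) {
  n <- nrow(X); p <- ncol(X)
  eps <- 1e-12
  betav <- numeric(p)
  r <- y
  active <- integer(0)
  steps <- list(); beta <- list(); act <- list()
  record <- function(event, col_idx) {
    a <- sort(active)
    steps[[length(steps) + 1L]] <<- data.frame(
      step = length(steps) + 1L, event = event,
      column = if (is.na(col_idx)) NA_character_ else info$column[col_idx],
      aic = .knot_aic(X, y, a))
    beta[[length(beta) + 1L]] <<- betav
    act[[length(act) + 1L]] <<- info$column[a]
  }
  truncated <- FALSE
  # initial entry
  cvec <- drop(crossprod(X, r))
  elig <- .eligible_idx(info, active)
  if (length(elig) && max(abs(cvec[elig])) > eps * n) {
    j0 <- elig[which.max(abs(cvec[elig]))]
    active <- j0
    record("enter", j0)
    repeat {
      if (length(steps) >= ctl$max_steps) { truncated <- TRUE; break }
      cvec <- drop(crossprod(X, r))
      C <- max(abs(cvec[active]))
      if (C < eps * n) { record("terminal", NA_integer_); break }
      s <- sign(cvec[active])
      Xa <- X[, active, drop = FALSE]
      Ga <- crossprod(Xa)
      Gis <- tryCatch(solve(Ga, s), error = function(e)
        stop("rank-deficient active set at columns: ",
             paste(info$column[active], collapse = ", ")))
      AA <- 1 / sqrt(sum(s * Gis))
      w <- AA * Gis                       # coefficient-space direction
      u <- drop(Xa %*% w)                 # unit equiangular vector
      elig <- setdiff(.eligible_idx(info, active), active)
      gamma_in <- Inf; j_in <- NA_integer_
      if (length(elig)) {
        a <- drop(crossprod(X[, elig, drop = FALSE], u))
        cj <- cvec[elig]
        g1 <- (C - cj) / (AA - a)
        g2 <- (C + cj) / (AA + a)
        g <- pmin(ifelse(g1 > eps, g1, Inf), ifelse(g2 > eps, g2, Inf))
        if (any(is.finite(g))) {
          gamma_in <- min(g)
          j_in <- elig[which(g <= gamma_in + eps)][1L]  # number-order ties
        }
      }
      gamma_full <- C / AA
      gamma_drop <- Inf; j_drop <- NA_integer_
      if (lasso) {
        gd <- -betav[active] / w
        ok <- which(gd > eps)
        if (length(ok)) {
          gamma_drop <- min(gd[ok])
          j_drop <- active[ok[which.min(gd[ok])]]
        }
      }
      gamma <- min(gamma_in, gamma_full, gamma_drop)
      betav[active] <- betav[active] + gamma * w
      r <- r - gamma * u
      if (lasso && gamma_drop <= min(gamma_in, gamma_full) - eps) {
        betav[j_drop] <- 0
        active <- setdiff(active, j_drop)   # concept becomes eligible again
        record("drop", j_drop)
        if (!length(active)) {
          cvec <- drop(crossprod(X, r))
          elig <- .eligible_idx(info, active)
          if (!length(elig) || max(abs(cvec[elig])) < eps * n) break
          j0 <- elig[which.max(abs(cvec[elig]))]
          active <- j0
          record("enter", j0)
        }
      } else if (gamma_in <= gamma_full + eps && is.finite(gamma_in)) {
        active <- c(active, j_in)
        record("enter", j_in)
      } else {
        record("terminal", NA_integer_)    # reached the active-set OLS fit
        break
      }
    }
  }
  .assemble_path(steps, beta, act, info, p, truncated = truncated)
}

.assemble_path <- function(steps, beta, act, info, p, truncated) {
  if (length(steps)) {
    steps <- do.call(rbind, steps)
    i <- match(steps$column, info$column)
    steps$concept <- info$concept[i]
    steps$scale <- info$scale[i]
    steps <- steps[, c("step", "event", "column", "concept", "scale", "aic")]
    B <- do.call(rbind, beta)
    colnames(B) <- info$column
  } else {
    steps <- data.frame(step = integer(), event = character(),
                        column = character(), concept = character(),
                        scale = character(), aic = numeric())
    B <- matrix(numeric(0), 0L, p, dimnames = list(NULL, info$column))
  }
  list(steps = steps, beta = B, active = act, truncated = truncated)
}

#' Choose the minimum-AIC knot of a selection path
#'
#' Refit-based model choice along a path: every recorded knot's active set is
#' refit by OLS (done once, when the path is built) and the knot with the
#' smallest AIC is chosen; ties go to the earliest knot.
#'
#' @param path an `ss_path`.
#' @return An `ss_model`: list with `step` (chosen knot), `columns` (active
#'   columns there), `path_coef` (path coefficients at that knot, standardized
#'   scale), `aic`, and the parent path's method and metadata.
#' @export
choose_min_aic <- function(path) {
  stopifnot(inherits(path, "ss_path"))
  if (!nrow(path$steps)) stop("empty selection path")
  aic <- path$steps$aic
  k <- which(aic == min(aic, na.rm = TRUE))[1L]
  .make_model(path, k)
}

.make_model <- function(path, k) {
  cols <- path$active[[k]]
  structure(list(step = k, columns = cols,
                 path_coef = path$beta[k, cols],
                 aic = path$steps$aic[k],
                 method = path$method, info = path$info,
                 control = path$control), class = "ss_model")
}

#' Extract the final model implied by each algorithm's stopping rule
#'
#' Stepwise paths end at their last accepted step; stagewise paths end at
#' their terminal increment; LARS and lasso paths are scanned for the
#' minimum-AIC knot.
#'
#' @param path an `ss_path`.
#' @return An `ss_model` (see [choose_min_aic()]); for an empty path, a model
#'   with no columns.
#' @export
selected_model <- function(path) {
  stopifnot(inherits(path, "ss_path"))
  if (!nrow(path$steps))
    return(structure(list(step = 0L, columns = character(),
                          path_coef = numeric(), aic = NA_real_,
                          method = path$method, info = path$info,
                          control = path$control), class = "ss_model"))
  switch(path$method,
         stepwise = .make_model(path, nrow(path$steps)),
         stagewise = .make_model(path, nrow(path$steps)),
         choose_min_aic(path))
}

#' @export
print.ss_model <- function(x, ...) {
  cat("Scale-selected model (", x$method, "), ",
      length(x$columns), " terms\n", sep = "")
  if (length(x$columns)) {
    df <- data.frame(column = x$columns,
                     path_coef = round(unname(x$path_coef), 4))
    print(df, row.names = FALSE)
  }
  invisible(x)
}

#' @export
print.ss_path <- function(x, ...) {
  cat("Spatial-scale selection path: ", x$method, "\n", sep = "")
  cat("  candidates: ", ncol(x$beta), " columns, ",
      length(unique(x$info$concept)), " concepts\n", sep = "")
  cat("  recorded knots: ", nrow(x$steps),
      if (isTRUE(x$truncated)) " (truncated at max_steps)", "\n", sep = "")
  sel <- selected_model(x)
  cat("  selected terms: ", length(sel$columns), "\n", sep = "")
  invisible(x)
}

#' @export
summary.ss_path <- function(object, ...) {
  sel <- selected_model(object)
  tab <- table(factor(object$info$scale[match(sel$columns,
                                              object$info$column)],
                      levels = c("individual", "CBK", "CBG", "CT")))
  out <- list(method = object$method, steps = object$steps,
              selected = sel, scale_counts = tab,
              truncated = object$truncated)
  class(out) <- "summary.ss_path"
  out
}

#' @export
print.summary.ss_path <- function(x, ...) {
  cat("Spatial-scale selection (", x$method, ")\n", sep = "")
  cat("Selected columns per scale:\n")
  print(x$scale_counts)
  cat("\nPath events:\n")
  ev <- x$steps[x$steps$event %in% c("enter", "drop"), ]
  print(ev[, c("step", "event", "column", "aic")], row.names = FALSE)
  invisible(x)
}

#' @export
coef.ss_path <- function(object, step = NULL, ...) {
  if (is.null(step)) {
    sel <- selected_model(object)
    b <- structure(numeric(ncol(object$beta)), names = colnames(object$beta))
    b[sel$columns] <- sel$path_coef
    b
  } else object$beta[step, ]
}

#' @export
coef.ss_model <- function(object, ...) object$path_coef

#' Plot coefficient paths
#'
#' Draws the coefficient trajectory of every candidate column against path
#' step, coloured by spatial scale (individual black, CBG red, CT green, CBK
#' blue), mirroring the conventional display of scale-selection paths.
#'
#' @param x an `ss_path`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.ss_path <- function(x, ...) {
  if (!nrow(x$beta)) {
    warning("empty path; nothing to plot")
    return(invisible(x))
  }
  colmap <- c(individual = "black", CBG = "red", CT = "darkgreen",
              CBK = "blue")
  cols <- colmap[x$info$scale[match(colnames(x$beta), x$info$column)]]
  graphics::matplot(x$steps$step, x$beta, type = "l", lty = 1, col = cols,
                    xlab = "Path step", ylab = "Standardized coefficient",
                    main = paste("SS", x$method, "coefficient paths"), ...)
  sel <- selected_model(x)
  if (sel$step > 0L) graphics::abline(v = sel$step, lty = 3)
  invisible(x)
}

#' @export
predict.ss_path <- function(object, design = NULL, ...) {
  b <- coef(object)
  if (is.null(design)) return(drop(object$X %*% b))
  X <- if (inherits(design, "candidate_design")) design$X else
    as.matrix(design)
  if (!is.null(object$recipe)) {
    i <- match(colnames(X), object$recipe$columns$column)
    X <- sweep(sweep(X, 2L, object$recipe$columns$center[i]), 2L,
               object$recipe$columns$divisor[i], "/")
    yhat <- drop(X %*% b[colnames(X)])
    yhat * object$recipe$outcome$divisor + object$recipe$outcome$center
  } else drop(X %*% b[colnames(X)])
}

#' @export
residuals.ss_path <- function(object, ...) {
  drop(object$y - object$X %*% coef(object))
}
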