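# Wrap a plain numeric matrix as a candidate design whose columns are all
# individual-level (no sibling structure).
wrap_design <- function(X) {
  if (is.null(colnames(X)) || anyDuplicated(colnames(X)) ||
      any(colnames(X) == ""))
    colnames(X) <- paste0("v", seq_len(ncol(X)))
  coh <- as.data.frame(X)
  coh$cbk_id <- coh$cbg_id <- coh$ct_id <- "u1"
  build_candidate_design(coh, list(),
                         variable_spec(individual = colnames(X)))
}

# Hand-built candidate design with explicit concept/scale metadata, for
# sibling-constraint fixtures.
meta_design <- function(X, concept, scale) {
  stopifnot(ncol(X) == length(concept), length(concept) == length(scale))
  colnames(X) <- ifelse(scale == "individual", concept,
                        paste(concept, scale, sep = "_"))
  structure(list(X = X,
                 info = data.frame(column = colnames(X), concept = concept,
                                   scale = scale,
                                   number = seq_along(concept)),
                 ids = data.frame(cbk_id = rep("u1", nrow(X)),
                                  cbg_id = "u1", ct_id = "u1")),
            class = "candidate_design")
}

# Random standardized single-scale regression problem (every concept at one
# scale, so the constraint never binds).
random_single_scale <- function(seed, n = 200, p = 6, snr = 2) {
  set.seed(seed)
  A <- matrix(stats::rnorm(p * p), p)
  S <- stats::cov2cor(crossprod(A) + 0.1 * diag(p))
  X <- matrix(stats::rnorm(n * p), n, p) %*% chol(S)
  colnames(X) <- paste0("v", seq_len(p))
  beta <- stats::rnorm(p, 0, snr) * stats::rbinom(p, 1, 0.6)
  y <- drop(X %*% beta) + stats::rnorm(n)
  std <- standardize_full(wrap_design(X), y)
  list(design = std$design, outcome = std$outcome)
}

# Orthogonal standardized design: columns mean 0, sample SD 1, X'X = (n-1) I.
orthogonal_design <- function(seed, n = 100, p = 5) {
  set.seed(seed)
  X <- stats::poly(seq_len(n) + stats::runif(n, -0.2, 0.2), p)
  X <- sweep(scale(X, scale = FALSE), 2L, apply(X, 2, stats::sd), "/")
  colnames(X) <- paste0("v", seq_len(p))
  unclass(X)
}

# Small multi-scale synthetic study for constraint / recovery checks.
small_scenario <- function(seed, n = 400, n_ct = 30) {
  synthetic_scenario(n_ct = n_ct, cbg_per_ct = 2L, cbk_per_cbg = 1L,
                     n = n, seed = seed)
}

standardized_study <- function(scenario) {
  sim <- simulate_study(scenario)
  d <- build_candidate_design(sim$cohort, sim$area_tables, sim$spec)
  c(standardize_full(d, sim$cohort$bmiz),
    list(sim = sim, design_raw = d))
}
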