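---
title: "Selecting the spatial scale of neighborhood covariates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting the spatial scale of neighborhood covariates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spscale)
```

## The problem and the model

Individual outcomes such as a pediatric BMI z-score depend both on
individual characteristics and on attributes of the place of residence.
Neighborhood attributes are published at several nested census geographies —
block (CBK), block group (CBG), tract (CT) — and there is rarely a priori
knowledge of which scale is the right one for a given covariate. Forcing all
area-level covariates to one common scale (the traditional approach) can
attenuate or distort effects that truly operate at a different scale.

`spscale` frames the scale choice as constrained variable selection. Each
substantive covariate is a *concept* with one candidate column per scale at
which it is observed; the candidate design matrix contains all columns of
all concepts plus the individual-level covariates. The working model is the
Gaussian linear model

$$ y_i = \sum_j \beta_j x_{ij} + b_{g(i)} + b_{t(i)} + \varepsilon_i, $$

where the $x_{ij}$ are candidate columns, $b_g$ and $b_t$ are optional
random intercepts at the block-group and tract level, and selection must
activate at most one column per concept. The assumptions are those of any
linear exposure model at this resolution: additive effects, homoscedastic
residuals, and area effects that are constant within a unit (everyone in a
block group experiences that block group's value).

## The four path algorithms and the eligibility constraint

All four algorithms run on fully standardized data: outcome and every
column centered and scaled to unit sample SD (denominator $n-1$
throughout the package), which removes the intercept — a convenience for
the lasso in particular. Eligibility is the shared ingredient: a column may
enter only if its concept has no active column. The constraint is enforced
at entry for stepwise, LARS and lasso, and at the first coefficient
increment for stagewise. After a lasso drop the concept's columns all
become eligible again; a permanent ban would let one early step disqualify
a concept forever, which is not what the penalized problem does. Sibling
scales compete simultaneously — no pre-screening decides a concept's scale
before the algorithms run; the data decide at each step.

- **Forward stepwise** tries every eligible column by OLS on the enlarged
  active set and accepts the AIC-minimizing candidate if it improves AIC by
  at least $\varepsilon$ (default 1 AIC unit). The comparison is against the
  *current* model's AIC, not a best-so-far value: the path is monotone in
  AIC by construction so the two readings coincide until the stop, and the
  current-model reading is the simpler contract. The selected model is the
  last accepted step.
- **Incremental forward stagewise** computes residual covariances
  $c_j = x_j^\top r /(n-1)$, increments the argmax eligible coefficient by
  $\delta\,\mathrm{sign}(c_j)$ with $\delta = 0.001$, and stops when
  $\max_j |c_j|$ falls below the tolerance 0.01. Its terminal coefficient
  vector is the selected model — no AIC scan — because the tolerance is
  itself the stopping rule for this algorithm. On orthogonal designs the
  terminal coefficients are within one step of the soft-thresholded OLS
  solution at the tolerance level, which the tests verify.
- **LARS** moves the active coefficients along the equiangular direction
  (computed from the active Gram matrix) until an eligible inactive column
  ties the active absolute correlation; each knot records the active set,
  coefficients, and the OLS-based AIC of the active set.
- **Lasso** adds the drop step: when an active coefficient path crosses
  zero the column leaves at that knot and the direction is recomputed. At
  every knot the active columns share the maximal absolute inner product
  with the residual and no eligible inactive column exceeds it (the KKT
  conditions, asserted to 1e-8 in the tests). When no drop occurs, LARS and
  lasso paths are identical.

For LARS and the lasso the reported model is the minimum-AIC knot (earliest
knot on ties). The AIC convention is the profiled Gaussian form
$n\log(\mathrm{RSS}/n) + 2(k+1)$, counting the residual variance as a
parameter and omitting the $n(\log 2\pi + 1)$ constant; comparisons that
must cross likelihood families (OLS versus mixed models) use the full
$-2\ell + 2\,\mathrm{npar}$ form instead, so the two are never mixed.

Ties anywhere — correlation ties at entry, AIC ties along a path — break by
the smallest variable number in the candidate listing, making every path
deterministic and reproducible. Degenerate inputs are handled explicitly: a
zero-variance column is an error naming the column, a rank-deficient active
set is an error naming the columns, stepwise skips candidates that would
make the active set singular, and a path that exceeds `max_steps` is
returned with a truncation flag rather than an error. Stagewise paths
record every first entry, every 100th increment, and the terminal state;
intermediate increments carry no information about entry order, so thinning
loses nothing that downstream analysis uses.

## Standardization schemes

Two schemes are used for two purposes. Scale selection uses *full*
standardization (outcome and predictors to mean 0, SD 1). Interaction
models keep the outcome raw and rescale predictors per Gelman: dummies are
centered only, continuous columns are centered and divided by **two** SDs,
so binary and continuous coefficients are both read as a low-to-high
contrast and interaction coefficients are on a comparable footing. Both
schemes are recorded as invertible recipes. Area covariates are
standardized within the analysis sample (rather than over the full
geography): the analysis sample is what the model sees, and the recipe
records the choice so it can be revisited.

## Exclusion rules

The cohort filter applies the study's three rules sequentially —
underweight, then race restriction, then missing values — attributing each
removed row to the first rule it trips, so the per-rule counts always sum
to the number removed. Whether the three groups overlapped in any given raw
dataset is unknowable from published counts alone; the sequential semantics
is a declared convention that makes the arithmetic reproducible.
Underweight is implemented on the z-score scale as
$z < \Phi^{-1}(0.05) \approx -1.6449$, since a BMI-for-age below the fifth
percentile is exactly this threshold once the outcome is an age/sex
z-score; the cutoff is a parameter for other references.

## Mixed models and interactions

Random intercepts are fit by maximum likelihood (not REML) through `lme4`,
because the AIC comparisons change the fixed-effect set and REML
likelihoods are not comparable across fixed-effect sets. "Both" means
nested intercepts (CBG within CT) — the geography is strictly nested, so
crossed effects are not offered, and a non-nested grouping is an error.
Fixed-effect p-values are Wald z tests, the conventional companion of ML
estimates; group intercept predictions are the conditional modes (EBLUPs).
Variance components are non-negative by `lme4`'s parameterization of
standard deviations.

The interaction workflow builds the nine clinician-specified products
(male and black each crossed with population density, median household
income, park density, and exercise equipment; distance to the medical
center crossed with median income) on Gelman-rescaled parents. Products are
not re-rescaled and parents are never re-centered, so removing a product
leaves every other column bit-identical. The male indicator is
force-included even when not algorithm-selected, as a covariate of declared
substantive importance; parents of pairs whose concept was not selected
enter at the tract scale, the largest available. Pruning is one pass at
$\alpha = 0.05$ (the `+` mark at p < 0.1 is report-only): interactions with
p below the threshold are kept with all main effects, and the reduced model
is refit once. Main effects present before pruning stay in the model
whether or not their interactions survive.

## What the synthetic generator emulates — and what it does not

The generator produces a strictly nested geography with opaque identifiers,
area covariates that are standard normal at every scale with a single
cross-scale correlation $\rho$ induced top-down (a block group's value is
$\rho$ times its tract's value plus independent noise — finer measures as
noisy refinements of coarser ones), and a cohort whose outcome is linear in
population-standardized covariates at declared true scales, plus Gaussian
random intercepts and residual noise. A raw variant plants configured
numbers of exclusion-triggering rows (and reflects accidental underweight
z-scores above the cutoff) so filter arithmetic is exact by construction.

Default scenario values are chosen as a realistic mid-size registry
extract: 5,000 visits over 150 tracts × 3 block groups × 2 blocks,
$\rho = 0.7$ (neighboring census scales are strongly but not perfectly
correlated), standardized effects between 0.05 and 0.25 split between
tract-level and block-group-level truth, random-intercept SDs of 0.1, and
residual SD 0.9 for an outcome with roughly unit variance. Effect sizes
are set so that single-scale signals are detectable at these unit counts:
with a few hundred area units, standardized effects of 0.1–0.25 give the
selection algorithms a fair but not trivial discrimination task, whereas
effects of real published analyses (0.01–0.08 at tens of thousands of
observations and thousands of units) would require geographies far larger
than a test suite should build.

The generator deliberately omits several features of real data: spatial
autocorrelation between neighboring units (covariates are exchangeable
across units given the hierarchy), non-Gaussian covariate marginals, repeat
visits by the same child, and measurement error in the outcome. Passing
tests therefore demonstrate that the algorithms recover truth under the
stated hierarchical model, not that they are robust to adjacency structure
or longitudinal correlation.

## Validation suite sizes

The test suite exercises: oracle equivalence of the LARS/lasso paths
against an independent textbook LARS implementation and `glmnet` at the
knot penalties (20 random single-scale designs, $n \le 400$, $p \le 10$,
agreement to 1e-6); the one-scale-per-concept invariant over 50 seeded
multi-scale scenarios for all four algorithms; true-scale recovery at the
default scenario over 50 replicates (median recovery required ≥ 90% per
algorithm); the AIC advantage of scale-selected over single-scale
constrained fits over 20 replicates; random-effect placement and
variance-component recovery with 200 block groups × 20 observations (20
and 50 replicates respectively). These sizes keep the full suite around a
minute on a single core while leaving each property's sampling error well
inside its margin.

## Known limitations

The OLS p-values attached to path-selected covariate sets are approximate:
no post-selection correction is applied, matching standard practice for
these workflows. Cross-validated penalty choice, forced-in confounders
inside the path algorithms, interaction selection within the paths, and
spatially correlated random effects are out of scope. The percent-change
report compares coefficient magnitudes and is undefined for a zero
reference coefficient, where it returns `NA`.
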