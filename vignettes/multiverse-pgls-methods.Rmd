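---
title: "Methods: multiverse stability analysis for PGLS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiverse stability analysis for PGLS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pglsverse)
```

## The question the package answers

In phylogenetic comparative analysis it is routine to regress a trait —
brain size, say — on several candidate predictors with PGLS, report the
AIC-best model, and interpret the significant slopes. When the candidate
predictors covary substantially with each other and with the mandatory
body-size covariate, and the sample is a few dozen species, that workflow
is fragile: the slope and p-value assigned to a predictor depend on which
*concomitant* predictors share the model with it. `pglsverse` treats the
full set of predictor subsets as the object of analysis. For k candidates
it fits all 2^k − 1 non-empty subsets (each including the mandatory
covariate and an intercept), and summarises per predictor (a) in how many
of its 2^(k−1) models it was non-significant and (b) the extreme p-values
it attained and under which concomitant sets. A wide p-range straddling
the significance threshold is the quantitative signature of an unstable
conclusion.

## Model and estimation

Each model is `y = Xβ + ε`, `ε ~ N(0, σ² V(λ))`, where `V` is the
Brownian-motion covariance of the phylogeny (entry i,j = branch length
shared from the root to the MRCA of species i and j) and `V(λ)` rescales
the off-diagonal by Pagel's λ. The GLS estimate is computed by Cholesky
whitening: with `V(λ) = LLᵀ`, the model is transformed by `L⁻¹` and solved
by QR. No explicit matrix inverse is formed; the whitened route agrees
with a dense-inverse oracle to ~1e−15 in the tests, and with
`nlme::gls` + `ape::corPagel` to 1e−8.

**λ estimation.** The profile log-likelihood is evaluated on a 0.05-step
grid over [0, 1], then refined by `stats::optimize` in the bracketing
interval; the refined optimum is compared against the best grid point and
the exact boundaries, and the tests verify the result dominates a
0.01-step grid. λ is restricted to [0, 1] because values above 1 can
break positive semidefiniteness. When the profile cannot be evaluated,
the optimizer fails, or the profile is flat (λ is unidentifiable — e.g. a
star phylogeny, where every λ gives the same OLS fit), the fit falls back
to λ = 1 and flags it (`lambda_fixed = TRUE`) with a warning rather than
aborting; in a 63-model run a single model's fallback is a logged note,
not a failure. This mirrors how practitioners in this field handle
near-boundary optimization crashes.

**Likelihood and AIC.** Likelihoods are ML, not REML: AIC comparisons
across models with different fixed-effect sets are only valid under ML,
and the multiverse exists to make exactly such comparisons. AIC uses
k = (#terms incl. intercept) + 1 for σ² + 1 for λ *only when estimated*: a
λ fixed by policy or fallback is not an estimated parameter, and the rule
is applied uniformly so rankings stay comparable. Ties in AIC break
toward fewer focal predictors, then enumeration order (by subset size,
then lexicographically in the candidate order given) — the single
deterministic tie-break rule used everywhere; the module has no RNG.

**Inference conventions.** t statistics use standard errors from the
unbiased whitened residual variance s² = RSSw/(n − p) and a t reference
with df = n − p, the convention of standard GLS summaries; σ² stored on
the fit is the ML estimate RSSw/n. The prediction interval for a new
observation is `x₀ᵀb ± t · sqrt(s²·s̄ + x₀ᵀCov(b)x₀)` with s̄ the mean
diagonal of V(λ): the new taxon's phylogenetic position is deliberately
not modeled (no covariance with training species), which is the honest
choice when predicting for a taxon outside the tree, and under V = I this
reduces exactly to the OLS closed-form interval — the identity the tests
assert, and the reason the unbiased s² (not the ML σ²) enters the
interval. R² is the squared Pearson correlation between fitted and
observed values; under a phylogenetic error structure this is a crude
descriptive quantity, reported because it is the field's convention, not
a likelihood-based measure.

## The shared species set

One complete-case species set — complete on the outcome, the mandatory
covariate, and *all* candidates, intersected with the tree — is computed
once and shared by all models. Per-model complete cases would let N vary
across models, making AIC values incomparable and the stability summaries
confounded with sample changes; the single-N design is also what lets one
N be reported for every table. The cost is that a predictor with much
missing data shrinks every model's sample, which is surfaced in the
dropped-species report.

## Stability summaries

Non-significance counts use strict `p > alpha` (alpha defaults to 0.05;
`p = alpha` counts as significant, matching the convention of reporting
"(p > 0.05)"). No multiple-testing correction is applied anywhere — the
analysis reproduces the field's practice and the alpha-inflation caveat
belongs in interpretation, not silently in the machinery. Concomitant
sets listed with the min/max p exclude the focal predictor itself and the
mandatory covariate (present in every model, so listing it carries no
information). Both summaries are pure functions of the flat fits table
and the tests recompute them from the exported CSV.

## Collinearity diagnostics

*VIF.* OLS VIF is the textbook 1/(1 − R²_j). "PGLS VIF" has no canonical
definition; here it is defined as OLS VIF computed on the whitened design
`L⁻¹[1, X]` (intercept column whitened too, and used as the projection
base) — collinearity as the fitted GLS actually experiences it. With
V = I or any star tree the two coincide exactly. VIF > 10 is flagged in
reports but gates nothing.

*Partial R².* `(RSS_reduced − RSS_full)/RSS_reduced` in the whitened
space at the full model's λ. Not additive across collinear terms, and the
tests assert the non-additivity.

*Posterior slope correlations.* The diagnostic target is whether slope
posteriors are entangled (when β₁ rises, β₂ must fall), the signature of
weak identifiability. Rather than running an MCMC sampler — which on this
class of problem mixes poorly precisely when collinearity is severe — the
package draws from the exact Normal–Inverse-Gamma conjugate posterior of
the whitened model under the reference prior p(b, σ²) ∝ 1/σ²:
σ²|y ~ Inv-Gamma((n−p)/2, RSSw/2), b|σ²,y ~ N(b̂, σ²(XwᵀXw)⁻¹). This is a
deliberate methodological substitution: same diagnostic, closed form, no
mixing pathology, bit-reproducible by seed. For two standardized
predictors with correlation r on a star tree the slope correlation is −r,
a closed form the tests check to 0.05 at 10⁴ draws.

## Data assembly

`pool_weighted` combines multi-source tables cell-wise by weighted mean
over the sources reporting that cell. Weights are the caller's choice
(per-source sample sizes where known are the natural choice; equal
weights are the default) and are recorded in the provenance attribute,
because pooled literature data are only interpretable with their
provenance. Transforms follow comparative practice: natural log for
sizes, counts and durations (natural rather than base-10 so slopes are
elasticities; the choice is recorded per column), and arcsine-square-root
for percentage variables, dividing by 100 first since asin is undefined
beyond 1. Transform state is tracked per column and double application is
an error, not a silent compounding. Lifespan is derived as maximum
recorded age minus age at sexual maturity, before the log; a non-positive
difference is treated as a data error.

## The synthetic generator and what it does (not) show

`simulate_tree` draws pure-birth trees rescaled to unit depth
(ultrametric, so the VCV diagonal is 1 and rates read as variances).
`simulate_predictors` uses a matrix-normal construction — among-species
covariance V(λ_pred), among-trait covariance C, via `X = L_v Z L_cᵀ` —
chosen because it is the simplest model giving *independent* control of
phylogenetic signal and cross-trait collinearity, the two dials whose
interaction the package studies. `simulate_response` is the generative
counterpart of the fitted model, so the simulate-then-fit pipeline is
exactly specified and its calibration testable.

The shipped fixture (`make_fixture()`, also written to `inst/extdata/`
with its generating seed) emulates the shape of the empirical design this
methodology targets: 40 species, six candidates plus a dominant body-size
covariate (covariate-only R² ≥ 0.9), candidate correlations in the
0.3–0.8 band. The correlation band and effect sizes are realistic choices
for primate socioecological data, fixed once at generation; the fixture
is versioned by its seed and the tests verify it regenerates bit-for-bit.
It is synthetic: passing tests on it demonstrates the machinery and the
instability phenomenon, not any empirical claim about primates. Real
comparative data additionally have non-Gaussian traits, measurement
error, phylogenetic uncertainty and non-random missingness, none of which
the generator emulates.

## Numerical choices and study sizes

* Singular V and rank-deficient designs are errors naming the offending
  taxa pair / aliased columns; in a multiverse run they become per-model
  failure records excluded from AIC ranking.
* Zero-length terminal edges are allowed; a tip at zero total root-to-tip
  distance is rejected (it would have zero trait variance).
* Taxon labels are matched after stripping quotes and mapping spaces to
  underscores — the minimal rule that lets Newick labels meet CSV species
  names; case is preserved.
* Calibration studies use 200 tips and 500 replicates per λ ∈ {0, 0.5, 1}
  (CI coverage within [0.90, 0.98]; null p-values KS-uniform at α = 0.01),
  sizes at which coverage estimates have ~1% Monte-Carlo error while the
  full study runs in about a minute. Replicate seeds are drawn from one
  master stream rather than as sequential integers: sequential seeding
  produces detectably dependent draw streams, which violates the i.i.d.
  assumption of the KS check even when the test statistic itself is
  exactly calibrated.
* The instability study varies pairwise candidate correlation over
  {0, 0.5, 0.95} on matched seeds (8 trees of 40 tips, k = 4) and checks
  that the mean per-predictor p-range width rises strictly — the
  package's quantitative restatement of its motivating thesis.

## Known limitations

Only Brownian/λ covariances (no OU or early-burst models), single
Gaussian responses, no measurement-error model, no model averaging or
AIC weights (deliberately: the package is about the dispersion of
conclusions across models, and averaging would hide exactly that), and
no tree inference — trees are inputs. The λ optimizer assumes a
unimodal-enough profile that a 0.05 grid brackets the optimum; profiles
pathological at finer scales than 0.05 would need a denser grid.
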