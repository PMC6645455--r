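# pglsverse

Multiverse stability analysis for phylogenetic regression.

## The problem

Comparative studies of trait evolution — the canonical example being what
drives primate brain size — regress a trait on a handful of candidate
predictors with phylogenetic generalized least squares (PGLS), pick a model,
and interpret the significant slopes. But candidate predictors in this
field (group size, life history, diet, innovation rate) covary strongly
with each other and with body size, samples are small (a few dozen
species), and after body size is accounted for there is little residual
variation to explain. In that regime the estimate and p-value of any one
predictor can change dramatically depending on which *other* predictors
happen to be in the model, and different defensible model choices support
contradictory conclusions.

`pglsverse` makes that instability measurable instead of anecdotal: it
fits **every** subset of the candidate predictors (2^k − 1 models for k
candidates, each always including a mandatory body-size covariate),
selects among them by AIC, and reports per predictor how often it was
non-significant and how far its p-value travelled across the model space
— together with the collinearity diagnostics that explain the movement.

## The model

Each fitted model is a PGLS regression

y = Xβ + ε,  ε ~ N(0, σ² V(λ)),

where V is the Brownian-motion covariance implied by the phylogeny
(V_ij = shared root-to-MRCA branch length) and V(λ) multiplies the
off-diagonal of V by Pagel's λ ∈ [0, 1]. Estimation is GLS by Cholesky
whitening (never an explicit inverse); λ is estimated by bounded
profile-likelihood maximization with a λ = 1 fallback when the profile is
flat or optimization fails; log-likelihoods are ML so AIC is comparable
across fixed-effect sets, with AIC = −2ℓ + 2k, k counting the regression
terms, σ², and λ only when it was estimated. Reported statistics per
model are the usual b, se, t, two-sided p (df = n − p), R² =
cor(fitted, observed)², λ, and N.

Around the core sit:

* **Stability summaries** — per predictor, the count of models where
  p > 0.05 and the min/max p with the concomitant predictor sets that
  attain them.
* **Diagnostics** — VIF in the raw and PGLS-whitened designs, partial R²,
  and exact conjugate-posterior slope correlations (no MCMC), the signal
  of weak identifiability.
* **Data pooling** — weighted averaging of multi-source trait tables,
  log / arcsine-square-root transforms, lifespan derivation, complete-case
  filtering against the tree.
* **Synthetic data** — pure-birth trees and matrix-normal predictors with
  controlled phylogenetic signal and collinearity, plus a shipped 40-species
  "paper-like" fixture (fully synthetic, regenerable from its seed) in
  `inst/extdata/`.

## Worked example

```r
library(pglsverse)

fx <- make_fixture()          # 40 species, 6 collinear candidates + body mass
mv <- run_multiverse(fx$data, fx$tree, "total_brain",
                     fx$meta$candidates, fx$meta$mandatory)
best_by_aic(mv)
#> PGLS fit: total_brain ~ female_weight + female_sexual_maturity + life_span + fruit
#>                            b    se      t     p
#> (Intercept)            4.944 0.242 20.469 0.000
#> female_weight          0.579 0.024 23.818 0.000
#> female_sexual_maturity 0.122 0.070  1.755 0.088
#> life_span              0.247 0.091  2.724 0.010
#> fruit                  0.262 0.071  3.667 0.001
#> lambda = 1.000  sigma2 = 0.02128  logLik = 44.459  AIC = -74.918
#> R2 = 0.986  N = 40

stability_table(mv)[, c("predictor", "n_nonsignificant", "min_p", "max_p")]
#>                predictor n_nonsignificant    min_p   max_p
#> 1      female_group_size               28 1.82e-04 0.90361
#> 2        male_group_size               26 8.29e-04 0.96804
#> 3 female_sexual_maturity               16 2.57e-03 0.18081
#> 4              life_span                0 3.07e-04 0.02235
#> 5             innovation               31 4.43e-02 0.63740
#> 6                  fruit                0 4.07e-06 0.00245
```

Read the stability table as the point of the analysis: female group size,
say, attains p = 0.0002 under one concomitant set and p = 0.90 under
another — the same data would "support" or "refute" the social-brain
hypothesis depending on which other predictors the analyst included. The
AIC-best model is one point in that space, not a verdict. `report_multiverse()`
writes the flat fits table, both stability tables (CSV + markdown) and the
best-model report to a directory; `diagnose_collinearity()` explains the
instability (here, OLS VIFs run up to ≈ 4.3 and posterior slope
correlations are strongly negative for the entangled pairs).

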