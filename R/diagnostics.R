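# Core VIF computation on an already-assembled design: regress column j on
# the remaining columns *including* `base` (the intercept column, whitened
# or not), without adding any further intercept. R2_j is measured against
# the residual variation left after projecting on `base` alone, which
# reduces to the usual centered R2 when base is the constant column.
vif_engine <- function(P, base) {
  k <- ncol(P)
  nm <- colnames(P) %||% paste0("x", seq_len(k))
  out <- stats::setNames(numeric(k), nm)
  for (j in seq_len(k)) {
    others <- cbind(base, P[, -j, drop = FALSE])
    rss0 <- sum(stats::lm.fit(cbind(base), P[, j])$residuals^2)
    if (rss0 <= .Machine$double.eps * nrow(P))
      stop("predictor '", nm[j], "' is constant (no variation to inflate)")
    fitj <- stats::lm.fit(others, P[, j])
    rss <- sum(fitj$residuals^2)
    r2 <- 1 - rss / rss0
    if (r2 >= 1 - 1e-12) {
      coefs <- fitj$coefficients[-seq_len(ncol(base))]
      coefs[is.na(coefs)] <- 0
      aliased <- nm[-j][abs(coefs) > 1e-8]
      warning("predictor '", nm[j], "' is exactly collinear with {",
              paste(aliased, collapse = ", "), "}; VIF is infinite")
      out[j] <- Inf
    } else out[j] <- 1 / (1 - r2)
  }
  out
}

#' Variance inflation factors (ordinary least squares)
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` comes from regressing predictor j
#' on the remaining predictors (with intercept). VIF = 1 for mutually
#' orthogonal predictors; for two predictors with correlation r it is the
#' closed form `1 / (1 - r^2)`. Values above 10 are conventionally flagged
#' as worrying, though the flag gates nothing here.
#'
#' @param X numeric matrix or data frame of predictors (no intercept
#'   column), at least two columns.
#' @return named numeric vector of VIFs.
#' @export
#' @examples
#' x1 <- rnorm(50); x2 <- rnorm(50)
#' vif(cbind(a = x1, b = x2))
vif <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 2L) stop("VIF needs at least two predictors")
  vif_engine(X, base = matrix(1, nrow(X), 1))
}

#' Variance inflation factors in the PGLS-whitened design
#'
#' There is no canonical "PGLS VIF"; the definition adopted here is the
#' OLS VIF computed on the whitened design `L^-1 [1, X]` with
#' `V(lambda) = L L'` — collinearity as the fitted GLS actually
#' experiences it. With `V = I` (or any star phylogeny) this equals
#' [vif()] exactly.
#'
#' @inheritParams vif
#' @param V phylogenetic covariance matrix aligned to the rows of `X`.
#' @param lambda Pagel's lambda applied to `V` before whitening.
#' @return named numeric vector of VIFs.
#' @export
vif_pgls <- function(X, V, lambda = 1) {
  X <- as.matrix(X)
  if (ncol(X) < 2L) stop("VIF needs at least two predictors")
  stopifnot(nrow(V) == nrow(X))
  R <- chol(lambda_transform(V, lambda))
  Xw <- backsolve(R, X, transpose = TRUE)
  onew <- backsolve(R, matrix(1, nrow(X), 1), transpose = TRUE)
  colnames(Xw) <- colnames(X)
  vif_engine(Xw, base = onew)
}

#' Partial R-squared of one term in a PGLS fit
#'
#' `(RSS_reduced - RSS_full) / RSS_reduced`, both residual sums of squares
#' computed in the whitened space at the *full* model's lambda: the
#' proportional reduction in residual variation attributable to the term
#' given all others. Partial R2 values are not additive across terms when
#' predictors are collinear.
#'
#' @param fit a `pgls_fit`.
#' @param term name of a non-intercept model term.
#' @return scalar in \[0, 1\].
#' @export
partial_r2 <- function(fit, term) {
  stopifnot(inherits(fit, "pgls_fit"))
  terms <- colnames(fit$X)
  if (!term %in% terms) stop("term '", term, "' is not in the model")
  if (term == "(Intercept)") stop("partial R2 is defined for predictors, ",
                                  "not the intercept")
  R <- chol(fit$Vlambda)
  yw <- backsolve(R, fit$y, transpose = TRUE)
  Xw <- backsolve(R, fit$X, transpose = TRUE)
  rss_full <- sum(stats::lm.fit(Xw, yw)$residuals^2)
  keep <- terms != term
  rss_red <- sum(stats::lm.fit(Xw[, keep, drop = FALSE], yw)$residuals^2)
  (rss_red - rss_full) / rss_red
}

#' Exact draws from the conjugate posterior of a GLS model
#'
#' Samples `(b, sigma^2)` from the Normal-Inverse-Gamma posterior of the
#' whitened linear model under the flat reference prior
#' `p(b, sigma^2) proportional to 1/sigma^2`:
#' `sigma^2 | y ~ Inv-Gamma((n-p)/2, RSS_w/2)` and
#' `b | sigma^2, y ~ N(b_hat, sigma^2 (Xw' Xw)^-1)`. Because the posterior
#' is available in closed form, no Markov chain is involved and there are
#' no mixing concerns; the draws are exact and reproducible by seed. The
#' correlation structure of the slope draws is the collinearity
#' diagnostic: strongly covarying predictors yield strongly (negatively)
#' correlated slopes.
#'
#' @inheritParams fit_gls
#' @param lambda Pagel's lambda applied to `V`.
#' @param n_draws number of posterior draws (>= 1000).
#' @param seed integer seed; draws are identical for identical seeds.
#' @return an `n_draws x p` matrix of coefficient draws (columns named by
#'   term), with attributes `sigma2_draws`, `seed`, `lambda`.
#' @export
posterior_sample <- function(y, X, V, lambda = 1, n_draws = 10000,
                             seed = 1) {
  if (n_draws < 1000) stop("n_draws must be at least 1000")
  X <- as.matrix(X)
  g <- fit_gls(y, X, lambda_transform(V, lambda))
  n <- g$n; p <- g$p
  Rx <- chol(solve(g$cov_unscaled))  # chol of Xw'Xw
  draws <- with_seed(seed, {
    s2 <- g$rss / stats::rchisq(n_draws, df = n - p)
    Z <- matrix(stats::rnorm(n_draws * p), nrow = p)
    B <- backsolve(Rx, Z)        # cols ~ N(0, (Xw'Xw)^-1)
    t(g$coefficients + sweep(B, 2, sqrt(s2), `*`))
  })
  colnames(draws) <- names(g$coefficients)
  attr(draws, "sigma2_draws") <- g$rss /
    with_seed(seed, stats::rchisq(n_draws, df = n - p))
  attr(draws, "seed") <- seed
  attr(draws, "lambda") <- lambda
  draws
}

#' Correlation matrix of posterior coefficient draws
#'
#' Pearson correlations between the columns of a draw matrix — the
#' operational version of inspecting whether posterior slope distributions
#' correlate, which is the collinearity signal a weakly identified model
#' shows.
#'
#' @param draws matrix of posterior draws (e.g. from [posterior_sample()]).
#' @param include_intercept keep the `(Intercept)` column? Default drops
#'   it, since slope entanglement is the quantity of interest.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
posterior_correlation <- function(draws, include_intercept = FALSE) {
  draws <- as.matrix(draws)
  if (!include_intercept && "(Intercept)" %in% colnames(draws))
    draws <- draws[, colnames(draws) != "(Intercept)", drop = FALSE]
  if (ncol(draws) < 2L) stop("need at least two coefficient columns")
  stats::cor(draws)
}

#' Full collinearity diagnostics for a fitted PGLS model
#'
#' Bundles the OLS and whitened-design VIFs, the predictor correlation
#' matrix, per-term partial R2, and the posterior slope-correlation matrix
#' at the fitted lambda into one report.
#'
#' @param fit a `pgls_fit` with at least two non-intercept terms.
#' @param n_draws posterior draws for the slope-correlation block.
#' @param seed seed for the posterior draws.
#' @return an object of class `diagnostics_report`.
#' @export
diagnose_collinearity <- function(fit, n_draws = 10000, seed = 1) {
  stopifnot(inherits(fit, "pgls_fit"))
  P <- fit$X[, colnames(fit$X) != "(Intercept)", drop = FALSE]
  if (ncol(P) < 2L) stop("diagnostics need at least two predictors")
  draws <- posterior_sample(fit$y, fit$X, fit$V, lambda = fit$lambda,
                            n_draws = n_draws, seed = seed)
  structure(list(
    vif_ols = vif(P),
    vif_pgls = vif_pgls(P, fit$V, lambda = fit$lambda),
    correlation = stats::cor(P),
    partial_r2 = stats::setNames(
      vapply(colnames(P), function(tm) partial_r2(fit, tm), numeric(1)),
      colnames(P)),
    posterior_correlation = posterior_correlation(draws),
    n_draws = n_draws, seed = seed, lambda = fit$lambda),
    class = "diagnostics_report")
}

#' @export
print.diagnostics_report <- function(x, digits = 3, ...) {
  cat("Collinearity diagnostics (lambda =", format(x$lambda, digits = 3),
      ")\n\nVIF (OLS / whitened PGLS design):\n")
  print(round(rbind(ols = x$vif_ols, pgls = x$vif_pgls), digits))
  cat("\nPredictor correlations:\n")
  print(round(x$correlation, digits))
  cat("\nPartial R2:\n")
  print(round(x$partial_r2, digits))
  cat("\nPosterior slope correlations (", x$n_draws, " draws, seed ",
      x$seed, "):\n", sep = "")
  print(round(x$posterior_correlation, digits))
  invisible(x)
}
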