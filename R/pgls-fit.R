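#' Model specification for a PGLS fit
#'
#' A model spec names one outcome, the mandatory covariates included in
#' every model (in comparative brain-size work, (log) female body weight),
#' and the focal predictor subset under consideration. The intercept is
#' always present and never listed.
#'
#' @param outcome outcome variable name.
#' @param focal character vector of focal predictor names (may be empty).
#' @param mandatory character vector of always-included covariate names.
#' @return an object of class `model_spec`.
#' @export
#' @examples
#' model_spec("total_brain", c("female_group_size"), "female_weight")
model_spec <- function(outcome, focal = character(), mandatory = character()) {
  outcome <- as.character(outcome)
  focal <- as.character(focal)
  mandatory <- as.character(mandatory)
  stopifnot(length(outcome) == 1L)
  if (anyDuplicated(c(focal, mandatory)))
    stop("duplicate terms across focal and mandatory sets")
  if (outcome %in% c(focal, mandatory))
    stop("outcome cannot appear among the predictors")
  structure(list(outcome = outcome, mandatory = mandatory, focal = focal),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  rhs <- c(x$mandatory, x$focal)
  cat(x$outcome, "~", if (length(rhs)) paste(rhs, collapse = " + ")
      else "1", "\n")
  invisible(x)
}

# Locate the most nearly dependent taxon pair of a singular covariance,
# to produce an actionable error message.
singular_pair <- function(V) {
  d <- sqrt(pmax(diag(V), .Machine$double.eps))
  C <- V / outer(d, d)
  diag(C) <- 0
  ij <- which(abs(C) == max(abs(C)), arr.ind = TRUE)[1, ]
  nm <- rownames(V) %||% as.character(seq_len(nrow(V)))
  paste(nm[ij[1]], "and", nm[ij[2]])
}

#' Generalized least squares by Cholesky whitening
#'
#' Estimates `b = (X' V^-1 X)^-1 X' V^-1 y` without ever forming `V^-1`:
#' with `V = L L'`, the model is whitened to `L^-1 y = L^-1 X b + e`,
#' `e ~ N(0, sigma^2 I)`, and solved by QR on the whitened design. Returns
#' the ML residual rate `sigma2 = RSS_w / n`, the exact multivariate-normal
#' log-likelihood at the ML estimates, and the unscaled coefficient
#' covariance for standard errors.
#'
#' @param y numeric response vector.
#' @param X numeric design matrix (including the intercept column), rows
#'   aligned with `y` and with the rows/columns of `V`.
#' @param V positive-definite covariance matrix.
#' @return a list with elements `coefficients`, `se`, `sigma2` (ML),
#'   `s2` (unbiased, RSS_w / (n - p); used for `se`), `loglik`, `rss`,
#'   `cov_unscaled`, `fitted` (on the original scale), `n`, `p`.
#' @export
fit_gls <- function(y, X, V) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n, nrow(V) == n, ncol(V) == n)
  p <- ncol(X)
  R <- tryCatch(chol(V), error = function(e)
    stop("covariance matrix is singular (offending taxa pair: ",
         singular_pair(V), ")", call. = FALSE))
  yw <- backsolve(R, y, transpose = TRUE)
  Xw <- backsolve(R, X, transpose = TRUE)
  qrX <- qr(Xw)
  if (qrX$rank < p) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):p]]
    stop("design matrix is rank deficient; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  b <- qr.coef(qrX, yw)
  resw <- yw - Xw %*% b
  rss <- sum(resw^2)
  sigma2 <- rss / n
  logdetV <- 2 * sum(log(diag(R)))
  loglik <- -0.5 * (n * log(2 * pi) + n * log(sigma2) + logdetV + n)
  cov_unscaled <- chol2inv(chol(crossprod(Xw)))
  dimnames(cov_unscaled) <- list(colnames(X), colnames(X))
  s2 <- if (n > p) rss / (n - p) else NA_real_
  se <- sqrt(s2 * diag(cov_unscaled))
  names(b) <- names(se) <- colnames(X)
  list(coefficients = b, se = se, sigma2 = sigma2, s2 = s2,
       loglik = loglik, rss = rss, cov_unscaled = cov_unscaled,
       fitted = drop(X %*% b), n = n, p = p)
}

#' Profile log-likelihood in Pagel's lambda
#'
#' The ML log-likelihood of the GLS model with covariance
#' `lambda_transform(V, lambda)`, maximized over `b` and `sigma2`.
#'
#' @inheritParams fit_gls
#' @param lambda scalar in \[0, 1\].
#' @return the log-likelihood (scalar).
#' @export
profile_loglik <- function(y, X, V, lambda) {
  fit_gls(y, X, lambda_transform(V, lambda))$loglik
}

#' Estimate Pagel's lambda by bounded profile-likelihood maximization
#'
#' Evaluates the profile likelihood on a coarse grid over \[0, 1\], then
#' refines by golden-section/parabolic search in the bracketing interval.
#' If the likelihood cannot be evaluated, the optimizer fails, or the
#' profile is flat (lambda unidentifiable, e.g. on a star phylogeny), the
#' estimate falls back to `lambda = 1` and is flagged as fixed, with a
#' warning. The fallback mirrors field practice: near-boundary optimization
#' failures are resolved by fixing lambda at 1 rather than aborting.
#'
#' @inheritParams fit_gls
#' @param policy `"estimate"` (the default) or a numeric value in \[0, 1\]
#'   at which lambda is fixed.
#' @return a list with `lambda`, `lambda_fixed` (logical: TRUE when fixed
#'   by policy or by fallback), and `loglik` at the returned lambda.
#' @export
estimate_lambda <- function(y, X, V, policy = "estimate") {
  if (is.numeric(policy)) {
    if (length(policy) != 1L || is.na(policy) || policy < 0 || policy > 1)
      stop("fixed lambda must be a single value in [0, 1]")
    return(list(lambda = policy, lambda_fixed = TRUE,
                loglik = profile_loglik(y, X, V, policy)))
  }
  if (!identical(policy, "estimate"))
    stop("policy must be \"estimate\" or a numeric value in [0, 1]")
  f <- function(l) tryCatch(profile_loglik(y, X, V, l),
                            error = function(e) NA_real_)
  grid <- seq(0, 1, by = 0.05)
  ll <- vapply(grid, f, numeric(1))
  ok <- is.finite(ll)
  if (!any(ok)) {
    warning("lambda profile likelihood could not be evaluated; ",
            "falling back to lambda = 1 (fixed)")
    return(list(lambda = 1, lambda_fixed = TRUE, loglik = f(1)))
  }
  if (diff(range(ll[ok])) < 1e-8) {
    warning("lambda is unidentifiable (flat profile likelihood); ",
            "falling back to lambda = 1 (fixed)")
    return(list(lambda = 1, lambda_fixed = TRUE, loglik = f(1)))
  }
  i <- which.max(ll)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- tryCatch(
    stats::optimize(f, interval = c(lo, hi), maximum = TRUE, tol = 1e-7),
    error = function(e) NULL)
  if (is.null(opt) || !is.finite(opt$objective)) {
    warning("lambda optimization failed to converge; ",
            "falling back to lambda = 1 (fixed)")
    return(list(lambda = 1, lambda_fixed = TRUE, loglik = f(1)))
  }
  # keep the better of the refined optimum and the best grid point,
  # and prefer the exact boundary when it dominates
  cand_l <- c(opt$maximum, grid[i], 0, 1)
  cand_ll <- c(opt$objective, ll[i], ll[1L], ll[length(grid)])
  j <- which.max(cand_ll)
  list(lambda = cand_l[j], lambda_fixed = FALSE, loglik = cand_ll[j])
}

#' Fit a phylogenetic generalized least squares regression
#'
#' Assembles the aligned response, design and covariance on the species
#' shared by the trait table and the tree (complete cases on all model
#' variables), estimates Pagel's lambda per `policy`, and fits by
#' [fit_gls()] at the lambda-transformed covariance. Reports the statistics
#' conventional in comparative analyses: per-term b, se, t and two-sided p
#' (t distribution with `n - p` df), sigma^2, log-likelihood, AIC, the
#' correlation-based R^2, lambda and N.
#'
#' @param data a data frame with a `species` column (or row names) and
#'   numeric trait columns; typically already transformed
#'   (see [apply_transforms()]).
#' @param spec a [model_spec()].
#' @param tree a `phylo` object.
#' @param policy lambda policy as in [estimate_lambda()].
#' @param species_col name of the species column in `data`.
#' @return an object of class `pgls_fit`.
#' @export
#' @examples
#' sim <- make_fixture(seed = 1)
#' fit <- fit_pgls(sim$data, model_spec("total_brain", "female_group_size",
#'                 "female_weight"), sim$tree)
#' fit
fit_pgls <- function(data, spec, tree, policy = "estimate",
                     species_col = "species") {
  stopifnot(inherits(spec, "model_spec"))
  vars <- c(spec$outcome, spec$mandatory, spec$focal)
  miss <- setdiff(vars, names(data))
  if (length(miss))
    stop("variable(s) absent from data: ", paste(miss, collapse = ", "))
  cc <- complete_cases_phylo(data, tree, vars, species_col = species_col)
  dat <- cc$data
  tr <- cc$tree
  n <- nrow(dat)
  terms <- c("(Intercept)", spec$mandatory, spec$focal)
  p <- length(terms)
  if (n <= p + 1L)
    stop("insufficient species for model size: n = ", n,
         " with ", p, " terms")
  V <- vcv_matrix(tr)
  sp <- normalize_labels(dat[[species_col]])
  V <- V[sp, sp, drop = FALSE]  # align covariance to the data row order
  y <- as.numeric(dat[[spec$outcome]])
  X <- cbind(`(Intercept)` = 1,
             as.matrix(dat[, c(spec$mandatory, spec$focal), drop = FALSE]))
  colnames(X) <- terms
  est <- estimate_lambda(y, X, V, policy = policy)
  Vl <- lambda_transform(V, est$lambda)
  g <- fit_gls(y, X, Vl)
  tval <- g$coefficients / g$se
  df <- n - p
  pval <- 2 * stats::pt(-abs(tval), df = df)
  k <- p + 1L + as.integer(!est$lambda_fixed)  # + sigma2, + lambda if estimated
  aic <- -2 * g$loglik + 2 * k
  r2 <- if (stats::sd(g$fitted) > 0) stats::cor(g$fitted, y)^2 else NA_real_
  structure(list(
    spec = spec, coefficients = g$coefficients, se = g$se, t_values = tval,
    p_values = pval, lambda = est$lambda, lambda_fixed = est$lambda_fixed,
    sigma2 = g$sigma2, s2 = g$s2, loglik = g$loglik, aic = aic, k = k,
    r2 = r2, n = n, df_resid = df, fitted = g$fitted,
    cov_unscaled = g$cov_unscaled, y = y, X = X, V = V, Vlambda = Vl,
    species = sp, dropped = cc$dropped), class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, digits = 3, ...) {
  cat("PGLS fit:", x$spec$outcome, "~",
      paste(c(x$spec$mandatory, x$spec$focal), collapse = " + "), "\n")
  tab <- data.frame(b = x$coefficients, se = x$se, t = x$t_values,
                    p = x$p_values)
  print(round(tab, digits))
  cat(sprintf("lambda = %.3f%s  sigma2 = %.4g  logLik = %.3f  AIC = %.3f\n",
              x$lambda, if (x$lambda_fixed) " (fixed)" else "",
              x$sigma2, x$loglik, x$aic))
  cat(sprintf("R2 = %.3f  N = %d\n", x$r2, x$n))
  invisible(x)
}

#' @export
logLik.pgls_fit <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = object$n, class = "logLik")
}

#' Akaike information criterion of a PGLS fit
#'
#' `AIC = -2 logLik + 2 k` with `k` = number of regression terms
#' (including the intercept) + 1 for `sigma^2` + 1 for lambda when it was
#' estimated. A lambda fixed by policy or by the unidentifiability fallback
#' is not an estimated parameter and is not counted, keeping AIC values
#' comparable across a multiverse in which some models hit the fallback.
#'
#' @param object a `pgls_fit`.
#' @param ... ignored.
#' @param k penalty per parameter (2 for AIC).
#' @return the AIC (scalar).
#' @export
AIC.pgls_fit <- function(object, ..., k = 2) {
  -2 * object$loglik + k * object$k
}

#' Correlation-based R-squared of a PGLS fit
#'
#' The squared Pearson correlation between the (unwhitened) fitted values
#' `X b` and the observed outcome. This is the descriptive convention used
#' in comparative brain-size work, not a likelihood-based pseudo-R^2; under
#' a phylogenetic error structure it gives only a crude picture of
#' explained variation.
#'
#' @param fit a `pgls_fit`.
#' @return scalar in \[0, 1\].
#' @export
r_squared <- function(fit) {
  stopifnot(inherits(fit, "pgls_fit"))
  if (stats::sd(fit$fitted) == 0)
    stop("fitted values have zero variance (intercept-only model); ",
         "correlation R^2 is undefined")
  stats::cor(fit$fitted, fit$y)^2
}

#' Predict from a PGLS fit with a prediction interval
#'
#' Point prediction `x0' b` for a new observation, with a
#' `level` prediction interval
#' `x0' b +/- t_{df, (1+level)/2} sqrt(s2 * s_bar + x0' Cov(b) x0)`,
#' where `s_bar` is the mean diagonal of the lambda-transformed covariance.
#' The new observation's phylogenetic position is *not* modeled (no
#' covariance with the training species is assumed), so the residual
#' variance term uses the average tip variance; this is the standard caveat
#' when predicting for a taxon outside the fitted tree. Predictions are on
#' the (typically log) scale of the fitted outcome; exponentiating the
#' bounds yields the asymmetric intervals seen on the raw scale.
#'
#' @param object a `pgls_fit`.
#' @param newdata a one-row data frame (or named list) supplying every
#'   model term except the intercept.
#' @param level coverage of the prediction interval, in (0, 1).
#' @param ... ignored.
#' @return a list of class `pgls_prediction` with `point`, `interval_low`,
#'   `interval_high`, `level`.
#' @export
predict.pgls_fit <- function(object, newdata, level = 0.95, ...) {
  stopifnot(level > 0, level < 1)
  terms <- setdiff(colnames(object$X), "(Intercept)")
  newdata <- as.list(newdata)
  miss <- setdiff(terms, names(newdata))
  if (length(miss))
    stop("newdata is missing model term(s): ", paste(miss, collapse = ", "))
  x0 <- c(1, vapply(terms, function(v) as.numeric(newdata[[v]])[1],
                    numeric(1)))
  point <- drop(x0 %*% object$coefficients)
  sbar <- mean(diag(object$Vlambda))
  pred_var <- object$s2 * sbar +
    object$s2 * drop(t(x0) %*% object$cov_unscaled %*% x0)
  half <- stats::qt((1 + level) / 2, df = object$df_resid) * sqrt(pred_var)
  structure(list(point = point, interval_low = point - half,
                 interval_high = point + half, level = level),
            class = "pgls_prediction")
}

#' @export
print.pgls_prediction <- function(x, ...) {
  cat(sprintf("prediction: %.4f  [%g%% PI: %.4f, %.4f]\n",
              x$point, 100 * x$level, x$interval_low, x$interval_high))
  invisible(x)
}

#' Flatten a PGLS fit to one row per term
#'
#' @param x a `pgls_fit`.
#' @param model_id optional model identifier recorded in each row.
#' @param ... ignored.
#' @return a data frame with columns model_id, outcome, focal_set, term,
#'   b, se, t, p, lambda, lambda_fixed, aic, r2, n.
#' @export
as.data.frame.pgls_fit <- function(x, model_id = NA_character_, ...) {
  terms <- names(x$coefficients)
  data.frame(
    model_id = model_id, outcome = x$spec$outcome,
    focal_set = paste(x$spec$focal, collapse = "+"),
    term = terms, b = unname(x$coefficients), se = unname(x$se),
    t = unname(x$t_values), p = unname(x$p_values),
    lambda = x$lambda, lambda_fixed = x$lambda_fixed,
    aic = x$aic, r2 = x$r2, n = x$n,
    stringsAsFactors = FALSE, row.names = NULL)
}
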