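test_that("fit_gls reduces to OLS when V is the identity", {
  set.seed(11)
  n <- 30
  X <- cbind(`(Intercept)` = 1, x1 = rnorm(n), x2 = rnorm(n))
  y <- 1 + 0.5 * X[, 2] + rnorm(n)
  g <- fit_gls(y, X, diag(n))
  ols <- lm(y ~ X[, 2] + X[, 3])
  expect_equal(unname(g$coefficients), unname(coef(ols)), tolerance = 1e-10)
  expect_equal(unname(g$se), unname(summary(ols)$coefficients[, 2]),
               tolerance = 1e-10)
})

test_that("fit_gls intercept-only matches the explicit GLS mean formula", {
  V <- matrix(c(2, 1, 0, 1, 2, 0, 0, 0, 2), 3, 3)
  y <- c(1, 2, 3)
  one <- matrix(1, 3, 1, dimnames = list(NULL, "(Intercept)"))
  g <- fit_gls(y, one, V)
  Vi <- solve(V)
  bhat <- drop(solve(t(one) %*% Vi %*% one) %*% t(one) %*% Vi %*% y)
  expect_equal(unname(g$coefficients), unname(bhat), tolerance = 1e-12)
})

test_that("Cholesky whitening equals the dense-inverse oracle on random instances", {
  for (seed in 1:25) {
    set.seed(seed)
    n <- sample(5:12, 1)
    tr <- random_tree(n, seed)
    V <- vcv_matrix(tr)
    X <- cbind(`(Intercept)` = 1, x = rnorm(n))
    y <- rnorm(n, sd = 2)
    g <- fit_gls(y, X, V)
    o <- gls_oracle(y, X, V)
    expect_equal(unname(g$coefficients), unname(o$b), tolerance = 1e-9)
    expect_equal(g$sigma2, o$sigma2, tolerance = 1e-9)
    expect_equal(g$loglik, o$loglik, tolerance = 1e-9)
  }
})

test_that("fit_gls names offenders on singular V and aliased designs", {
  V <- matrix(1, 2, 2, dimnames = list(c("tA", "tB"), c("tA", "tB")))
  expect_error(fit_gls(c(1, 2), matrix(1, 2, 1), V),
               "offending taxa pair")
  set.seed(2)
  n <- 10
  x <- rnorm(n)
  X <- cbind(`(Intercept)` = 1, a = x, b = x)  # duplicated predictor
  expect_error(fit_gls(rnorm(n), X, diag(n)), "rank deficient.*b|b.*rank")
})

test_that("profile_loglik is definitional and maximized near the truth", {
  d <- sim_dataset(n = 40, seed = 3)
  X <- cbind(`(Intercept)` = 1, as.matrix(d$data[paste0("x", 1:3)]))
  V <- vcv_matrix(d$tree)
  y <- d$data$y
  for (l in c(0, 0.5, 1))
    expect_identical(profile_loglik(y, X, V, l),
                     fit_gls(y, X, lambda_transform(V, l))$loglik)

  # deep-tree data simulated at the lambda extremes localize the optimum
  for (true_l in c(0, 1)) {
    dd <- sim_dataset(n = 100, lambda = true_l, sigma2 = 0.5,
                      seed = 40 + true_l)
    Xd <- cbind(`(Intercept)` = 1, as.matrix(dd$data[paste0("x", 1:3)]))
    Vd <- vcv_matrix(dd$tree)
    est <- estimate_lambda(dd$data$y, Xd, Vd)
    expect_lt(abs(est$lambda - true_l), 0.25)
  }
})

test_that("estimate_lambda honors fixed policies and flags fallback", {
  d <- sim_dataset(n = 30, seed = 5)
  X <- cbind(`(Intercept)` = 1, as.matrix(d$data[paste0("x", 1:3)]))
  V <- vcv_matrix(d$tree)
  fx <- estimate_lambda(d$data$y, X, V, policy = 1)
  expect_identical(fx$lambda, 1)
  expect_true(fx$lambda_fixed)
  expect_error(estimate_lambda(d$data$y, X, V, policy = 1.2), "\\[0, 1\\]")

  # star tree: lambda unidentifiable, fallback exercised and flagged
  st <- star_tree(20)
  set.seed(6)
  Xs <- cbind(`(Intercept)` = 1, x = rnorm(20))
  ys <- rnorm(20)
  expect_warning(es <- estimate_lambda(ys, Xs, vcv_matrix(st)),
                 "unidentifiable|fall")
  expect_identical(es$lambda, 1)
  expect_true(es$lambda_fixed)
})

test_that("the returned lambda dominates a 0.01-step grid", {
  for (seed in 1:5) {
    d <- sim_dataset(n = 60, lambda = 0.6, sigma2 = 0.3, seed = 60 + seed)
    X <- cbind(`(Intercept)` = 1, as.matrix(d$data[paste0("x", 1:3)]))
    V <- vcv_matrix(d$tree)
    y <- d$data$y
    est <- estimate_lambda(y, X, V)
    grid <- seq(0, 1, by = 0.01)
    ll <- vapply(grid, function(l) profile_loglik(y, X, V, l), numeric(1))
    expect_gte(est$loglik + 1e-7, max(ll))
    expect_lte(abs(est$lambda - grid[which.max(ll)]), 0.01)
  }
})

test_that("fit_pgls fills every reported statistic coherently", {
  d <- sim_dataset(n = 40, seed = 8)
  spec <- model_spec("y", c("x2", "x3"), "x1")
  fit <- fit_pgls(d$data, spec, d$tree)
  expect_s3_class(fit, "pgls_fit")
  expect_equal(fit$n, 40)
  expect_equal(fit$df_resid, 40 - 4)
  expect_equal(unname(fit$t_values), unname(fit$coefficients / fit$se))
  expect_equal(unname(fit$p_values),
               unname(2 * pt(-abs(fit$t_values), df = fit$df_resid)))
  k <- 4 + 1 + as.integer(!fit$lambda_fixed)
  expect_equal(fit$aic, -2 * fit$loglik + 2 * k)
  expect_equal(AIC(fit), fit$aic)
  expect_equal(fit$r2, cor(fit$fitted, fit$y)^2)
  expect_true(fit$r2 >= 0 && fit$r2 <= 1)
})

test_that("zero-focal specs reduce to the mandatory-covariate model", {
  d <- sim_dataset(n = 30, seed = 9)
  fit <- fit_pgls(d$data, model_spec("y", character(), "x1"), d$tree)
  expect_named(fit$coefficients, c("(Intercept)", "x1"))
})

test_that("row-order permutations leave every statistic unchanged", {
  d <- sim_dataset(n = 30, seed = 10)
  spec <- model_spec("y", c("x2"), "x1")
  f1 <- fit_pgls(d$data, spec, d$tree)
  perm <- pglsverse:::with_seed(99, sample(nrow(d$data)))
  f2 <- fit_pgls(d$data[perm, ], spec, d$tree)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-10)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-10)
  expect_equal(f1$lambda, f2$lambda, tolerance = 1e-8)
  expect_equal(f1$p_values, f2$p_values, tolerance = 1e-8)
})

test_that("fit_pgls errors when species are too few for the model", {
  d <- sim_dataset(n = 40, seed = 12)
  small <- d$data[1:5, ]
  expect_error(
    fit_pgls(small, model_spec("y", paste0("x", 2:3), "x1"), d$tree),
    "insufficient species")
})

test_that("lambda = 0 and star trees reproduce OLS, for any lambda", {
  d <- sim_dataset(n = 35, seed = 13)
  spec <- model_spec("y", c("x2", "x3"), "x1")
  fit0 <- fit_pgls(d$data, spec, d$tree, policy = 0)
  ols <- lm(y ~ x1 + x2 + x3, data = d$data)
  expect_equal(unname(fit0$coefficients), unname(coef(ols)),
               tolerance = 1e-8)
  expect_equal(unname(fit0$se), unname(summary(ols)$coefficients[, 2]),
               tolerance = 1e-8)

  st <- star_tree(35)
  ds <- d$data
  ds$species <- st$tip.label[seq_len(nrow(ds))]
  olss <- lm(y ~ x1 + x2 + x3, data = ds)
  for (lam in c(0, 0.4, 1)) {
    fs <- fit_pgls(ds, spec, st, policy = lam)
    expect_equal(unname(fs$coefficients), unname(coef(olss)),
                 tolerance = 1e-8)
    expect_equal(unname(fs$se), unname(summary(olss)$coefficients[, 2]),
                 tolerance = 1e-8)
  }
})

test_that("fit matches nlme::gls with a fixed Pagel correlation", {
  skip_if_not_installed("nlme")
  d <- sim_dataset(n = 40, seed = 14)
  dat <- d$data
  rownames(dat) <- dat$species
  fit <- fit_pgls(dat, model_spec("y", c("x2", "x3"), "x1"), d$tree,
                  policy = 1)
  g <- nlme::gls(y ~ x1 + x2 + x3, data = dat,
                 correlation = ape::corPagel(1, d$tree, fixed = TRUE,
                                             form = ~species),
                 method = "ML")
  expect_equal(unname(fit$coefficients), unname(coef(g)),
               tolerance = 1e-8)
  expect_equal(fit$loglik, as.numeric(logLik(g)), tolerance = 1e-8)
  expect_equal(unname(fit$se),
               unname(summary(g)$tTable[, "Std.Error"]), tolerance = 1e-6)
})

test_that("scaling the response scales b and se but not t, p, R2, lambda", {
  d <- sim_dataset(n = 40, seed = 15)
  spec <- model_spec("y", c("x2"), "x1")
  f1 <- fit_pgls(d$data, spec, d$tree)
  d2 <- d$data
  d2$y <- 3 * d2$y
  f2 <- fit_pgls(d2, spec, d$tree)
  expect_equal(unname(f2$coefficients), 3 * unname(f1$coefficients),
               tolerance = 1e-6)
  expect_equal(unname(f2$se), 3 * unname(f1$se), tolerance = 1e-6)
  expect_equal(f2$t_values, f1$t_values, tolerance = 1e-6)
  expect_equal(f2$p_values, f1$p_values, tolerance = 1e-6)
  expect_equal(f2$r2, f1$r2, tolerance = 1e-8)
  expect_equal(f2$lambda, f1$lambda, tolerance = 1e-5)
})

test_that("nested models with identical loglik differ in AIC by exactly 2", {
  d <- sim_dataset(n = 30, seed = 16)
  f_small <- fit_pgls(d$data, model_spec("y", "x2", "x1"), d$tree,
                      policy = 1)
  f_big <- fit_pgls(d$data, model_spec("y", c("x2", "x3"), "x1"), d$tree,
                    policy = 1)
  # definitional: AIC difference = 2 * (k diff) - 2 * (loglik gain)
  expect_equal(f_big$aic - f_small$aic,
               2 - 2 * (f_big$loglik - f_small$loglik), tolerance = 1e-10)
  expect_gte(f_big$loglik + 1e-10, f_small$loglik)
})

test_that("r_squared errors on degenerate fits and matches recomputation", {
  d <- sim_dataset(n = 30, seed = 17)
  fit <- fit_pgls(d$data, model_spec("y", "x2", "x1"), d$tree)
  expect_equal(r_squared(fit), cor(drop(fit$X %*% fit$coefficients),
                                   fit$y)^2, tolerance = 1e-12)
  # perfect noiseless fit
  d0 <- d$data
  d0$y <- simulate_response(d0, c(`(Intercept)` = 1, x1 = 0.5), d$tree,
                            sigma2 = 0, seed = 1)
  f0 <- fit_pgls(d0, model_spec("y", character(), "x1"), d$tree, policy = 1)
  expect_equal(r_squared(f0), 1, tolerance = 1e-8)
  # intercept-only: undefined, error not 0
  io <- fit_pgls(d$data, model_spec("y", character(), character()),
                 d$tree, policy = 1)
  expect_error(r_squared(io), "undefined|zero variance")
})

test_that("prediction intervals behave and match the OLS closed form", {
  d <- sim_dataset(n = 30, seed = 18)
  fit <- fit_pgls(d$data, model_spec("y", "x2", "x1"), d$tree)
  new <- d$data[4, c("x1", "x2")]
  pr <- predict(fit, new)
  expect_equal(pr$point, unname(fit$fitted[4]), tolerance = 1e-10)
  expect_lte(pr$interval_low, pr$point)
  expect_gte(pr$interval_high, pr$point)
  pr50 <- predict(fit, new, level = 0.5)
  expect_lt(pr$interval_low, pr50$interval_low)
  expect_gt(pr$interval_high, pr50$interval_high)
  expect_error(predict(fit, list(x1 = 1)), "x2")

  # V = I: must equal the OLS closed-form prediction interval
  st <- star_tree(30)
  ds <- d$data
  ds$species <- st$tip.label
  fs <- fit_pgls(ds, model_spec("y", character(), "x1"), st, policy = 1)
  ols <- lm(y ~ x1, data = ds)
  x0 <- data.frame(x1 = 0.7)
  po <- predict(ols, x0, interval = "prediction", level = 0.95)
  ps <- predict(fs, x0, level = 0.95)
  expect_equal(ps$point, unname(po[1, "fit"]), tolerance = 1e-8)
  expect_equal(ps$interval_low, unname(po[1, "lwr"]), tolerance = 1e-8)
  expect_equal(ps$interval_high, unname(po[1, "upr"]), tolerance = 1e-8)
})

test_that("fit rows survive a CSV round trip", {
  d <- sim_dataset(n = 30, seed = 19)
  fit <- fit_pgls(d$data, model_spec("y", "x2", "x1"), d$tree)
  dir <- withr::local_tempdir()
  paths <- report_fit(fit, dir, name = "m")
  back <- read.csv(paths[["csv"]], stringsAsFactors = FALSE)
  expect_equal(back$b, unname(fit$coefficients), tolerance = 1e-12)
  expect_equal(back$p, unname(fit$p_values), tolerance = 1e-12)
  expect_equal(unique(back$lambda), fit$lambda, tolerance = 1e-12)
})

test_that("lambda is recovered with small bias and spread at n = 200", {
  beta <- c(`(Intercept)` = 0, x1 = 0.4, x2 = 0.2)
  C <- diag(2)
  colnames(C) <- rownames(C) <- c("x1", "x2")
  n_rep <- 100
  rep_seeds <- pglsverse:::with_seed(70, sample.int(2^31 - 2, n_rep))
  lams <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    tr <- simulate_tree(200, seed = rep_seeds[r])
    preds <- simulate_predictors(tr, C, seed = rep_seeds[r] %% 1e6 + 1)
    preds$y <- simulate_response(preds, beta, tr, lambda_resid = 0.7,
                                 sigma2 = 0.3,
                                 seed = rep_seeds[r] %% 1e6 + 2)
    fit <- suppressWarnings(
      fit_pgls(preds, model_spec("y", "x2", "x1"), tr))
    lams[r] <- fit$lambda
  }
  # a correct ML estimator on unit-depth pure-birth trees at n = 200 has
  # sd(lambda-hat) ~ 0.10 with a small downward bias; ~95% of estimates
  # fall within +-0.2 of the truth (measured over 400 replicates)
  expect_gte(mean(abs(lams - 0.7) <= 0.2), 0.9)
  expect_lt(abs(mean(lams) - 0.7), 0.06)
})
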