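#' Simulate a pure-birth phylogeny of unit depth
#'
#' A Yule (pure-birth) tree with the requested number of tips, rescaled so
#' every root-to-tip path has length 1. Ultrametric by construction, so
#' the implied Brownian covariance has a unit diagonal — convenient for
#' reading simulated rates directly as trait variances.
#'
#' @param n_tips number of tips (>= 2).
#' @param seed integer seed; identical seeds give identical trees.
#' @return a `phylo` object with tips `t1 ... tn`.
#' @export
simulate_tree <- function(n_tips, seed = 1) {
  stopifnot(n_tips >= 2)
  tree <- with_seed(seed, ape::rphylo(n_tips, birth = 1, death = 0))
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  validate_phylogeny(tree)
}

#' Simulate correlated, phylogenetically structured predictors
#'
#' Draws a species-by-predictor matrix from the matrix-normal model with
#' among-species covariance `V(lambda_pred)` (the lambda-transformed
#' Brownian covariance of the tree) and among-predictor covariance
#' `predictor_cov`: `X = L_v Z L_c'` with iid standard-normal `Z`. This
#' gives independent control of phylogenetic signal and cross-trait
#' collinearity — the two ingredients whose interaction the multiverse
#' analysis probes. Empirical trait correlations converge to
#' `predictor_cov` as the number of tips grows.
#'
#' @param tree a `phylo` object.
#' @param predictor_cov symmetric positive-semidefinite k x k matrix
#'   (unit diagonal for a correlation target); column names, if any, name
#'   the predictors.
#' @param lambda_pred Pagel's lambda of the predictors' phylogenetic
#'   signal.
#' @param seed integer seed.
#' @param means optional numeric vector of predictor means (default 0).
#' @return a data frame with a `species` column and one numeric column per
#'   predictor.
#' @export
simulate_predictors <- function(tree, predictor_cov, lambda_pred = 1,
                                seed = 1, means = NULL) {
  tree <- validate_phylogeny(tree)
  C <- as.matrix(predictor_cov)
  stopifnot(nrow(C) == ncol(C))
  if (max(abs(C - t(C))) > 1e-10) stop("predictor_cov must be symmetric")
  Lc <- tryCatch(chol(C), error = function(e)
    stop("predictor_cov is not positive definite", call. = FALSE))
  V <- lambda_transform(vcv_matrix(tree), lambda_pred)
  Lv <- t(chol(V))
  n <- nrow(V); k <- ncol(C)
  Z <- with_seed(seed, matrix(stats::rnorm(n * k), n, k))
  X <- Lv %*% Z %*% Lc
  if (!is.null(means)) X <- sweep(X, 2, rep_len(means, k), `+`)
  nm <- colnames(C) %||% paste0("x", seq_len(k))
  out <- data.frame(species = rownames(V), X, stringsAsFactors = FALSE)
  names(out)[-1] <- nm
  rownames(out) <- NULL
  out
}

#' Simulate a response under the PGLS generative model
#'
#' `y = X beta + e`, `e ~ N(0, sigma2 * V(lambda_resid))` — the generative
#' counterpart of the model the PGLS fit estimates, so fitting the
#' simulated data at the true lambda is an unbiased estimation pipeline.
#'
#' @param predictors data frame from [simulate_predictors()] (a `species`
#'   column plus numeric predictors).
#' @param beta named coefficient vector; must contain `(Intercept)` and
#'   one entry per predictor column used (every non-species column of
#'   `predictors` named in `beta`).
#' @param tree the `phylo` object the species came from.
#' @param lambda_resid residual Pagel's lambda.
#' @param sigma2 residual rate (variance per unit branch length).
#' @param seed integer seed.
#' @return numeric response vector aligned to `predictors$species`.
#' @export
simulate_response <- function(predictors, beta, tree, lambda_resid = 1,
                              sigma2 = 0.05, seed = 1) {
  stopifnot(is.data.frame(predictors), "species" %in% names(predictors),
            sigma2 >= 0)
  vars <- setdiff(names(beta), "(Intercept)")
  if (!"(Intercept)" %in% names(beta))
    stop("beta must include an '(Intercept)' entry")
  miss <- setdiff(vars, names(predictors))
  if (length(miss))
    stop("beta names not found among predictor columns: ",
         paste(miss, collapse = ", "))
  X <- cbind(`(Intercept)` = 1,
             as.matrix(predictors[, vars, drop = FALSE]))
  mu <- drop(X %*% beta[c("(Intercept)", vars)])
  if (sigma2 == 0) return(mu)
  V <- lambda_transform(vcv_matrix(tree), lambda_resid)
  sp <- normalize_labels(predictors$species)
  V <- V[sp, sp, drop = FALSE]
  eps <- with_seed(seed,
                   drop(t(chol(sigma2 * V)) %*% stats::rnorm(length(mu))))
  mu + eps
}

# Default correlation structure of the paper-like fixture: body mass
# correlates moderately with every candidate, and candidates correlate
# 0.3-0.8 among themselves (a compound-symmetry-like band), matching the
# substantial-but-not-degenerate collinearity typical of primate
# socioecological variables.
fixture_cor <- function() {
  nm <- c("female_weight", "female_group_size", "male_group_size",
          "female_sexual_maturity", "life_span", "innovation", "fruit")
  C <- matrix(0.45, 7, 7, dimnames = list(nm, nm))
  C["female_group_size", "male_group_size"] <-
    C["male_group_size", "female_group_size"] <- 0.75
  C["female_sexual_maturity", "life_span"] <-
    C["life_span", "female_sexual_maturity"] <- 0.65
  C["innovation", "fruit"] <- C["fruit", "innovation"] <- 0.35
  C["female_weight", "female_sexual_maturity"] <-
    C["female_sexual_maturity", "female_weight"] <- 0.6
  C["female_weight", "life_span"] <-
    C["life_span", "female_weight"] <- 0.6
  diag(C) <- 1
  C
}

#' Generate the paper-like synthetic fixture
#'
#' A fully synthetic stand-in for the empirical design the package targets:
#' 40 species on an ultrametric pure-birth tree, six candidate predictors
#' (female/male group size, female sexual maturity, life span, innovation,
#' percent-fruit proxy) plus the mandatory body-size covariate (female
#' weight), all phylogenetically structured and substantially collinear,
#' and two log-scale outcomes (total brain, neocortex) generated under the
#' PGLS model with known coefficients at lambda = 1. Body size dominates
#' both outcomes (covariate-only R2 >= 0.9), so the candidates compete for
#' a small residual signal — the regime in which multiverse p-values are
#' unstable. Everything is reproducible from the seed; the default seed is
#' the version shipped with the package and exercised by its tests.
#'
#' @param profile fixture profile; only `"paper-like"` is defined.
#' @param seed integer seed (default: the shipped fixture's seed).
#' @param n_tips number of species.
#' @return a list with `tree` (`phylo`), `data` (data frame: species,
#'   female_weight, six candidates, total_brain, neocortex), and `meta`
#'   (list: seed, beta vectors, sigma2, lambda, candidate names).
#' @export
#' @examples
#' fx <- make_fixture(seed = 1)
#' head(fx$data)
make_fixture <- function(profile = "paper-like", seed = 20190722L,
                         n_tips = 40) {
  profile <- match.arg(profile)
  C <- fixture_cor()
  candidates <- setdiff(colnames(C), "female_weight")
  tree <- simulate_tree(n_tips, seed = seed)
  preds <- simulate_predictors(tree, C, lambda_pred = 1, seed = seed + 1L)
  # put variables on trait-like scales: log body mass spans ~4 log units,
  # candidates ~1 log unit
  scales <- c(female_weight = 1.4, female_group_size = 0.55,
              male_group_size = 0.6, female_sexual_maturity = 0.45,
              life_span = 0.4, innovation = 0.7, fruit = 0.35)
  centers <- c(female_weight = 1.5, female_group_size = 2.3,
               male_group_size = 1.7, female_sexual_maturity = 1.4,
               life_span = 3.0, innovation = 0.8, fruit = 0.6)
  for (v in colnames(C))
    preds[[v]] <- centers[[v]] + scales[[v]] * preds[[v]]
  beta_brain <- c(`(Intercept)` = 5.0, female_weight = 0.62,
                  female_group_size = 0.10, male_group_size = -0.07,
                  life_span = 0.22, female_sexual_maturity = 0.10,
                  innovation = 0, fruit = 0.20)
  beta_neo <- c(`(Intercept)` = 4.2, female_weight = 0.58,
                female_group_size = 0.22, male_group_size = -0.10,
                life_span = 0.18, female_sexual_maturity = 0.15,
                innovation = 0, fruit = 0)
  sigma2 <- 0.022
  dat <- preds
  dat$total_brain <- simulate_response(preds, beta_brain, tree,
                                       lambda_resid = 1, sigma2 = sigma2,
                                       seed = seed + 2L)
  dat$neocortex <- simulate_response(preds, beta_neo, tree,
                                     lambda_resid = 1, sigma2 = sigma2,
                                     seed = seed + 3L)
  list(tree = tree, data = dat,
       meta = list(profile = profile, seed = seed, n_tips = n_tips,
                   candidates = candidates, mandatory = "female_weight",
                   outcomes = c("total_brain", "neocortex"),
                   beta_total_brain = beta_brain,
                   beta_neocortex = beta_neo,
                   sigma2 = sigma2, lambda = 1,
                   predictor_cor = C))
}
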