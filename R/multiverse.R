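#' Enumerate all predictor-subset model specifications
#'
#' Builds one [model_spec()] for every non-empty subset of the candidate
#' predictors (2^k - 1 models for k candidates), each with the mandatory
#' covariates prepended. Order is deterministic: by subset size, then
#' lexicographically in the order the candidates were given — this order is
#' also the tie-breaker used everywhere downstream.
#'
#' @param outcome outcome variable name.
#' @param candidates character vector of candidate predictor names.
#' @param mandatory character vector of always-included covariates.
#' @return a list of `model_spec` objects of length `2^k - 1`.
#' @export
#' @examples
#' length(enumerate_models("y", paste0("x", 1:6), "mass"))  # 63
enumerate_models <- function(outcome, candidates, mandatory = character()) {
  candidates <- as.character(candidates)
  if (!length(candidates)) stop("need at least one candidate predictor")
  if (anyDuplicated(candidates))
    stop("duplicate candidate names: ",
         paste(unique(candidates[duplicated(candidates)]), collapse = ", "))
  if (length(intersect(candidates, mandatory)))
    stop("candidates and mandatory sets must be disjoint")
  k <- length(candidates)
  specs <- list()
  for (size in seq_len(k)) {
    idx <- utils::combn(k, size, simplify = FALSE)
    for (s in idx)
      specs[[length(specs) + 1L]] <-
        model_spec(outcome, focal = candidates[s], mandatory = mandatory)
  }
  names(specs) <- vapply(specs,
                         function(s) paste(s$focal, collapse = "+"),
                         character(1))
  specs
}

#' Fit the full multiverse of predictor subsets
#'
#' Fits every model from [enumerate_models()] on a single shared species
#' set: the complete cases over the outcome, the mandatory covariates and
#' *all* candidates, intersected with the tree. Holding the species set
#' fixed across models is what makes the AIC values comparable and what the
#' single N reported for every model requires. Individual model failures
#' (e.g. rank deficiency) are recorded, not fatal; lambda fallbacks are
#' collected as messages.
#'
#' @inheritParams fit_pgls
#' @param outcome outcome variable name.
#' @param candidates candidate predictor names.
#' @param mandatory always-included covariate names.
#' @param alpha two-sided significance threshold used by the stability
#'   summaries (default 0.05).
#' @return an object of class `multiverse_result` with elements `fits`
#'   (named list of `pgls_fit`, in enumeration order), `failures` (named
#'   character vector of error messages), `outcome`, `candidates`,
#'   `mandatory`, `alpha`, `n`, `species`, `notes`.
#' @export
run_multiverse <- function(data, tree, outcome, candidates,
                           mandatory = character(), policy = "estimate",
                           alpha = 0.05, species_col = "species") {
  specs <- enumerate_models(outcome, candidates, mandatory)
  vars <- c(outcome, mandatory, candidates)
  cc <- complete_cases_phylo(data, tree, vars, species_col = species_col)
  fits <- list()
  failures <- character()
  notes <- character()
  for (id in names(specs)) {
    res <- withCallingHandlers(
      tryCatch(fit_pgls(cc$data, specs[[id]], cc$tree, policy = policy,
                        species_col = species_col),
               error = function(e) e),
      warning = function(w) {
        notes[[id]] <<- conditionMessage(w)
        invokeRestart("muffleWarning")
      })
    if (inherits(res, "error")) failures[[id]] <- conditionMessage(res)
    else fits[[id]] <- res
  }
  structure(list(outcome = outcome, candidates = as.character(candidates),
                 mandatory = as.character(mandatory), alpha = alpha,
                 fits = fits, failures = failures, notes = notes,
                 n = nrow(cc$data),
                 species = normalize_labels(cc$data[[species_col]]),
                 dropped = cc$dropped),
            class = "multiverse_result")
}

#' @export
print.multiverse_result <- function(x, ...) {
  cat("Multiverse:", x$outcome, "~ [", paste(x$candidates, collapse = ", "),
      "] +", paste(x$mandatory, collapse = " + "), "\n")
  cat(length(x$fits), "fitted models,", length(x$failures), "failures, N =",
      x$n, "\n")
  invisible(x)
}

#' AIC-best model of a multiverse
#'
#' Returns the fitted model with minimal AIC among the successful fits.
#' Ties are broken toward fewer focal predictors, then enumeration order.
#'
#' @param result a `multiverse_result`.
#' @return the winning `pgls_fit`.
#' @export
best_by_aic <- function(result) {
  stopifnot(inherits(result, "multiverse_result"))
  if (!length(result$fits)) stop("no successful fits to select among")
  aics <- vapply(result$fits, function(f) f$aic, numeric(1))
  sizes <- vapply(result$fits, function(f) length(f$spec$focal), numeric(1))
  ord <- order(aics, sizes, seq_along(aics))
  result$fits[[ord[1L]]]
}

#' Flatten a multiverse to one row per (model, term)
#'
#' @param result a `multiverse_result`.
#' @return a data frame with columns model_id, outcome, focal_set, term,
#'   b, se, t, p, lambda, lambda_fixed, aic, r2, n — the flat export from
#'   which every stability summary can be recomputed.
#' @export
multiverse_table <- function(result) {
  stopifnot(inherits(result, "multiverse_result"))
  rows <- lapply(names(result$fits), function(id)
    as.data.frame(result$fits[[id]], model_id = id))
  do.call(rbind, c(rows, make.row.names = FALSE))
}

# p-value of `predictor` in each fit of `result` that contains it,
# in enumeration order, named by model id.
predictor_pvalues <- function(result, predictor) {
  ids <- names(result$fits)[vapply(result$fits, function(f)
    predictor %in% f$spec$focal, logical(1))]
  stats::setNames(vapply(ids, function(id)
    result$fits[[id]]$p_values[[predictor]], numeric(1)), ids)
}

#' Count non-significant models per predictor
#'
#' For each candidate predictor, counts in how many of the models
#' containing it the two-sided p-value exceeds `alpha` (strictly:
#' `p == alpha` counts as significant). With k candidates each predictor
#' appears in 2^(k-1) models, so the counts read "m / 2^(k-1)".
#'
#' @param result a `multiverse_result`.
#' @param alpha significance threshold; defaults to the one stored in
#'   `result`.
#' @return a data frame of class `stability_table` with columns
#'   `predictor`, `n_models`, `n_nonsignificant`.
#' @export
significance_counts <- function(result, alpha = result$alpha) {
  stopifnot(inherits(result, "multiverse_result"))
  rows <- lapply(result$candidates, function(v) {
    p <- predictor_pvalues(result, v)
    data.frame(predictor = v, n_models = length(p),
               n_nonsignificant = sum(p > alpha),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  attr(out, "alpha") <- alpha
  class(out) <- c("stability_table", "data.frame")
  out
}

#' Extreme p-values per predictor and their concomitant sets
#'
#' For each candidate predictor, the minimum and maximum p-value it
#' attains across the models containing it, together with the concomitant
#' focal predictors of the attaining model (the focal set minus the
#' predictor itself; mandatory covariates, present in every model, are not
#' listed). Ties go to the first model in enumeration order.
#'
#' @param result a `multiverse_result`.
#' @return a data frame of class `stability_table` with columns
#'   `predictor`, `min_p`, `min_p_concomitants`, `max_p`,
#'   `max_p_concomitants` (concomitant sets as "+"-joined strings, empty
#'   string for none).
#' @export
p_extremes <- function(result) {
  stopifnot(inherits(result, "multiverse_result"))
  concomitants <- function(id, v) {
    setdiff(result$fits[[id]]$spec$focal, v)
  }
  rows <- lapply(result$candidates, function(v) {
    p <- predictor_pvalues(result, v)
    imin <- which.min(p)  # first attaining index = enumeration order
    imax <- which.max(p)
    data.frame(
      predictor = v,
      min_p = unname(p[imin]),
      min_p_concomitants = paste(concomitants(names(p)[imin], v),
                                 collapse = "+"),
      max_p = unname(p[imax]),
      max_p_concomitants = paste(concomitants(names(p)[imax], v),
                                 collapse = "+"),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  class(out) <- c("stability_table", "data.frame")
  out
}

#' Combined per-predictor stability summary
#'
#' Joins [significance_counts()] and [p_extremes()] into one table: for
#' each candidate predictor, how often it was non-significant and how far
#' its p-value travelled as concomitant predictors changed.
#'
#' @inheritParams significance_counts
#' @return a `stability_table` data frame.
#' @export
stability_table <- function(result, alpha = result$alpha) {
  out <- merge(significance_counts(result, alpha), p_extremes(result),
               by = "predictor", sort = FALSE)
  out <- out[match(result$candidates, out$predictor), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  class(out) <- c("stability_table", "data.frame")
  out
}
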