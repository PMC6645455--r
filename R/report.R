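# Display-round a p-value the way comparative-analysis tables do:
# three decimals, with values under 0.0005 rendered "<0.000". Only the
# markdown rendering uses this; CSV exports always carry full precision.
format_p <- function(p) {
  ifelse(p < 5e-4, "<0.000", sprintf("%.3f", p))
}

md_table <- function(df) {
  cells <- vapply(df, function(col)
    if (is.numeric(col)) sprintf("%.3f", col) else as.character(col),
    character(nrow(df)))
  cells <- matrix(cells, nrow = nrow(df))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(cells, 1, function(r)
    paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, body)
}

write_manifest <- function(dir, config) {
  manifest <- c(list(package = "pglsverse",
                     version = as.character(
                       utils::packageVersion("pglsverse"))),
                config)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Write a single-model PGLS report
#'
#' Emits the term table (b, se, t, p) plus the model summary (R2, lambda,
#' N, AIC) as a full-precision CSV and a rounded markdown table in the
#' style of comparative-analysis result tables (p under 0.0005 shown as
#' "<0.000"; the intercept row is kept in the CSV but omitted from the
#' markdown display).
#'
#' @param fit a `pgls_fit`.
#' @param dir output directory (created if needed).
#' @param name file stem.
#' @return invisibly, the paths written.
#' @export
report_fit <- function(fit, dir, name = "fit") {
  stopifnot(inherits(fit, "pgls_fit"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  flat <- as.data.frame(fit, model_id = name)
  csv <- file.path(dir, paste0(name, ".csv"))
  utils::write.csv(flat, csv, row.names = FALSE)
  show <- flat[flat$term != "(Intercept)", c("term", "b", "se", "t", "p")]
  show$p <- format_p(show$p)
  names(show) <- c("Predictor", "b", "se", "t", "p")
  md <- c(md_table(show), "",
          sprintf("R2 %.3f | lambda %.3g%s | N %d | AIC %.3f",
                  fit$r2, fit$lambda,
                  if (fit$lambda_fixed) " (fixed)" else "", fit$n, fit$aic))
  mdp <- file.path(dir, paste0(name, ".md"))
  writeLines(md, mdp)
  invisible(c(csv = csv, md = mdp))
}

#' Write the full multiverse report
#'
#' Writes, for one multiverse run: the flat one-row-per-(model, term)
#' fits table, the per-predictor non-significance counts and p-value
#' extremes (CSV plus markdown), the AIC-best model report, a failure
#' summary, and a run manifest. Outputs are deterministic given the run,
#' so re-running the same configuration reproduces the files byte for
#' byte.
#'
#' @param result a `multiverse_result`.
#' @param dir output directory.
#' @return invisibly, the output directory.
#' @export
report_multiverse <- function(result, dir) {
  stopifnot(inherits(result, "multiverse_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(multiverse_table(result),
                   file.path(dir, "fits.csv"), row.names = FALSE)
  counts <- significance_counts(result)
  utils::write.csv(counts, file.path(dir, "significance_counts.csv"),
                   row.names = FALSE)
  ext <- p_extremes(result)
  utils::write.csv(ext, file.path(dir, "p_extremes.csv"), row.names = FALSE)
  cshow <- data.frame(Predictor = counts$predictor,
                      `Non-significant` = sprintf("%d/%d",
                        counts$n_nonsignificant, counts$n_models),
                      check.names = FALSE)
  eshow <- data.frame(`Focal predictor` = ext$predictor,
                      `Min p` = format_p(ext$min_p),
                      `Concomitants (min)` = gsub("\\+", ", ",
                                                  ext$min_p_concomitants),
                      `Max p` = format_p(ext$max_p),
                      `Concomitants (max)` = gsub("\\+", ", ",
                                                  ext$max_p_concomitants),
                      check.names = FALSE)
  writeLines(c(md_table(cshow), "", md_table(eshow)),
             file.path(dir, "stability.md"))
  best <- best_by_aic(result)
  report_fit(best, dir, name = "best_model")
  if (length(result$failures))
    utils::write.csv(data.frame(model_id = names(result$failures),
                                error = unname(result$failures)),
                     file.path(dir, "failures.csv"), row.names = FALSE)
  write_manifest(dir, list(
    outcome = result$outcome, candidates = result$candidates,
    mandatory = result$mandatory, alpha = result$alpha, n = result$n,
    n_models = length(result$fits), n_failures = length(result$failures)))
  invisible(dir)
}

#' Write a collinearity diagnostics report
#'
#' CSV blocks mirroring the usual supplementary-table shapes: the VIF
#' table (OLS and whitened-PGLS columns with the conventional >10 flag),
#' the predictor correlation matrix, the partial-R2 table, and the
#' posterior slope-correlation matrix with its seed and draw count.
#'
#' @param report a `diagnostics_report` from [diagnose_collinearity()].
#' @param dir output directory.
#' @return invisibly, the output directory.
#' @export
report_diagnostics <- function(report, dir) {
  stopifnot(inherits(report, "diagnostics_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  viftab <- data.frame(predictor = names(report$vif_ols),
                       vif_ols = unname(report$vif_ols),
                       vif_pgls = unname(report$vif_pgls),
                       flag_gt_10 = unname(report$vif_ols > 10 |
                                             report$vif_pgls > 10))
  utils::write.csv(viftab, file.path(dir, "vif.csv"), row.names = FALSE)
  utils::write.csv(report$correlation,
                   file.path(dir, "correlation_matrix.csv"))
  utils::write.csv(data.frame(term = names(report$partial_r2),
                              partial_r2 = unname(report$partial_r2)),
                   file.path(dir, "partial_r2.csv"), row.names = FALSE)
  utils::write.csv(report$posterior_correlation,
                   file.path(dir, "posterior_correlation.csv"))
  write_manifest(dir, list(n_draws = report$n_draws, seed = report$seed,
                           lambda = report$lambda))
  invisible(dir)
}

#' Write a synthetic fixture to disk
#'
#' Drives [make_fixture()] and writes the Newick tree, the trait CSV, and
#' a YAML metadata file echoing the generating seed and true parameters —
#' so a fixture on disk can always be regenerated and checked.
#'
#' @inheritParams make_fixture
#' @param dir output directory.
#' @return invisibly, the fixture list.
#' @export
write_fixture <- function(dir, profile = "paper-like", seed = 20190722L,
                          n_tips = 40) {
  fx <- make_fixture(profile = profile, seed = seed, n_tips = n_tips)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ape::write.tree(fx$tree, file.path(dir, "fixture_tree.nwk"))
  utils::write.csv(fx$data, file.path(dir, "fixture_traits.csv"),
                   row.names = FALSE)
  meta <- fx$meta
  meta$predictor_cor <- apply(meta$predictor_cor, 1, as.list)
  yaml::write_yaml(meta, file.path(dir, "fixture_meta.yaml"))
  invisible(fx)
}

#' Load and validate a run configuration
#'
#' Reads a YAML run configuration (paths to the tree and trait table,
#' outcome, mandatory covariate, candidate predictors, optional transform
#' rules, alpha, lambda policy, seed, output directory) and validates the
#' fields needed by [run_config()].
#'
#' @param path path to a YAML file.
#' @return a named list (class `run_config`).
#' @export
load_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  req <- c("tree", "traits", "outcome", "candidates")
  miss <- setdiff(req, names(cfg))
  if (length(miss))
    stop("run config is missing field(s): ", paste(miss, collapse = ", "))
  cfg$mandatory <- cfg$mandatory %||% character()
  cfg$alpha <- cfg$alpha %||% 0.05
  cfg$policy <- cfg$policy %||% "estimate"
  cfg$seed <- cfg$seed %||% 1L
  cfg$out <- cfg$out %||% "pglsverse_output"
  structure(cfg, class = "run_config")
}

#' Run a configured multiverse analysis end to end
#'
#' The programmatic entry point tying the pipeline together: read the
#' tree and trait table, apply any configured transforms, run the
#' multiverse for each configured outcome, write reports (and diagnostics
#' for the full model) under the configured output directory.
#'
#' @param config a `run_config` (or path to a YAML file).
#' @return invisibly, a named list of `multiverse_result`s, one per
#'   outcome.
#' @export
run_config <- function(config) {
  if (is.character(config)) config <- load_run_config(config)
  tree <- read_newick(config$tree, file = TRUE)
  traits <- utils::read.csv(config$traits, stringsAsFactors = FALSE)
  traits$species <- normalize_labels(traits$species)
  if (!is.null(config$transforms))
    traits <- apply_transforms(traits, unlist(config$transforms))
  results <- list()
  for (outcome in config$outcome) {
    res <- run_multiverse(traits, tree, outcome,
                          candidates = unlist(config$candidates),
                          mandatory = unlist(config$mandatory),
                          policy = config$policy, alpha = config$alpha)
    report_multiverse(res, file.path(config$out, outcome))
    diag <- diagnose_collinearity(
      res$fits[[paste(res$candidates, collapse = "+")]],
      seed = config$seed)
    report_diagnostics(diag, file.path(config$out, outcome, "diagnostics"))
    results[[outcome]] <- res
  }
  invisible(results)
}
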