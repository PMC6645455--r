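#' Pool multi-source trait tables by weighted averaging
#'
#' Combines several species-by-trait tables into one by taking, for each
#' species-variable cell, the weighted average of the values reported by
#' the sources that report it (missing values simply do not contribute).
#' This is the standard way comparative datasets are assembled from
#' heterogeneous literature compilations. Provenance (which sources
#' contributed to each cell, with what weights) is recorded as an attribute.
#'
#' @param sources a list of data frames, each with a species column and
#'   shared variable names/units. If a source declares units via
#'   `attr(x, "units")` (named character vector), unit strings must agree
#'   across sources for shared variables.
#' @param weights numeric vector of per-source weights (recycled to the
#'   number of sources), all `>= 0` and not all zero. Default: equal
#'   weights. The choice of weights (e.g. per-source sample sizes) is the
#'   caller's; it is recorded in the provenance.
#' @param species_col name of the species column.
#' @return a data frame with one row per species (union over sources) and
#'   the union of variables, with attributes `provenance` (data frame) and
#'   `units` (if any source declared them).
#' @export
#' @examples
#' a <- data.frame(species = "A", mass = 10)
#' b <- data.frame(species = "A", mass = 20)
#' pool_weighted(list(a, b), weights = c(1, 3))$mass  # 17.5
pool_weighted <- function(sources, weights = NULL, species_col = "species") {
  stopifnot(is.list(sources), length(sources) >= 1L)
  ns <- length(sources)
  if (is.null(weights)) weights <- rep(1, ns)
  weights <- rep_len(as.numeric(weights), ns)
  if (any(is.na(weights)) || any(weights < 0))
    stop("weights must be nonnegative numbers")
  if (all(weights == 0)) stop("weights must not all be zero")
  src_names <- names(sources) %||% paste0("source", seq_len(ns))
  src_names[src_names == ""] <- paste0("source", which(src_names == ""))

  units <- list()
  for (i in seq_len(ns)) {
    u <- attr(sources[[i]], "units")
    for (v in names(u)) {
      if (!is.null(units[[v]]) && units[[v]] != u[[v]])
        stop("unit mismatch for variable '", v, "': '", units[[v]],
             "' vs '", u[[v]], "'")
      units[[v]] <- u[[v]]
    }
    if (!species_col %in% names(sources[[i]]))
      stop("source ", src_names[i], " lacks a '", species_col, "' column")
    sources[[i]][[species_col]] <- normalize_labels(
      sources[[i]][[species_col]])
    if (anyDuplicated(sources[[i]][[species_col]]))
      stop("source ", src_names[i], " has duplicated species rows")
  }

  species <- sort(unique(unlist(lapply(sources,
                                       function(s) s[[species_col]]))))
  vars <- setdiff(unique(unlist(lapply(sources, names))), species_col)
  out <- data.frame(species = species, stringsAsFactors = FALSE)
  names(out)[1] <- species_col
  prov <- list()
  for (v in vars) {
    num <- stats::setNames(rep(0, length(species)), species)
    den <- num
    contrib <- stats::setNames(rep("", length(species)), species)
    for (i in seq_len(ns)) {
      s <- sources[[i]]
      if (!v %in% names(s)) next
      val <- s[[v]]
      has <- !is.na(val)
      sp <- s[[species_col]][has]
      num[sp] <- num[sp] + weights[i] * val[has]
      den[sp] <- den[sp] + weights[i]
      contrib[sp] <- ifelse(contrib[sp] == "", src_names[i],
                            paste(contrib[sp], src_names[i], sep = ";"))
    }
    out[[v]] <- ifelse(den > 0, num / den, NA_real_)
    rep_sp <- species[den > 0]
    if (length(rep_sp))
      prov[[v]] <- data.frame(species = rep_sp, variable = v,
                              sources = contrib[rep_sp],
                              weight_sum = unname(den[den > 0]),
                              stringsAsFactors = FALSE)
  }
  attr(out, "provenance") <- do.call(rbind, c(prov, make.row.names = FALSE))
  attr(out, "pool_weights") <- stats::setNames(weights, src_names)
  if (length(units)) attr(out, "units") <- unlist(units)
  attr(out, "transforms") <- stats::setNames(rep("raw", length(vars)), vars)
  out
}

#' Apply the standard comparative-data transforms
#'
#' Natural log for strictly positive continuous variables (sizes, counts,
#' durations) and the arcsine-square-root transform for percentage
#' variables (percent is divided by 100 first, so 25 percent maps to
#' `asin(sqrt(0.25)) = pi/6`). Transform state is tracked per column and a
#' second application to an already-transformed column is rejected rather
#' than silently compounding.
#'
#' @param table a data frame (e.g. from [pool_weighted()]).
#' @param rules named character vector mapping column names to one of
#'   `"log"`, `"arcsine_sqrt"`, `"none"`.
#' @return the transformed data frame, with the `transforms` attribute
#'   updated.
#' @export
#' @examples
#' d <- data.frame(species = "A", mass = 2.718282, fruit = 25)
#' t <- apply_transforms(d, c(mass = "log", fruit = "arcsine_sqrt"))
apply_transforms <- function(table, rules) {
  stopifnot(is.data.frame(table), is.character(rules),
            !is.null(names(rules)))
  bad <- setdiff(names(rules), names(table))
  if (length(bad))
    stop("rules name column(s) absent from the table: ",
         paste(bad, collapse = ", "))
  state <- attr(table, "transforms") %||%
    stats::setNames(rep("raw", ncol(table)), names(table))
  sp <- if ("species" %in% names(table)) table$species
        else rownames(table)
  for (v in names(rules)) {
    rule <- match.arg(rules[[v]], c("log", "arcsine_sqrt", "none"))
    if (rule == "none") next
    cur <- if (v %in% names(state) && !is.na(state[v])) state[[v]] else "raw"
    if (cur != "raw")
      stop("column '", v, "' is already transformed (", cur,
           "); refusing to transform twice")
    x <- table[[v]]
    if (!is.numeric(x)) stop("column '", v, "' is not numeric")
    if (rule == "log") {
      nonpos <- which(!is.na(x) & x <= 0)
      if (length(nonpos))
        stop("log transform of '", v, "' undefined for nonpositive ",
             "values; species: ",
             paste(sp[nonpos] %||% nonpos, collapse = ", "))
      table[[v]] <- log(x)
      state[v] <- "log"
    } else {
      over <- which(!is.na(x) & (x < 0 | x > 100))
      if (length(over))
        stop("'", v, "' has percentage values outside [0, 100]; species: ",
             paste(sp[over] %||% over, collapse = ", "))
      table[[v]] <- asin(sqrt(x / 100))
      state[v] <- "arcsine_sqrt"
    }
  }
  attr(table, "transforms") <- state
  table
}

#' Derive lifespan from maximum age and age at sexual maturity
#'
#' Lifespan is the adult period: maximum recorded age at death minus age at
#' female sexual maturity, in years, computed before any log transform.
#' A non-positive difference flags a data problem and raises an error
#' rather than returning a nonsensical lifespan.
#'
#' @param max_age numeric vector of maximum recorded ages (years).
#' @param sexual_maturity numeric vector of ages at sexual maturity (years).
#' @return numeric vector of lifespans; `NA` where either input is `NA`.
#' @export
derive_lifespan <- function(max_age, sexual_maturity) {
  stopifnot(length(max_age) == length(sexual_maturity))
  ok <- !is.na(max_age) & !is.na(sexual_maturity)
  if (any(sexual_maturity[ok] <= 0))
    stop("sexual maturity must be positive; offending position(s): ",
         paste(which(ok & sexual_maturity <= 0), collapse = ", "))
  bad <- which(ok & max_age <= sexual_maturity)
  if (length(bad))
    stop("max_age <= sexual_maturity (data problem) at position(s): ",
         paste(bad, collapse = ", "))
  ifelse(ok, max_age - sexual_maturity, NA_real_)
}

#' Restrict a trait table and tree to complete cases
#'
#' Keeps the species with no missing value on every listed variable *and*
#' present in the phylogeny, prunes the tree to match, and reports each
#' dropped species with the reason (which variables were missing, or
#' absence from the tree).
#'
#' @param table data frame with a species column.
#' @param tree a `phylo` object.
#' @param variables character vector of required columns.
#' @param species_col name of the species column.
#' @return a list with `data` (the filtered table), `tree` (pruned), and
#'   `dropped` (data frame of species and reason).
#' @export
complete_cases_phylo <- function(table, tree, variables,
                                 species_col = "species") {
  stopifnot(is.data.frame(table))
  if (!species_col %in% names(table))
    stop("table lacks a '", species_col, "' column")
  miss <- setdiff(variables, names(table))
  if (length(miss))
    stop("variable(s) absent from the table: ", paste(miss, collapse = ", "))
  tree <- validate_phylogeny(tree)
  sp <- normalize_labels(table[[species_col]])
  table[[species_col]] <- sp
  reasons <- character(nrow(table))
  for (i in seq_len(nrow(table))) {
    mv <- variables[vapply(variables,
                           function(v) is.na(table[[v]][i]), logical(1))]
    r <- character()
    if (length(mv)) r <- paste0("missing: ", paste(mv, collapse = ", "))
    if (!sp[i] %in% tree$tip.label) r <- c(r, "not in tree")
    reasons[i] <- paste(r, collapse = "; ")
  }
  keep <- reasons == ""
  dropped <- data.frame(species = sp[!keep], reason = reasons[!keep],
                        stringsAsFactors = FALSE)
  extra_tips <- setdiff(tree$tip.label, sp)
  if (length(extra_tips))
    dropped <- rbind(dropped,
                     data.frame(species = extra_tips,
                                reason = "tip not in trait table",
                                stringsAsFactors = FALSE))
  if (sum(keep) < 2L)
    stop("fewer than 2 species with complete data and a tree position")
  tr <- if (length(setdiff(tree$tip.label, sp[keep])))
    prune_and_match(tree, sp[keep]) else tree
  list(data = table[keep, , drop = FALSE], tree = tr, dropped = dropped)
}
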