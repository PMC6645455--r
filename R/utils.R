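#' Normalize taxon labels
#'
#' Strips surrounding single or double quotes and replaces runs of spaces
#' with underscores, so Newick tip labels and trait-table species names
#' match under the usual space/underscore ambiguity. Case is preserved.
#'
#' @param x character vector of labels.
#' @return character vector of normalized labels.
#' @export
#' @examples
#' normalize_labels(c("'Homo sapiens'", "Pan_troglodytes"))
normalize_labels <- function(x) {
  x <- trimws(as.character(x))
  x <- gsub("^['\"]+|['\"]+$", "", x)
  gsub("[ ]+", "_", x)
}

# Evaluate `code` under set.seed(seed), restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
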