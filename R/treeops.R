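#' Read and validate a Newick phylogeny
#'
#' Parses a Newick string into an [ape::phylo] object and enforces the
#' contract PGLS needs: every edge carries a finite, nonnegative branch
#' length; tip labels are unique after [normalize_labels()] normalization;
#' and no tip sits at zero distance from the root (which would imply zero
#' trait variance for that species).
#'
#' @param text a Newick string (must end in `;`), or a path to a file
#'   containing one when `file = TRUE`.
#' @param file logical; treat `text` as a file path.
#' @return an object of class `phylo`, rooted, with normalized tip labels.
#' @export
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' tr$tip.label
read_newick <- function(text, file = FALSE) {
  if (file) text <- paste(readLines(text, warn = FALSE), collapse = "")
  stopifnot(is.character(text), length(text) == 1L)
  check_newick_syntax(text)
  tree <- ape::read.tree(text = text)
  if (is.null(tree))
    stop("Newick parse failed near character offset ", nchar(text), ": ",
         substr(text, max(1, nchar(text) - 20), nchar(text)))
  validate_phylogeny(tree)
}

# Pre-scan a Newick string, reporting the first offending character offset.
# ape::read.tree returns NULL (or NaN edge lengths) silently; this supplies
# the explicit errors the package contracts promise.
check_newick_syntax <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  in_quote <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "'") in_quote <- !in_quote
    if (in_quote) next
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("malformed Newick: unbalanced ')' at character offset ", i)
    }
  }
  if (in_quote) stop("malformed Newick: unterminated quote")
  if (depth != 0L)
    stop("malformed Newick: ", depth, " unclosed '(' at character offset ",
         length(chars))
  if (!grepl(";\\s*$", text))
    stop("malformed Newick: missing terminating ';' at character offset ",
         length(chars))
  invisible(TRUE)
}

#' Validate a phylogeny for comparative analysis
#'
#' @param tree a `phylo` object.
#' @return the tree, with tip labels normalized, invisibly usable downstream.
#' @export
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths; every edge must carry a length")
  bad <- which(!is.finite(tree$edge.length))
  if (length(bad)) {
    tips <- edge_tip_hint(tree, bad)
    stop("missing or non-finite branch length on ", length(bad),
         " edge(s)", tips)
  }
  if (any(tree$edge.length < 0))
    stop("negative branch length(s) found; lengths must be nonnegative")
  tree$tip.label <- normalize_labels(tree$tip.label)
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup))
    stop("duplicate tip labels after normalization: ",
         paste(dup, collapse = ", "))
  depths <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  zero <- tree$tip.label[depths <= 0]
  if (length(zero))
    stop("tip(s) at zero root-to-tip distance (degenerate variance): ",
         paste(zero, collapse = ", "))
  tree
}

# Name the tips subtended by offending edges, when identifiable.
edge_tip_hint <- function(tree, edge_idx) {
  kids <- tree$edge[edge_idx, 2]
  tips <- kids[kids <= ape::Ntip(tree)]
  if (!length(tips)) return("")
  paste0(" (leading to tip(s): ",
         paste(tree$tip.label[tips], collapse = ", "), ")")
}

#' Brownian-motion variance-covariance matrix of a phylogeny
#'
#' Entry (i, j) is the summed branch length from the root to the most
#' recent common ancestor of tips i and j; the diagonal holds root-to-tip
#' distances. This matrix is the residual covariance structure (up to the
#' rate sigma^2 and a lambda transform) of the PGLS model.
#'
#' @param tree a validated `phylo` object.
#' @return a symmetric numeric matrix with tip labels as dimnames.
#' @details A `root.edge` on the tree (e.g. the stem retained by
#'   [prune_and_match()]) is ancestral to every tip and is added to every
#'   entry of the matrix.
#' @export
#' @examples
#' vcv_matrix(read_newick("((A:1,B:1):1,C:2);"))
vcv_matrix <- function(tree) {
  tree <- validate_phylogeny(tree)
  V <- ape::vcv.phylo(tree)
  if (!is.null(tree$root.edge) && is.finite(tree$root.edge) &&
      tree$root.edge > 0)
    V <- V + tree$root.edge
  V
}

#' Pagel's lambda transform of a phylogenetic covariance matrix
#'
#' Multiplies the off-diagonal entries by `lambda`, leaving the diagonal
#' untouched. `lambda = 1` returns the Brownian-motion matrix unchanged;
#' `lambda = 0` removes all shared history (PGLS collapses to a
#' heteroskedastic OLS). The transform preserves positive semidefiniteness
#' for `lambda` in [0, 1], which is why the domain is restricted there.
#'
#' @param V symmetric covariance matrix (e.g. from [vcv_matrix()]).
#' @param lambda scalar in \[0, 1\].
#' @return the transformed matrix.
#' @export
lambda_transform <- function(V, lambda) {
  stopifnot(is.matrix(V), nrow(V) == ncol(V))
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 0 || lambda > 1)
    stop("lambda must be a single value in [0, 1]; got ", lambda)
  d <- diag(V)
  Vl <- lambda * V
  diag(Vl) <- d
  Vl
}

#' Prune a phylogeny to a taxon set, preserving path lengths
#'
#' Returns the induced subtree on `taxa`: removed-tip edges are dropped and
#' resulting degree-2 internal nodes collapsed with their edge lengths
#' summed. When the kept taxa all descend from one child of the original
#' root, the stem between the old root and their MRCA is retained as the
#' pruned tree's `root.edge`, so every root-to-tip and shared-path length
#' is preserved exactly and the VCV of the pruned tree equals the
#' corresponding submatrix of the original VCV.
#'
#' @param tree a `phylo` object.
#' @param taxa character vector of tip labels to keep (normalized or not).
#' @return the pruned `phylo` object.
#' @export
prune_and_match <- function(tree, taxa) {
  tree <- validate_phylogeny(tree)
  taxa <- normalize_labels(taxa)
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing))
    stop("taxa absent from the tree: ", paste(missing, collapse = ", "))
  if (length(taxa) < 2L) stop("need at least 2 taxa to keep")
  pruned <- ape::keep.tip(tree, taxa)
  tip_depth <- function(tr, lab) {
    d <- ape::node.depth.edgelength(tr)[match(lab, tr$tip.label)]
    d + (tr$root.edge %||% 0)
  }
  stem <- tip_depth(tree, taxa[1]) - tip_depth(pruned, taxa[1])
  if (stem > 1e-12) pruned$root.edge <- stem
  pruned
}
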