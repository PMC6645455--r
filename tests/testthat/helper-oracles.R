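# Independent oracles, deliberately naive: dense inverses, explicit path
# intersections, brute-force scans. They share no code with the package
# internals they check.

# GLS estimator by explicit dense matrix inversion.
gls_oracle <- function(y, X, V) {
  Vi <- solve(V)
  b <- solve(t(X) %*% Vi %*% X) %*% t(X) %*% Vi %*% y
  n <- length(y)
  r <- y - X %*% b
  qf <- drop(t(r) %*% Vi %*% r)
  sigma2 <- qf / n
  loglik <- -0.5 * (n * log(2 * pi) + n * log(sigma2) +
                      determinant(V, logarithm = TRUE)$modulus + n)
  list(b = drop(b), sigma2 = sigma2, loglik = as.numeric(loglik))
}

# Phylogenetic VCV by explicit root-path intersection: the shared branch
# length of two tips is the summed length of the edges on both root paths.
vcv_oracle <- function(tree) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  parent <- integer(max(tree$edge))
  elen <- numeric(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  path_edges <- function(tip) {
    e <- integer()
    node <- tip
    while (node != root) {
      e <- c(e, node)  # identify each edge by its child node
      node <- parent[node]
    }
    e
  }
  paths <- lapply(seq_len(ntip), path_edges)
  V <- matrix(0, ntip, ntip,
              dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(ntip))
    for (j in seq_len(ntip))
      V[i, j] <- sum(elen[intersect(paths[[i]], paths[[j]])])
  V
}

# A random non-ultrametric test tree with strictly positive branch lengths.
random_tree <- function(n, seed) {
  pglsverse:::with_seed(seed, {
    tr <- ape::rtree(n)
    tr$edge.length <- tr$edge.length + 0.1
    tr
  })
}

# Star phylogeny with unit tip edges.
star_tree <- function(n) {
  txt <- paste0("(", paste0("t", seq_len(n), ":1", collapse = ","), ");")
  ape::read.tree(text = txt)
}

# A design matrix with two standardized columns of exact sample
# correlation r (constructed by Gram-Schmidt, so the correlation is exact
# to machine precision).
exact_cor_design <- function(n, r, seed = 1) {
  pglsverse:::with_seed(seed, {
    z <- matrix(rnorm(n * 2), n, 2)
    z <- scale(qr.Q(qr(cbind(1, z)))[, 2:3]) / sqrt((n - 1) / n)
    x1 <- z[, 1]
    x2 <- r * z[, 1] + sqrt(1 - r^2) * z[, 2]
    s <- cbind(x1 = x1 / stats::sd(x1), x2 = x2 / stats::sd(x2))
    sweep(s, 2, colMeans(s))
  })
}

# Minimal aligned data set for single-fit tests.
sim_dataset <- function(n = 40, k = 3, r = 0.5, lambda = 1,
                        beta = NULL, sigma2 = 0.05, seed = 1) {
  tree <- simulate_tree(n, seed = seed)
  C <- matrix(r, k, k); diag(C) <- 1
  colnames(C) <- rownames(C) <- paste0("x", seq_len(k))
  preds <- simulate_predictors(tree, C, lambda_pred = 1, seed = seed + 1L)
  if (is.null(beta))
    beta <- c(`(Intercept)` = 1,
              stats::setNames(c(0.6, rep(0.2, k - 1)), paste0("x", 1:k)))
  preds$y <- simulate_response(preds, beta, tree, lambda_resid = lambda,
                               sigma2 = sigma2, seed = seed + 2L)
  list(tree = tree, data = preds, beta = beta)
}
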