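# Independent oracles used across tests. These deliberately avoid the
# package's own code paths.

# brute-force phylogenetic covariance: walk root-to-node paths explicitly
brute_force_vcv <- function(tree, taxa = tree$tip.label) {
  n_all <- ape::Ntip(tree) + tree$Nnode
  parent <- rep(NA_integer_, n_all)
  plen <- rep(NA_real_, n_all)
  for (e in seq_len(nrow(tree$edge))) {
    parent[tree$edge[e, 2]] <- tree$edge[e, 1]
    plen[tree$edge[e, 2]] <- tree$edge.length[e]
  }
  path_to_root <- function(node) {
    out <- integer(0)
    while (!is.na(parent[node])) { out <- c(out, node); node <- parent[node] }
    out # nodes whose parent-edges are on the path
  }
  idx <- match(taxa, tree$tip.label)
  C <- matrix(0, length(idx), length(idx), dimnames = list(taxa, taxa))
  paths <- lapply(idx, path_to_root)
  for (i in seq_along(idx)) {
    for (j in seq_along(idx)) {
      shared <- intersect(paths[[i]], paths[[j]])
      C[i, j] <- sum(plen[shared])
    }
  }
  C
}

# a seeded random bifurcating tree with positive branch lengths
random_tree <- function(n, seed) {
  withr::with_seed(seed, {
    tr <- ape::rtree(n)
    tr$edge.length <- stats::runif(nrow(tr$edge), 0.1, 2)
    tr
  })
}

# dense multivariate-normal log-density via determinant() and solve(),
# independent of the package's Cholesky route
dense_mvn_loglik <- function(x, mu, S) {
  r <- x - mu
  ld <- as.numeric(determinant(S, logarithm = TRUE)$modulus)
  -0.5 * (length(x) * log(2 * pi) + ld + drop(t(r) %*% solve(S, r)))
}

# tiny trait tibble for a tree, from a named value vector
trait_frame <- function(values, extant = NULL) {
  tibble::tibble(
    taxon = names(values), value = unname(values),
    extant = extant %||% rep(TRUE, length(values))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

quick_settings <- function(seed = 1L, iterations = 10000, burn_in = 4000,
                           thin = 10, sample_nodes = TRUE) {
  mcmc_settings(iterations = iterations, burn_in = burn_in, thin = thin,
                seed = seed, sample_nodes = sample_nodes)
}
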