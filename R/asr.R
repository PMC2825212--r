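#' Ancestral states by weighted squared-change parsimony
#'
#' Internal node states minimise the sum over branches of
#' `(child - parent)^2 / branch_length`. The minimiser solves a sparse linear
#' (weighted graph Laplacian) system and is unique. Zero-length branches
#' (from polytomy resolution or fossils last seen at their attachment node)
#' are contracted: child and parent share one state, so resolution order can
#' never change an estimate.
#'
#' @param data Trait tibble with `taxon` column (all tips must have values).
#' @param tree A `phylo` object.
#' @param trait Trait column name.
#' @return Tibble with `node`, `age`, `method = "parsimony"`, `estimate`
#'   for every internal node.
#' @export
asr_parsimony <- function(data, tree, trait = "log10_brain") {
  check_tree_traits(tree, data)
  if (!setequal(data$taxon, tree$tip.label)) {
    abort("every tip needs a trait value (and no extras): prune the tree or complete the data")
  }
  x <- setNames(data[[trait]], data$taxon)[tree$tip.label]
  n_tip <- ape::Ntip(tree)
  n_all <- n_tip + tree$Nnode
  len <- tree$edge.length
  tol <- 1e-12

  # contract zero-length edges (union-find)
  parent_uf <- seq_len(n_all)
  find <- function(i) { while (parent_uf[i] != i) { parent_uf[i] <<- parent_uf[parent_uf[i]]; i <- parent_uf[i] }; i }
  for (e in which(len <= tol)) {
    a <- find(tree$edge[e, 1]); b <- find(tree$edge[e, 2])
    if (a != b) parent_uf[b] <- a
  }
  grp <- vapply(seq_len(n_all), find, integer(1))
  groups <- unique(grp)
  gid <- match(grp, groups)
  n_grp <- length(groups)

  # fixed groups: those containing >= 1 tip
  gval <- rep(NA_real_, n_grp)
  for (i in seq_len(n_tip)) {
    g <- gid[i]
    if (is.na(gval[g])) gval[g] <- x[i]
    else if (abs(gval[g] - x[i]) > 1e-9) {
      abort("two tips joined by zero-length branches carry different values: parsimony problem is infeasible")
    }
  }
  fixed <- !is.na(gval)
  free <- which(!fixed)

  if (length(free)) {
    keep <- len > tol
    gp <- gid[tree$edge[keep, 1]]
    gc <- gid[tree$edge[keep, 2]]
    w <- 1 / len[keep]
    # Laplacian over groups
    L <- matrix(0, n_grp, n_grp)
    for (k in seq_along(w)) {
      i <- gp[k]; j <- gc[k]
      L[i, i] <- L[i, i] + w[k]; L[j, j] <- L[j, j] + w[k]
      L[i, j] <- L[i, j] - w[k]; L[j, i] <- L[j, i] - w[k]
    }
    rhs <- -L[free, fixed, drop = FALSE] %*% gval[fixed]
    sol <- tryCatch(solve(L[free, free, drop = FALSE], rhs),
                    error = function(e) abort("disconnected parsimony system: no finite-weight path to data"))
    gval[free] <- drop(sol)
  }
  internal <- n_tip + seq_len(tree$Nnode)
  ages <- node_ages(tree)
  tibble(
    node = internal,
    age = ages$age[internal],
    method = "parsimony",
    estimate = gval[gid[internal]]
  )
}

# covariance of every node (tips and internals) with every other: shared
# root-to-MRCA path length under a kappa-transformed tree
full_node_vcv <- function(tree, kappa = 1) {
  kt <- kappa_tree(tree, kappa)
  d <- node_depths(kt)
  M <- ape::mrca(tree, full = TRUE)
  C <- matrix(d[M], nrow(M), ncol(M))
  rownames(C) <- colnames(C) <- c(tree$tip.label, as.character(ape::Ntip(tree) + seq_len(tree$Nnode)))
  list(C = C, depth = d)
}

#' Ancestral states by maximum likelihood under Brownian motion
#'
#' Each internal node's estimate is its conditional expectation given the tip
#' data under the (optionally directional) Brownian model, with the root and
#' drift profiled by GLS; the standard error includes the uncertainty of the
#' estimated root/drift, so deeper nodes have larger SE on ultrametric trees.
#' Point estimates coincide with weighted squared-change parsimony (both are
#' the mode of the same Gaussian joint density).
#'
#' @inheritParams asr_parsimony
#' @param directional Include a drift term (needs path-length variation).
#' @param kappa Fixed branch-length power transform applied throughout.
#' @return Tibble with `node`, `age`, `method = "ml"`, `estimate`, `se`.
#' @export
asr_ml <- function(data, tree, trait = "log10_brain", directional = FALSE, kappa = 1) {
  check_tree_traits(tree, data)
  if (!setequal(data$taxon, tree$tip.label)) {
    abort("every tip needs a trait value (and no extras)")
  }
  x <- setNames(data[[trait]], data$taxon)[tree$tip.label]
  n_tip <- ape::Ntip(tree)
  fv <- full_node_vcv(tree, kappa)
  tip_idx <- seq_len(n_tip)
  int_idx <- n_tip + seq_len(tree$Nnode)
  C <- fv$C[tip_idx, tip_idx, drop = FALSE]
  p_tip <- fv$depth[tip_idx]
  if (directional && paths_ultrametric(p_tip)) {
    abort("directional model requires root-to-tip path-length variation")
  }
  X <- if (directional) cbind(1, p_tip) else cbind(rep(1, n_tip))
  g <- gls_profile(x, C, X)
  theta <- as.numeric(g$theta)
  ch <- g$chol
  resid <- x - drop(X %*% theta)

  Cn <- fv$C[int_idx, tip_idx, drop = FALSE]       # node-to-tip covariances
  v_node <- diag(fv$C)[int_idx]
  A <- backsolve(ch, t(Cn), transpose = TRUE)       # chol^-T C_n^T
  Rs <- backsolve(ch, resid, transpose = TRUE)
  Xs <- backsolve(ch, X, transpose = TRUE)
  Xd <- if (directional) cbind(1, fv$depth[int_idx]) else cbind(rep(1, length(int_idx)))
  est <- drop(Xd %*% theta) + drop(crossprod(A, Rs))
  # conditional variance + propagation of GLS coefficient uncertainty
  XtXinv <- solve(g$XtX)
  D <- Xd - t(crossprod(Xs, A))                     # rows: d_a' = x_a' - c_a' Cinv X
  var_cond <- v_node - colSums(A^2) + rowSums((D %*% XtXinv) * D)
  var_cond <- pmax(var_cond, 0) * g$alpha
  ages <- node_ages(tree)
  tibble(
    node = int_idx,
    age = ages$age[int_idx],
    method = "ml",
    estimate = unname(est),
    se = sqrt(var_cond)
  )
}

#' Log harmonic mean of likelihoods from a log-likelihood trace
#'
#' Computed stably in log space: `log(n) - logsumexp(-loglik)`. The harmonic
#' mean is the marginal-likelihood estimator used by the Bayes-factor trend
#' tests; it is retained for methodological fidelity despite its well-known
#' instability.
#'
#' @param loglik Numeric vector of sampled log-likelihoods.
#' @return Scalar log harmonic mean.
#' @export
log_harmonic_mean <- function(loglik) {
  if (!length(loglik)) abort("empty log-likelihood trace")
  neg <- -loglik
  m <- max(neg)
  log(length(loglik)) - (m + log(sum(exp(neg - m))))
}

#' Bayes factor from two log harmonic means
#'
#' `BF = 2 * (logHM_A - logHM_B)`. Evidence for model A over B is read as:
#' BF > 2 positive, > 5 strong, > 10 very strong, otherwise none.
#'
#' @param log_hm_a,log_hm_b Log harmonic means (A typically the richer model).
#' @return One-row tibble with `log_hm_a`, `log_hm_b`, `bayes_factor`,
#'   `verdict`.
#' @export
bayes_factor <- function(log_hm_a, log_hm_b) {
  if (!is.finite(log_hm_a) || !is.finite(log_hm_b)) abort("log harmonic means must be finite")
  bf <- 2 * (log_hm_a - log_hm_b)
  verdict <- if (bf > 10) "very strong" else if (bf > 5) "strong" else if (bf > 2) "positive" else "none"
  tibble(log_hm_a = log_hm_a, log_hm_b = log_hm_b, bayes_factor = bf, verdict = verdict)
}

#' Spearman congruence between two sets of node estimates
#'
#' Rank correlation (average ranks for ties, two-sided p) between estimates of
#' the same nodes produced by two methods or data treatments (e.g. with vs
#' without fossils).
#'
#' @param est_a,est_b Numeric vectors, or tibbles with `node` and `estimate`
#'   columns (joined on `node`).
#' @return One-row tibble with `r_s`, `p_value`, `n`.
#' @export
congruence <- function(est_a, est_b) {
  if (is.data.frame(est_a)) {
    joined <- dplyr::inner_join(
      dplyr::select(est_a, "node", a = "estimate"),
      dplyr::select(est_b, "node", b = "estimate"),
      by = "node"
    )
    a <- joined$a; b <- joined$b
  } else {
    a <- est_a; b <- est_b
  }
  if (length(a) < 3) abort("need at least 3 shared nodes for a rank correlation")
  ct <- suppressWarnings(cor.test(a, b, method = "spearman", exact = FALSE))
  rs <- unname(cor(rank(a), rank(b)))
  tibble(r_s = rs, p_value = ct$p.value, n = length(a))
}
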