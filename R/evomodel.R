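#' Pagel branch-length transforms applied to a phylogenetic covariance
#'
#' kappa raises each branch length to the power kappa before the covariance is
#' assembled (kappa = 0 collapses every branch to equal length: punctuational
#' change; kappa = 1 is gradualism). lambda multiplies the off-diagonal
#' entries (lambda = 0 is a star phylogeny: no phylogenetic signal). delta
#' raises the assembled covariance entries to the power delta (delta < 1
#' concentrates change early, > 1 late). (1, 1, 1) is the identity.
#' Order: kappa at branch level, then lambda, then delta.
#'
#' @param tree A `phylo` object.
#' @param kappa,lambda,delta Scaling parameters; `kappa, delta >= 0`,
#'   `0 <= lambda <= 1`.
#' @param taxa Optional tip subset/ordering.
#' @return Transformed covariance matrix.
#' @export
transform_covariance <- function(tree, kappa = 1, lambda = 1, delta = 1, taxa = NULL) {
  check_scaling(kappa, lambda, delta)
  C <- phylo_vcv(kappa_tree(tree, kappa), taxa = taxa)
  apply_lambda_delta(C, lambda, delta)
}

check_scaling <- function(kappa, lambda, delta) {
  if (kappa < 0) abort("kappa must be >= 0")
  if (delta < 0) abort("delta must be >= 0")
  if (lambda < 0 || lambda > 1) abort("lambda must lie in [0, 1]")
  invisible(TRUE)
}

kappa_tree <- function(tree, kappa) {
  if (kappa == 1) return(tree)
  out <- tree
  out$edge.length <- tree$edge.length^kappa
  out
}

apply_lambda_delta <- function(C, lambda, delta) {
  if (lambda != 1) {
    d <- diag(C)
    C <- C * lambda
    diag(C) <- d
  }
  if (delta != 1) C <- C^delta
  C
}

#' Log-likelihood of a (possibly directional) Brownian random walk
#'
#' The tip vector is multivariate normal with mean
#' `root_state + beta * path_length` and covariance `alpha * C`. `beta = 0` is
#' the constant-variance (non-directional) model; a non-zero drift `beta` is
#' only identifiable when root-to-tip path lengths vary (fossil tips).
#'
#' @param x Named trait vector (names must match `rownames(C)` if both named).
#' @param C Phylogenetic covariance (Myr).
#' @param alpha Instantaneous variance of evolution (trait^2 per Myr).
#' @param root_state Trait value at the root.
#' @param beta Directional trend per Myr.
#' @param paths Root-to-tip path lengths; defaults to `diag(C)`, which is
#'   correct for an untransformed covariance.
#' @return The log-likelihood (scalar).
#' @export
bm_loglik <- function(x, C, alpha, root_state, beta = 0, paths = diag(C)) {
  if (length(x) != nrow(C)) abort("length(x) must equal dim(C)")
  if (alpha <= 0) abort("alpha must be > 0")
  if (!is.null(names(x)) && !is.null(rownames(C))) x <- x[rownames(C)]
  mu <- root_state + beta * paths
  mvn_loglik(x - mu, alpha * C)
}

mvn_loglik <- function(r, S) {
  ch <- tryCatch(chol(S), error = function(e) {
    dup <- which(duplicated(round(S, 12)))
    abort(paste0(
      "singular phylogenetic covariance",
      if (length(dup)) sprintf(" (duplicate structure at rows %s)", paste(dup, collapse = ","))
      else "", ": ", conditionMessage(e)
    ))
  })
  z <- backsolve(ch, r, transpose = TRUE)
  -0.5 * (length(r) * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(z^2))
}

# GLS profile of the mean coefficients and ML alpha given C (with unit rate).
# X: design matrix (n x p). Returns coefficients, alpha_ml, max loglik, and
# the pieces needed for standard errors.
gls_profile <- function(x, C, X) {
  ch <- tryCatch(chol(C), error = function(e) abort(paste("singular covariance:", conditionMessage(e))))
  n <- length(x)
  Xs <- backsolve(ch, X, transpose = TRUE)
  xs <- backsolve(ch, x, transpose = TRUE)
  XtX <- crossprod(Xs)
  qrX <- qr(XtX)
  if (qrX$rank < ncol(X)) {
    abort("design is rank-deficient: no root-to-tip path-length variation (directional model needs non-ultrametric data) or constant predictor")
  }
  theta <- solve(qrX, crossprod(Xs, xs))
  rownames(theta) <- colnames(X)
  dimnames(XtX) <- list(colnames(X), colnames(X))
  res <- xs - Xs %*% theta
  rss <- sum(res^2)
  alpha <- rss / n
  loglik <- -0.5 * (n * log(2 * pi * alpha) + 2 * sum(log(diag(ch))) + n)
  list(
    theta = drop(theta), alpha = alpha, loglik = loglik, rss = rss,
    XtX = XtX, chol = ch, n = n
  )
}

#' Fit a Brownian random-walk model by maximum likelihood
#'
#' The root state (and drift, if `directional`) are profiled analytically by
#' GLS and alpha by its closed form; any free scaling parameters are
#' maximised numerically (bounded quasi-Newton, seeded multi-start).
#'
#' @param data Trait tibble with a `taxon` column.
#' @param tree A `phylo` object.
#' @param trait Name of the trait column (string).
#' @param directional Estimate a drift term `beta`? Requires root-to-tip
#'   path-length variation.
#' @param estimate_kappa,estimate_lambda,estimate_delta Free the corresponding
#'   Pagel parameter (otherwise fixed at `kappa`/`lambda`/`delta`).
#' @param kappa,lambda,delta Fixed values when not estimated.
#' @param n_restarts Number of seeded multi-start draws for the numerical
#'   stage (ignored when no scaling parameter is free).
#' @param seed Seed for the restarts.
#' @return An object of class `evo_fit` with elements `params` (tibble),
#'   `loglik`, `n`, and the call ingredients; see [tidy()] / [glance()].
#' @export
fit_ml <- function(data, tree, trait = "log10_brain", directional = FALSE,
                   estimate_kappa = FALSE, estimate_lambda = FALSE,
                   estimate_delta = FALSE, kappa = 1, lambda = 1, delta = 1,
                   n_restarts = 5, seed = 1L) {
  check_tree_traits(tree, data)
  x <- setNames(data[[trait]], data$taxon)
  taxa <- data$taxon
  p <- path_lengths(tree, taxa)
  if (directional && paths_ultrametric(p)) {
    abort("directional model requires root-to-tip path-length variation; this tree is ultrametric over the supplied taxa")
  }
  if (directional && length(x) < 3) abort("need >= 3 taxa to estimate a trend")
  X <- if (directional) cbind(intercept = 1, path = p) else cbind(intercept = rep(1, length(x)))

  eval_at <- function(sc) {
    C <- transform_covariance(tree, sc[["kappa"]], sc[["lambda"]], sc[["delta"]], taxa = taxa)
    gls_profile(x, C, X)
  }
  free <- c(kappa = estimate_kappa, lambda = estimate_lambda, delta = estimate_delta)
  fixed <- c(kappa = kappa, lambda = lambda, delta = delta)
  if (any(free)) {
    lower <- c(kappa = 1e-6, lambda = 0, delta = 1e-6)[free]
    upper <- c(kappa = 3, lambda = 1, delta = 3)[free]
    obj <- function(par) {
      sc <- fixed; sc[names(par)] <- par
      -eval_at(sc)$loglik
    }
    starts <- withr::with_seed(seed, {
      s0 <- fixed[free]
      extra <- purrr::map(seq_len(max(0, n_restarts - 1)), function(i) {
        runif(sum(free), min = lower, max = pmin(upper, 2))
      })
      c(list(s0), extra)
    })
    fits <- purrr::map(starts, function(s0) {
      par0 <- setNames(pmin(pmax(as.numeric(s0), lower), upper), names(lower))
      tryCatch(
        optim(par0, obj, method = "L-BFGS-B", lower = lower, upper = upper,
              control = list(factr = 1e3)),
        error = function(e) NULL
      )
    })
    fits <- purrr::compact(fits)
    best <- fits[[which.min(purrr::map_dbl(fits, "value"))]]
    fixed[names(best$par)] <- best$par
  }
  g <- eval_at(fixed)
  beta <- if (directional) g$theta[["path"]] else 0
  params <- tibble(
    parameter = c("alpha", "root_state", "beta", "kappa", "lambda", "delta"),
    value = c(g$alpha, g$theta[["intercept"]], beta, fixed[["kappa"]],
              fixed[["lambda"]], fixed[["delta"]]),
    estimated = c(TRUE, TRUE, directional, unname(free))
  )
  structure(
    list(
      params = params, loglik = g$loglik, n = g$n, trait = trait,
      directional = directional, scaling = fixed, data = data, tree = tree
    ),
    class = "evo_fit"
  )
}

#' Extract a named parameter from an `evo_fit`
#' @param fit An `evo_fit`.
#' @param name Parameter name (`"alpha"`, `"root_state"`, `"beta"`, ...).
#' @export
evo_param <- function(fit, name) {
  fit$params$value[match(name, fit$params$parameter)]
}

#' Phylogenetic generalized least squares regression
#'
#' GLS regression of one trait on another under the (optionally transformed)
#' Brownian covariance of the tree: the workhorse for the brain-on-body
#' allometry and its residual ("relative brain size") computation.
#'
#' @param data Trait tibble with a `taxon` column.
#' @param formula Two-sided formula, e.g. `log10_brain ~ log10_body`.
#' @param tree A `phylo` object.
#' @inheritParams fit_ml
#' @return An object of class `pgls_fit` with intercept, slope, `t_statistic`
#'   (slope), `df = n - 2`, `r_squared` (GLS metric), per-taxon residuals,
#'   log-likelihood, and the scaling parameters used.
#' @export
pgls <- function(data, formula = log10_brain ~ log10_body, tree,
                 estimate_kappa = FALSE, estimate_lambda = FALSE,
                 estimate_delta = FALSE, kappa = 1, lambda = 1, delta = 1,
                 n_restarts = 5, seed = 1L) {
  check_tree_traits(tree, data)
  vars <- all.vars(formula)
  if (length(vars) != 2) abort("formula must be response ~ predictor")
  y <- setNames(data[[vars[1]]], data$taxon)
  x <- setNames(data[[vars[2]]], data$taxon)
  if (sd(x) == 0) abort("predictor is constant")
  taxa <- data$taxon
  n <- length(y)
  X <- cbind(intercept = 1, slope = x)

  eval_at <- function(sc) {
    C <- transform_covariance(tree, sc[["kappa"]], sc[["lambda"]], sc[["delta"]], taxa = taxa)
    gls_profile(y, C, X)
  }
  free <- c(kappa = estimate_kappa, lambda = estimate_lambda, delta = estimate_delta)
  fixed <- c(kappa = kappa, lambda = lambda, delta = delta)
  if (any(free)) {
    lower <- c(kappa = 1e-6, lambda = 0, delta = 1e-6)[free]
    upper <- c(kappa = 3, lambda = 1, delta = 3)[free]
    obj <- function(par) { sc <- fixed; sc[names(par)] <- par; -eval_at(sc)$loglik }
    starts <- withr::with_seed(seed, c(list(fixed[free]), purrr::map(
      seq_len(max(0, n_restarts - 1)),
      function(i) runif(sum(free), min = lower, max = pmin(upper, 2))
    )))
    fits <- purrr::compact(purrr::map(starts, function(s0) {
      par0 <- setNames(pmin(pmax(as.numeric(s0), lower), upper), names(lower))
      tryCatch(optim(par0, obj, method = "L-BFGS-B", lower = lower, upper = upper,
                     control = list(factr = 1e3)), error = function(e) NULL)
    }))
    best <- fits[[which.min(purrr::map_dbl(fits, "value"))]]
    fixed[names(best$par)] <- best$par
  }
  g <- eval_at(fixed)
  theta <- g$theta
  # classical t-test for the slope with the unbiased variance estimate
  sigma2 <- g$rss / (n - 2)
  covb <- sigma2 * solve(g$XtX)
  t_stat <- theta[["slope"]] / sqrt(covb["slope", "slope"])
  df <- n - 2
  # R^2 in the GLS metric: compare against the GLS-mean-only model
  g0 <- gls_profile(y, transform_covariance(tree, fixed[["kappa"]], fixed[["lambda"]],
                                            fixed[["delta"]], taxa = taxa),
                    cbind(intercept = rep(1, n)))
  r2 <- 1 - g$rss / g0$rss
  fitted <- drop(X %*% theta)
  residuals <- tibble(taxon = taxa, residual = unname(y - fitted))
  structure(
    list(
      intercept = unname(theta[["intercept"]]), slope = unname(theta[["slope"]]),
      t_statistic = unname(t_stat), df = df,
      p_value = 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE),
      r_squared = r2, residuals = residuals, loglik = g$loglik,
      alpha = g$alpha, scaling = fixed, n = n,
      response = vars[1], predictor = vars[2]
    ),
    class = "pgls_fit"
  )
}

#' Likelihood-ratio test for nested models
#'
#' `LR = 2 * (loglik_free - loglik_constrained)`, compared to a chi-square
#' with `df` degrees of freedom (1 by default, the single-scaling-parameter
#' case; the convention is approximate when the constraint sits on a
#' parameter-space boundary, e.g. lambda = 1).
#'
#' @param loglik_free,loglik_constrained Log-likelihoods (or objects with a
#'   `loglik` element, e.g. `evo_fit` / `pgls_fit`).
#' @param df Degrees of freedom of the test.
#' @param null_value The constrained parameter's null value (recorded only).
#' @return A one-row tibble with `statistic`, `df`, `p_value`, `null_value`.
#' @export
lr_test <- function(loglik_free, loglik_constrained, df = 1, null_value = 1) {
  ll1 <- if (is.list(loglik_free)) loglik_free$loglik else loglik_free
  ll0 <- if (is.list(loglik_constrained)) loglik_constrained$loglik else loglik_constrained
  lr <- 2 * (ll1 - ll0)
  if (lr < -1e-6) {
    abort(sprintf("free model fits worse than constrained (LR = %.4g): optimization failure", lr))
  }
  lr <- max(lr, 0)
  tibble(statistic = lr, df = df, p_value = pchisq(lr, df, lower.tail = FALSE),
         null_value = null_value)
}

#' @export
print.evo_fit <- function(x, ...) {
  cat(sprintf("Brownian random-walk fit (%s model) for '%s', n = %d\n",
              if (x$directional) "directional" else "constant-variance",
              x$trait, x$n))
  cat(sprintf("log-likelihood: %.4f\n", x$loglik))
  print(x$params)
  invisible(x)
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf("PGLS: %s = %.4g + %.4g * %s\n", x$response, x$intercept, x$slope, x$predictor))
  cat(sprintf("t_%d = %.3f, R^2 = %.3f, P = %.3g\n", x$df, x$t_statistic, x$r_squared, x$p_value))
  cat(sprintf("scaling: kappa = %.3g, lambda = %.3g, delta = %.3g\n",
              x$scaling[["kappa"]], x$scaling[["lambda"]], x$scaling[["delta"]]))
  invisible(x)
}
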