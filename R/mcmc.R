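#' MCMC settings
#'
#' Defaults follow the study design this package implements: uniform priors
#' on (-100, 100), 2,000,000 post-burn-in iterations sampled every 100 after
#' a burn-in of 500,000, with proposal widths auto-tuned during burn-in only
#' to hit a 20-40% acceptance band (then frozen). Tests and examples use much
#' shorter chains.
#'
#' @param iterations Post-burn-in iterations.
#' @param burn_in Burn-in iterations (discarded; tuning happens here).
#' @param thin Sampling interval; retained draws = `iterations / thin`.
#' @param prior Length-2 numeric: uniform prior bounds for location
#'   parameters (root state, drift, node states). `alpha` and kappa/delta get
#'   `(0, prior[2])` and lambda `(0, 1)`.
#' @param seed Integer seed; identical settings + seed give identical chains.
#' @param sample_nodes Sample internal node states as latent variables
#'   (needed for [asr_mcmc()]); if `FALSE` the chain runs on the marginal tip
#'   likelihood only (much faster; used for trend and scaling tests).
#' @param tune_window Iterations per width-adaptation window during burn-in.
#' @param target_accept Acceptance band targeted by tuning.
#' @return A list of class `mcmc_settings`.
#' @export
mcmc_settings <- function(iterations = 2e6, burn_in = 5e5, thin = 100,
                          prior = c(-100, 100), seed = 1L, sample_nodes = TRUE,
                          tune_window = 1000, target_accept = c(0.2, 0.4)) {
  if (iterations < 1 || burn_in < 0 || thin < 1) abort("invalid chain lengths")
  if (iterations < thin) abort("iterations must be >= thin")
  if (!all(is.finite(prior)) || prior[1] >= prior[2]) abort("prior bounds must be finite and ordered")
  structure(
    list(iterations = as.integer(iterations), burn_in = as.integer(burn_in),
         thin = as.integer(thin), prior = prior, seed = as.integer(seed),
         sample_nodes = isTRUE(sample_nodes), tune_window = as.integer(tune_window),
         target_accept = target_accept),
    class = "mcmc_settings"
  )
}

# contract zero-length edges; returns group structure shared by the parsimony
# solver and the latent-node sampler
zero_contraction <- function(tree, tol = 1e-12) {
  n_tip <- ape::Ntip(tree)
  n_all <- n_tip + tree$Nnode
  len <- tree$edge.length
  uf <- seq_len(n_all)
  find <- function(i) { while (uf[i] != i) { uf[i] <<- uf[uf[i]]; i <- uf[i] }; i }
  for (e in which(len <= tol)) {
    a <- find(tree$edge[e, 1]); b <- find(tree$edge[e, 2])
    if (a != b) uf[b] <- a
  }
  grp <- vapply(seq_len(n_all), find, integer(1))
  groups <- unique(grp)
  gid <- match(grp, groups)
  keep <- len > tol
  list(
    gid = gid, n_grp = length(groups), n_tip = n_tip,
    edge_gp = gid[tree$edge[keep, 1]], edge_gc = gid[tree$edge[keep, 2]],
    edge_len = len[keep]
  )
}

#' Bayesian MCMC fit of the (directional) random-walk model
#'
#' Metropolis-Hastings over the model parameters (`alpha`, `root_state`, and
#' `beta` when `directional`) under uniform priors, optionally jointly with
#' the internal node states as latent variables ("model" and "data" proposal
#' widths are tuned separately during burn-in, mirroring rate-deviation /
#' data-deviation tuning). With `sample_nodes = FALSE` the chain may also
#' sample Pagel scaling parameters named in `estimate_scaling`; the latent
#' sampler itself supports only a *fixed* `kappa` because lambda and delta do
#' not preserve the tree's edge-factorised density.
#'
#' The retained trace stores, for every draw, the marginal tip log-likelihood
#' used by [log_harmonic_mean()] / [bayes_factor()].
#'
#' @inheritParams asr_ml
#' @param settings An [mcmc_settings()] object.
#' @param kappa,lambda,delta Fixed scaling values (lambda/delta must be 1 when
#'   `sample_nodes = TRUE`).
#' @param estimate_scaling Character vector among `"kappa"`, `"lambda"`,
#'   `"delta"` to sample (only with `sample_nodes = FALSE`).
#' @return An object of class `mcmc_run`: `trace` tibble (parameters +
#'   `loglik`), `node_draws` matrix (draws x internal nodes) or `NULL`,
#'   `acceptance` rates, `log_hm`, and the run settings.
#' @export
mcmc_fit <- function(data, tree, trait = "log10_brain", directional = FALSE,
                     settings = mcmc_settings(), kappa = 1, lambda = 1, delta = 1,
                     estimate_scaling = NULL) {
  check_tree_traits(tree, data)
  if (!setequal(data$taxon, tree$tip.label)) abort("every tip needs a trait value (and no extras)")
  stopifnot(inherits(settings, "mcmc_settings"))
  if (settings$sample_nodes) {
    if (lambda != 1 || delta != 1) {
      abort("latent-node sampling supports only kappa among scaling transforms; set lambda = delta = 1 or use sample_nodes = FALSE")
    }
    if (!is.null(estimate_scaling)) abort("estimate_scaling requires sample_nodes = FALSE")
  }
  x <- setNames(data[[trait]], data$taxon)[tree$tip.label]
  p <- path_lengths(tree)
  if (directional && paths_ultrametric(p)) {
    abort("directional model requires root-to-tip path-length variation")
  }
  withr::with_seed(settings$seed, {
    if (settings$sample_nodes) {
      mcmc_joint(x, tree, directional, settings, kappa, trait)
    } else {
      mcmc_marginal(x, tree, directional, settings,
                    c(kappa = kappa, lambda = lambda, delta = delta),
                    estimate_scaling %||% character(0), trait)
    }
  })
}

# O(1) marginal tip loglik machinery: cache Cholesky cross-products so the
# likelihood is a closed form in (alpha, root, beta)
marginal_cache <- function(x, tree, scaling) {
  C <- transform_covariance(tree, scaling[["kappa"]], scaling[["lambda"]], scaling[["delta"]])
  C <- C[names(x), names(x)]
  p <- path_lengths(tree)[names(x)]
  ch <- chol(C)
  sv <- function(v) backsolve(ch, v, transpose = TRUE)
  one <- sv(rep(1, length(x))); pp <- sv(p); xx <- sv(x)
  list(
    n = length(x), logdet = 2 * sum(log(diag(ch))),
    S11 = sum(one^2), S1p = sum(one * pp), Spp = sum(pp^2),
    S1x = sum(one * xx), Spx = sum(pp * xx), Sxx = sum(xx^2)
  )
}

marginal_loglik <- function(cache, alpha, root, beta) {
  Q <- cache$Sxx - 2 * root * cache$S1x - 2 * beta * cache$Spx +
    root^2 * cache$S11 + 2 * root * beta * cache$S1p + beta^2 * cache$Spp
  -0.5 * (cache$n * log(2 * pi * alpha) + cache$logdet + Q / alpha)
}

param_bounds <- function(name, prior) {
  switch(name,
    alpha = c(1e-12, prior[2]),
    kappa = c(0, 3),
    delta = c(0, 3),
    lambda = c(0, 1),
    prior # root_state, beta
  )
}

tune_width <- function(w, rate, band) {
  if (rate < band[1]) w * 0.9 else if (rate > band[2]) w * 1.1 else w
}

# Initialise the chain at the ML solution with proposal widths ~2.4 GLS
# standard errors, so burn-in tuning (x1.1 / x0.9 per window) only fine-tunes.
init_chain <- function(x, tree, directional, sample_scaling, scaling) {
  C <- transform_covariance(tree, scaling[["kappa"]], scaling[["lambda"]], scaling[["delta"]])
  C <- C[names(x), names(x)]
  p <- path_lengths(tree)[names(x)]
  X <- if (directional) cbind(intercept = 1, beta = p) else cbind(intercept = rep(1, length(x)))
  g <- gls_profile(x, C, X)
  th <- c(alpha = unname(g$alpha), root_state = unname(g$theta[["intercept"]]))
  if (directional) th <- c(th, beta = unname(g$theta[["beta"]]))
  for (s in sample_scaling) th <- c(th, setNames(scaling[[s]], s))
  se <- sqrt(diag(g$alpha * solve(g$XtX)))
  w <- c(alpha = unname(g$alpha) * sqrt(2 / g$n), root_state = unname(se[["intercept"]]))
  if (directional) w <- c(w, beta = unname(se[["beta"]]))
  w <- 2.4 * w
  for (s in sample_scaling) w <- c(w, setNames(0.3, s))
  list(theta = th, widths = pmax(w, 1e-9))
}

mcmc_marginal <- function(x, tree, directional, settings, scaling, sample_scaling, trait) {
  prior <- settings$prior
  ini <- init_chain(x, tree, directional, sample_scaling, scaling)
  th <- ini$theta
  pn <- names(th)
  widths <- ini$widths
  cache <- marginal_cache(x, tree, scaling)
  cur_scaling <- scaling
  ll <- function(th, cache) marginal_loglik(cache, th[["alpha"]], th[["root_state"]],
                                            if (directional) th[["beta"]] else 0)
  cur_ll <- ll(th, cache)

  total <- settings$burn_in + settings$iterations
  n_keep <- settings$iterations %/% settings$thin
  keep_par <- matrix(NA_real_, n_keep, length(pn), dimnames = list(NULL, pn))
  keep_ll <- numeric(n_keep)
  acc <- setNames(numeric(length(pn)), pn); prop <- acc
  acc_post <- acc; prop_post <- acc
  k <- 0L
  for (iter in seq_len(total)) {
    for (j in seq_along(pn)) {
      nm <- pn[j]
      cand <- th
      cand[j] <- th[j] + rnorm(1, 0, widths[j])
      prop[j] <- prop[j] + 1
      if (iter > settings$burn_in) prop_post[j] <- prop_post[j] + 1
      b <- param_bounds(nm, prior)
      if (cand[j] <= b[1] && nm %in% c("alpha", "kappa", "delta")) next
      if (cand[j] < b[1] || cand[j] > b[2]) next
      if (nm %in% sample_scaling) {
        cs <- cur_scaling; cs[[nm]] <- cand[j]
        cand_cache <- marginal_cache(x, tree, cs)
        cand_ll <- ll(cand, cand_cache)
        if (log(runif(1)) < cand_ll - cur_ll) {
          th <- cand; cur_ll <- cand_ll; cache <- cand_cache; cur_scaling <- cs
          acc[j] <- acc[j] + 1
          if (iter > settings$burn_in) acc_post[j] <- acc_post[j] + 1
        }
      } else {
        cand_ll <- ll(cand, cache)
        if (log(runif(1)) < cand_ll - cur_ll) {
          th <- cand; cur_ll <- cand_ll
          acc[j] <- acc[j] + 1
          if (iter > settings$burn_in) acc_post[j] <- acc_post[j] + 1
        }
      }
    }
    if (iter <= settings$burn_in && iter %% settings$tune_window == 0) {
      rate <- acc / pmax(prop, 1)
      widths <- mapply(tune_width, widths, rate, MoreArgs = list(band = settings$target_accept))
      acc[] <- 0; prop[] <- 0
    }
    if (iter > settings$burn_in && (iter - settings$burn_in) %% settings$thin == 0) {
      k <- k + 1L
      keep_par[k, ] <- th
      keep_ll[k] <- cur_ll
    }
  }
  finish_run(keep_par, keep_ll, NULL, acc_post / pmax(prop_post, 1), NA_real_,
             settings, tree, trait, directional, widths, NULL)
}

mcmc_joint <- function(x, tree, directional, settings, kappa, trait) {
  prior <- settings$prior
  kt <- kappa_tree(tree, kappa)
  zc <- zero_contraction(kt)
  n_tip <- zc$n_tip

  gval <- rep(NA_real_, zc$n_grp)
  for (i in seq_len(n_tip)) {
    g <- zc$gid[i]
    if (is.na(gval[g])) gval[g] <- x[i]
    else if (abs(gval[g] - x[i]) > 1e-9) abort("two tips joined by zero-length branches differ in value")
  }
  fixed <- !is.na(gval)
  root_grp <- zc$gid[n_tip + 1L]
  if (fixed[root_grp]) abort("root coincides with a tip through zero-length branches; cannot sample root state")
  latent <- setdiff(which(!fixed), root_grp)

  # two-colouring by parity of depth in the contracted tree
  parity <- integer(zc$n_grp)
  kids <- split(seq_along(zc$edge_gp), zc$edge_gp)
  queue <- root_grp
  while (length(queue)) {
    g <- queue[[1]]; queue <- queue[-1]
    for (e in kids[[as.character(g)]] %||% integer(0)) {
      child <- zc$edge_gc[e]
      parity[child] <- 1L - parity[g]
      queue <- c(queue, child)
    }
  }

  # per-colour edge bookkeeping: every edge touches exactly one node of each
  # colour, so simultaneous proposals within a colour stay independent
  colour_sets <- purrr::map(c(0L, 1L), function(cl) {
    idx <- latent[parity[latent] == cl]
    if (!length(idx)) return(NULL)
    touch <- which(zc$edge_gp %in% idx | zc$edge_gc %in% idx)
    owner <- ifelse(zc$edge_gp[touch] %in% idx, zc$edge_gp[touch], zc$edge_gc[touch])
    list(idx = idx, edges = touch, owner_pos = match(owner, idx))
  })
  colour_sets <- purrr::compact(colour_sets)

  s <- gval
  s[!fixed] <- mean(x)
  p_tip <- path_lengths(tree)
  ini <- init_chain(x, tree, directional, character(0), c(kappa = kappa, lambda = 1, delta = 1))
  th <- ini$theta
  pn <- names(th)
  w_par <- ini$widths
  s[root_grp] <- th[["root_state"]] # latent root state tracks the parameter
  # node conditional sd is roughly sqrt(alpha * local branch length)
  w_node <- rep(2.5 * sqrt(th[["alpha"]] * stats::median(zc$edge_len)), zc$n_grp)

  elen <- zc$edge_len
  const_e <- -0.5 * log(2 * pi * elen)
  edge_ll <- function(s, alpha, beta) {
    dev <- s[zc$edge_gc] - s[zc$edge_gp] - beta * elen
    const_e - 0.5 * log(alpha) - dev^2 / (2 * alpha * elen)
  }
  beta_of <- function(th) if (directional) th[["beta"]] else 0
  ell <- edge_ll(s, th[["alpha"]], beta_of(th))
  cache <- marginal_cache(x, tree, c(kappa = kappa, lambda = 1, delta = 1))

  total <- settings$burn_in + settings$iterations
  n_keep <- settings$iterations %/% settings$thin
  keep_par <- matrix(NA_real_, n_keep, length(pn), dimnames = list(NULL, pn))
  keep_ll <- numeric(n_keep)
  internal <- n_tip + seq_len(tree$Nnode)
  keep_nodes <- matrix(NA_real_, n_keep, length(internal),
                       dimnames = list(NULL, as.character(internal)))
  acc_p <- setNames(numeric(length(pn)), pn); prop_p <- acc_p
  accp_post <- acc_p; propp_post <- acc_p
  acc_n <- numeric(zc$n_grp); prop_n <- numeric(zc$n_grp)
  accn_post <- 0; propn_post <- 0
  k <- 0L

  for (iter in seq_len(total)) {
    post <- iter > settings$burn_in
    # --- model parameters (rate deviation) ---
    for (j in seq_along(pn)) {
      nm <- pn[j]
      cand <- th
      cand[j] <- th[j] + rnorm(1, 0, w_par[j])
      prop_p[j] <- prop_p[j] + 1
      if (post) propp_post[j] <- propp_post[j] + 1
      b <- param_bounds(nm, prior)
      if ((nm == "alpha" && cand[j] <= b[1]) || cand[j] < b[1] || cand[j] > b[2]) next
      if (nm == "root_state") {
        s_cand_root <- cand[j]
        touch <- which(zc$edge_gp == root_grp | zc$edge_gc == root_grp)
        s2 <- s; s2[root_grp] <- s_cand_root
        new_e <- edge_ll(s2, cand[["alpha"]], beta_of(cand))[touch]
        dll <- sum(new_e) - sum(ell[touch])
        if (log(runif(1)) < dll) {
          s[root_grp] <- s_cand_root; th <- cand; ell[touch] <- new_e
          acc_p[j] <- acc_p[j] + 1; if (post) accp_post[j] <- accp_post[j] + 1
        }
      } else {
        new_ell <- edge_ll(s, cand[["alpha"]], beta_of(cand))
        if (log(runif(1)) < sum(new_ell) - sum(ell)) {
          th <- cand; ell <- new_ell
          acc_p[j] <- acc_p[j] + 1; if (post) accp_post[j] <- accp_post[j] + 1
        }
      }
    }
    # --- latent node states (data deviation), two-colour sweeps ---
    for (cs in colour_sets) {
      idx <- cs$idx
      eps <- rnorm(length(idx), 0, w_node[idx])
      s_new <- s
      s_new[idx] <- s[idx] + eps
      ok <- s_new[idx] >= prior[1] & s_new[idx] <= prior[2]
      new_e <- edge_ll(s_new, th[["alpha"]], beta_of(th))[cs$edges]
      d <- rowsum(new_e - ell[cs$edges], cs$owner_pos)
      dll_by_pos <- numeric(length(idx))
      dll_by_pos[as.integer(rownames(d))] <- drop(d)
      accept <- ok & (log(runif(length(idx))) < dll_by_pos)
      prop_n[idx] <- prop_n[idx] + 1
      if (post) propn_post <- propn_post + length(idx)
      if (any(accept)) {
        s[idx[accept]] <- s_new[idx[accept]]
        upd <- cs$edges[cs$owner_pos %in% which(accept)]
        ell[upd] <- edge_ll(s, th[["alpha"]], beta_of(th))[upd]
        acc_n[idx[accept]] <- acc_n[idx[accept]] + 1
        if (post) accn_post <- accn_post + sum(accept)
      }
    }
    if (!post && iter %% settings$tune_window == 0) {
      rate_p <- acc_p / pmax(prop_p, 1)
      w_par <- mapply(tune_width, w_par, rate_p, MoreArgs = list(band = settings$target_accept))
      rate_n <- acc_n / pmax(prop_n, 1)
      adj <- ifelse(rate_n < settings$target_accept[1], 0.9,
                    ifelse(rate_n > settings$target_accept[2], 1.1, 1))
      w_node <- w_node * adj
      acc_p[] <- 0; prop_p[] <- 0; acc_n[] <- 0; prop_n[] <- 0
    }
    if (post && (iter - settings$burn_in) %% settings$thin == 0) {
      k <- k + 1L
      keep_par[k, ] <- th
      keep_ll[k] <- marginal_loglik(cache, th[["alpha"]], th[["root_state"]], beta_of(th))
      full <- s
      full[root_grp] <- th[["root_state"]]
      keep_nodes[k, ] <- full[zc$gid[internal]]
    }
  }
  node_acc <- accn_post / max(propn_post, 1)
  finish_run(keep_par, keep_ll, keep_nodes, accp_post / pmax(propp_post, 1),
             node_acc, settings, tree, trait, directional, w_par, w_node)
}

finish_run <- function(keep_par, keep_ll, keep_nodes, acc_params, acc_nodes,
                       settings, tree, trait, directional, widths, node_widths) {
  rates <- c(acc_params, if (!is.na(acc_nodes)) c(nodes = acc_nodes))
  out_of_band <- rates[rates < 0.05 | rates > 0.8]
  if (length(out_of_band)) {
    warn(sprintf("acceptance rate outside [0.05, 0.8] after tuning: %s",
                 paste(sprintf("%s=%.2f", names(out_of_band), out_of_band), collapse = ", ")))
  }
  trace <- as_tibble(keep_par)
  trace$loglik <- keep_ll
  trace$iteration <- seq_len(nrow(trace)) * settings$thin
  structure(
    list(
      trace = trace, node_draws = keep_nodes,
      acceptance = list(params = acc_params, nodes = acc_nodes),
      log_hm = log_harmonic_mean(keep_ll),
      settings = settings, tree = tree, trait = trait, directional = directional,
      proposal_widths = list(params = widths, nodes = node_widths)
    ),
    class = "mcmc_run"
  )
}

#' Posterior summaries of ancestral node states from an MCMC run
#'
#' Per-node posterior mean, central 95% credible interval (2.5/97.5
#' percentiles), and a Shapiro-Wilk normality p-value of the posterior draws
#' (reported only; never used to alter estimates).
#'
#' @param run An `mcmc_run` fitted with `sample_nodes = TRUE`.
#' @param nodes Internal node ids (default: all).
#' @return Tibble with `node`, `age`, `method = "mcmc"`, `estimate`,
#'   `ci95_low`, `ci95_high`, `normality_p`.
#' @export
asr_mcmc <- function(run, nodes = NULL) {
  stopifnot(inherits(run, "mcmc_run"))
  if (is.null(run$node_draws)) abort("run was fitted with sample_nodes = FALSE; no node draws available")
  all_nodes <- as.integer(colnames(run$node_draws))
  nodes <- nodes %||% all_nodes
  bad <- setdiff(nodes, all_nodes)
  if (length(bad)) abort(sprintf("not internal nodes of the tree: %s", paste(bad, collapse = ", ")))
  ages <- node_ages(run$tree)
  draws <- run$node_draws[, as.character(nodes), drop = FALSE]
  purrr::map_dfr(seq_along(nodes), function(i) {
    d <- draws[, i]
    ds <- if (length(d) > 5000) d[round(seq(1, length(d), length.out = 5000))] else d
    np <- if (sd(ds) < 1e-12) NA_real_ else shapiro.test(ds)$p.value
    tibble(
      node = nodes[i], age = ages$age[ages$node == nodes[i]], method = "mcmc",
      estimate = mean(d),
      ci95_low = unname(quantile(d, 0.025)), ci95_high = unname(quantile(d, 0.975)),
      normality_p = np
    )
  })
}

#' Monte-Carlo standard error by batch means
#'
#' @param draws Numeric vector of (thinned) posterior draws.
#' @return Scalar MCSE of the mean.
#' @export
mcse <- function(draws) {
  n <- length(draws)
  nb <- max(floor(sqrt(n)), 2)
  bs <- floor(n / nb)
  means <- vapply(seq_len(nb), function(b) mean(draws[((b - 1) * bs + 1):(b * bs)]), numeric(1))
  sd(means) / sqrt(nb)
}

#' Trend test: directional vs constant-variance random walk by Bayes factor
#'
#' Runs two marginal-likelihood chains (drift free vs drift fixed at zero)
#' and compares their log harmonic means: `BF = 2 * (logHM_directional -
#' logHM_constant)`, read against the 2 / 5 / 10 evidence thresholds.
#' Requires fossil (non-ultrametric) tips for identifiability.
#'
#' @inheritParams mcmc_fit
#' @return One-row tibble: `trait`, harmonic means, `bayes_factor`, `verdict`.
#' @export
trend_test <- function(data, tree, trait = "log10_brain", settings = mcmc_settings(sample_nodes = FALSE),
                       kappa = 1, lambda = 1, delta = 1) {
  settings$sample_nodes <- FALSE
  run_dir <- mcmc_fit(data, tree, trait, directional = TRUE, settings = settings,
                      kappa = kappa, lambda = lambda, delta = delta)
  settings2 <- settings
  settings2$seed <- settings$seed + 1L
  run_con <- mcmc_fit(data, tree, trait, directional = FALSE, settings = settings2,
                      kappa = kappa, lambda = lambda, delta = delta)
  bf <- bayes_factor(run_dir$log_hm, run_con$log_hm)
  dplyr::bind_cols(tibble(trait = trait), bf)
}

#' @export
print.mcmc_run <- function(x, ...) {
  cat(sprintf("MCMC run: %s (%s model), %d retained draws\n", x$trait,
              if (x$directional) "directional" else "constant-variance",
              nrow(x$trace)))
  cat(sprintf("log harmonic mean: %.4f\n", x$log_hm))
  cat("acceptance (params):", paste(sprintf("%s=%.2f", names(x$acceptance$params),
                                            x$acceptance$params), collapse = ", "), "\n")
  if (!is.na(x$acceptance$nodes)) cat(sprintf("acceptance (nodes): %.2f\n", x$acceptance$nodes))
  invisible(x)
}
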