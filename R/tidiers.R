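#' @export
tidy.pgls_fit <- function(x, ...) {
  tibble(
    term = c("intercept", x$predictor),
    estimate = c(x$intercept, x$slope),
    statistic = c(NA_real_, x$t_statistic),
    df = c(NA_real_, x$df),
    p.value = c(NA_real_, x$p_value)
  )
}

#' @export
glance.pgls_fit <- function(x, ...) {
  tibble(
    r.squared = x$r_squared, statistic = x$t_statistic, df = x$df,
    p.value = x$p_value, logLik = x$loglik, nobs = x$n,
    kappa = x$scaling[["kappa"]], lambda = x$scaling[["lambda"]],
    delta = x$scaling[["delta"]]
  )
}

#' @export
augment.pgls_fit <- function(x, ...) x$residuals

#' @importFrom generics augment
#' @export
generics::augment

#' @export
tidy.evo_fit <- function(x, ...) {
  dplyr::rename(x$params, term = "parameter", estimate = "value")
}

#' @export
glance.evo_fit <- function(x, ...) {
  tibble(logLik = x$loglik, nobs = x$n, directional = x$directional,
         trait = x$trait)
}

#' @export
tidy.mcmc_run <- function(x, ...) {
  pars <- setdiff(names(x$trace), c("loglik", "iteration"))
  purrr::map_dfr(pars, function(p) {
    d <- x$trace[[p]]
    tibble(
      term = p, estimate = mean(d), std.error = mcse(d),
      conf.low = unname(quantile(d, 0.025)), conf.high = unname(quantile(d, 0.975))
    )
  })
}

#' @export
glance.mcmc_run <- function(x, ...) {
  tibble(
    log_hm = x$log_hm, n_draws = nrow(x$trace),
    acceptance_params = mean(x$acceptance$params),
    acceptance_nodes = x$acceptance$nodes,
    directional = x$directional, trait = x$trait
  )
}
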