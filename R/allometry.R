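#' Convert brain mass to cranial capacity
#'
#' Uses the empirical primate relationship
#' `log10(cranial capacity) = 1.018 * log10(brain mass) - 0.025`
#' with brain mass in grams and capacity in cm^3.
#'
#' @param brain_g Brain mass in grams (> 0); vectorised.
#' @return Cranial capacity in cm^3.
#' @export
#' @examples
#' cranial_capacity_from_brain_mass(338.75)
cranial_capacity_from_brain_mass <- function(brain_g) {
  if (any(brain_g <= 0)) abort("brain mass must be positive")
  10^(1.018 * log10(brain_g) - 0.025)
}

#' Convert cranial capacity to brain mass
#'
#' Exact inverse of [cranial_capacity_from_brain_mass()].
#'
#' @param cc Cranial capacity in cm^3 (> 0); vectorised.
#' @return Brain mass in grams.
#' @export
brain_mass_from_cranial_capacity <- function(cc) {
  if (any(cc <= 0)) abort("cranial capacity must be positive")
  10^((log10(cc) + 0.025) / 1.018)
}

#' An allometric brain-body regression line with explicit units
#'
#' The line `log10(brain) = intercept + slope * log10(body)` only makes sense
#' together with its unit conventions. Internally everything is converted to
#' grams for both masses; differences of residuals are invariant to the unit
#' choice for a fixed slope, but absolute residuals shift by a constant, so
#' all inter-taxon statistics in this package use differences.
#'
#' @param intercept,slope Regression coefficients on the declared unit scales.
#' @param brain_unit,body_unit `"g"`, `"mg"`, or `"kg"`.
#' @return A list of class `allometry_line` with grams-scale `intercept` and
#'   `slope`.
#' @export
#' @examples
#' # the primate line fitted with brain in mg and body in g:
#' allometry_line(2.18, 0.684, brain_unit = "mg")
allometry_line <- function(intercept, slope, brain_unit = "g", body_unit = "g") {
  if (!is.finite(slope) || !is.finite(intercept)) abort("line coefficients must be finite")
  f <- function(u) switch(u, g = 0, mg = -3, kg = 3, abort("unit must be g, mg or kg"))
  # log10 brain_g = intercept + f(brain) + slope * (log10 body_g - f(body))
  structure(
    list(
      intercept = intercept + f(brain_unit) - slope * f(body_unit),
      slope = slope,
      declared = list(intercept = intercept, slope = slope,
                      brain_unit = brain_unit, body_unit = body_unit)
    ),
    class = "allometry_line"
  )
}

#' @export
print.allometry_line <- function(x, ...) {
  cat(sprintf("allometry line (grams scale): log10(brain_g) = %.4g + %.4g * log10(body_g)\n",
              x$intercept, x$slope))
  invisible(x)
}

#' Build an allometry line from a PGLS fit
#'
#' @param fit A `pgls_fit` of `log10_brain ~ log10_body` (grams scale).
#' @return An `allometry_line`.
#' @export
as_allometry_line <- function(fit) {
  stopifnot(inherits(fit, "pgls_fit"))
  allometry_line(fit$intercept, fit$slope, brain_unit = "g", body_unit = "g")
}

#' Relative brain size: residual from the allometric line
#'
#' `residual = log10_brain - (intercept + slope * log10_body)`, in log10
#' units, masses in grams.
#'
#' @param log10_brain,log10_body log10 masses in grams; vectorised.
#' @param line An [allometry_line()].
#' @return Numeric residuals.
#' @export
residual_brain <- function(log10_brain, log10_body, line) {
  stopifnot(inherits(line, "allometry_line"))
  log10_brain - (line$intercept + line$slope * log10_body)
}

#' Add a relative-brain-size column to a trait table
#'
#' @param data Trait tibble with `log10_brain`, `log10_body`.
#' @param line An [allometry_line()].
#' @return The tibble with a `residual` column appended.
#' @export
relative_brain <- function(data, line) {
  dplyr::mutate(data, residual = residual_brain(.data$log10_brain, .data$log10_body, line))
}

#' Ancestral relative brain size by two pipelines
#'
#' `residuals_second`: reconstruct brain and body masses separately at every
#' node, then take each node's residual from the extant-fitted line.
#' `residuals_first`: compute tip residuals first, then reconstruct the
#' residuals themselves as the evolving trait. The two agree exactly for any
#' linear reconstruction engine when tips sit on the line, and are strongly
#' rank-correlated in practice.
#'
#' @param data Trait tibble (`taxon`, `log10_brain`, `log10_body`).
#' @param tree A `phylo` object.
#' @param line An [allometry_line()].
#' @param method `"residuals_second"` or `"residuals_first"`.
#' @param engine ASR engine: `"ml"`, `"parsimony"`, or `"mcmc"`.
#' @param directional Use the directional model (engine-dependent support).
#' @param settings [mcmc_settings()] when `engine = "mcmc"`.
#' @return Tibble with `node`, `age`, `method`, `engine`, `residual`.
#' @export
ancestral_relative <- function(data, tree, line,
                               method = c("residuals_second", "residuals_first"),
                               engine = c("ml", "parsimony", "mcmc"),
                               directional = FALSE, settings = NULL) {
  method <- match.arg(method)
  engine <- match.arg(engine)
  run_engine <- function(dat, trait, seed_offset = 0L) {
    switch(engine,
      parsimony = asr_parsimony(dat, tree, trait),
      ml = asr_ml(dat, tree, trait, directional = directional),
      mcmc = {
        st <- settings %||% mcmc_settings(iterations = 2e4, burn_in = 5e3, thin = 10)
        st$seed <- st$seed + seed_offset
        asr_mcmc(mcmc_fit(dat, tree, trait, directional = directional, settings = st))
      }
    )
  }
  if (method == "residuals_second") {
    brain <- run_engine(data, "log10_brain", 0L)
    body <- run_engine(data, "log10_body", 1L)
    out <- dplyr::inner_join(
      dplyr::select(brain, "node", "age", brain = "estimate"),
      dplyr::select(body, "node", body = "estimate"),
      by = "node"
    )
    out$residual <- residual_brain(out$brain, out$body, line)
    dplyr::mutate(
      dplyr::select(out, "node", "age", "residual"),
      method = method, engine = engine, .before = "residual"
    )
  } else {
    dat <- relative_brain(data, line)
    est <- run_engine(dat, "residual", 0L)
    dplyr::mutate(
      dplyr::select(est, "node", "age", residual = "estimate"),
      method = method, engine = engine, .before = "residual"
    )
  }
}
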