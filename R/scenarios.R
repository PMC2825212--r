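#' Envelope of observed brain-mass decreases
#'
#' The range of per-branch statistics observed among brain-mass decreases in
#' a dataset, against which a candidate dwarfism scenario is flagged as
#' within/outside the observed pattern. Build one from your own
#' [decrease_census()] with [as_decrease_envelope()], or use
#' [primate_decrease_envelope()] for published primate-wide reference values.
#'
#' @param ratio_min,ratio_max Range of the brain/body log-change ratio.
#' @param delta_log_brain_min Most extreme observed decrease in log10 brain
#'   mass (a negative number).
#' @param delta_rel_min Most extreme observed decrease in relative brain size
#'   (may be `NA`, in which case the relative-change flag is omitted).
#' @param source Free-text provenance tag.
#' @return A list of class `decrease_envelope`.
#' @export
decrease_envelope <- function(ratio_min, ratio_max, delta_log_brain_min,
                              delta_rel_min = NA_real_, source = "user") {
  if (ratio_min > ratio_max) abort("ratio_min must be <= ratio_max")
  structure(
    list(ratio_min = ratio_min, ratio_max = ratio_max,
         delta_log_brain_min = delta_log_brain_min,
         delta_rel_min = delta_rel_min, source = source),
    class = "decrease_envelope"
  )
}

#' @rdname decrease_envelope
#' @param census A [decrease_census()].
#' @param rel_changes Optional relative-brain [branch_changes()] tibble from
#'   which the relative-decrease bound is taken.
#' @export
as_decrease_envelope <- function(census, rel_changes = NULL) {
  stopifnot(inherits(census, "decrease_census"))
  if (!nrow(census$ratios)) abort("census has no decreasing brain-mass branches")
  rel_min <- if (!is.null(rel_changes)) {
    d <- rel_changes$delta_log[rel_changes$decrease]
    if (length(d)) min(d) else NA_real_
  } else NA_real_
  decrease_envelope(
    ratio_min = census$ratio_range[1], ratio_max = census$ratio_range[2],
    delta_log_brain_min = min(census$ratios$delta_log_brain),
    delta_rel_min = rel_min, source = "computed from decrease census"
  )
}

#' Published primate-wide decrease envelope
#'
#' Reference constants from the primate-wide analysis of brain-mass
#' decreases: across the 10 branches with decreasing absolute brain mass the
#' brain/body log-change ratio averaged 0.265 and ranged 0.006 to 0.825, and
#' the largest observed proportional decrease in brain mass was -0.273 (the
#' terminal mouse-lemur branch). The corresponding bound for relative brain
#' size was not published and is left `NA`. These are dataset-dependent
#' values supplied only as a documented default; prefer an envelope computed
#' from your own census.
#'
#' @return A `decrease_envelope`.
#' @export
primate_decrease_envelope <- function() {
  decrease_envelope(
    ratio_min = 0.006, ratio_max = 0.825,
    delta_log_brain_min = -0.273, delta_rel_min = NA_real_,
    source = "published primate reference values"
  )
}

#' Change in relative brain size implied by a brain change and a brain/body
#' ratio
#'
#' Given the change in log10 brain mass along a lineage and the ratio of
#' brain to body log-changes, the implied body change is
#' `delta_log_brain / ratio` and the change in relative brain size (residual
#' from a line of slope `slope`) is
#' `delta_rel = delta_log_brain - slope * delta_log_brain / ratio`.
#' This per-cell identity lets scenario tables be reproduced from their
#' printed brain-change and ratio columns alone.
#'
#' @param delta_log_brain Change in log10 brain mass.
#' @param ratio Brain/body log-change ratio.
#' @param slope Allometric slope (default 0.684).
#' @return Change in log10 relative brain size.
#' @export
relative_change_from_ratio <- function(delta_log_brain, ratio, slope = 0.684) {
  if (any(ratio == 0)) abort("ratio of zero implies no brain change per body change; undefined")
  delta_log_brain - slope * (delta_log_brain / ratio)
}

#' Evaluate a dwarfism scenario against the decrease envelope
#'
#' Computes, for a candidate ancestor -> small-bodied descendant transition,
#' the change in log10 brain mass, the brain/body log-change ratio, and the
#' change in relative brain size (`delta_rel = delta_log_brain -
#' slope * delta_log_body`, exactly), and flags whether each falls inside the
#' supplied envelope (closed intervals). All statistics are unit-invariant.
#'
#' @param ancestor Label for the ancestor.
#' @param ancestor_brain_g,ancestor_body_g Ancestor masses in grams.
#' @param descendant_brain_g,descendant_body_g Descendant masses in grams.
#' @param line An [allometry_line()] (only its slope enters).
#' @param envelope Optional [decrease_envelope()]; flags are `NA` without it.
#' @return One-row tibble: `ancestor`, `descendant_body_kg`, `ratio`,
#'   `delta_log_brain`, `delta_rel`, `within_ratio_range`,
#'   `within_brain_range`, `within_rel_range`.
#' @export
evaluate_scenario <- function(ancestor, ancestor_brain_g, ancestor_body_g,
                              descendant_brain_g, descendant_body_g,
                              line, envelope = NULL) {
  masses <- c(ancestor_brain_g, ancestor_body_g, descendant_brain_g, descendant_body_g)
  if (any(!is.finite(masses)) || any(masses <= 0)) abort("all masses must be positive and finite")
  stopifnot(inherits(line, "allometry_line"))
  dlb <- log10(descendant_brain_g) - log10(ancestor_brain_g)
  dlbody <- log10(descendant_body_g) - log10(ancestor_body_g)
  if (dlbody == 0) abort("ratio undefined: ancestor and descendant body masses are equal")
  ratio <- dlb / dlbody
  drel <- dlb - line$slope * dlbody
  flag <- function(v, lo, hi) {
    if (is.null(envelope) || is.na(lo) || is.na(hi)) NA else v >= lo & v <= hi
  }
  env <- envelope
  tibble(
    ancestor = ancestor,
    descendant_body_kg = descendant_body_g / 1000,
    ratio = ratio,
    delta_log_brain = dlb,
    delta_rel = drel,
    within_ratio_range = flag(ratio, env$ratio_min %||% NA, env$ratio_max %||% NA),
    within_brain_range = flag(dlb, env$delta_log_brain_min %||% NA, 0),
    within_rel_range = flag(drel, env$delta_rel_min %||% NA, Inf)
  )
}

#' Evaluate a grid of ancestors x descendant body masses
#'
#' One row per (ancestor, body mass) combination, mirroring the layout of
#' published hominin dwarfism scenario tables. Ancestors may be supplied per
#' body-mass hypothesis (a `descendant_body_kg` column in `ancestors`) for
#' analyses where the reconstructed ancestor shifts with the assumed tip
#' mass.
#'
#' @param ancestors Tibble with `ancestor`, `brain_g`, `body_g`, and
#'   optionally `descendant_body_kg` (restricting rows to that hypothesis).
#' @param descendant_brain_g Descendant brain mass in grams (default 380).
#' @param descendant_body_kg Descendant body masses in kg (default 16, 24, 32).
#' @param line An [allometry_line()].
#' @param envelope Optional [decrease_envelope()].
#' @return Tibble of [evaluate_scenario()] rows.
#' @export
scenario_grid <- function(ancestors, descendant_brain_g = 380,
                          descendant_body_kg = c(16, 24, 32),
                          line, envelope = NULL) {
  stopifnot(nrow(ancestors) > 0, length(descendant_body_kg) > 0)
  grid <- tidyr::crossing(
    dplyr::select(ancestors, dplyr::any_of(c("ancestor", "brain_g", "body_g", "descendant_body_kg"))),
    body_kg = descendant_body_kg
  )
  if ("descendant_body_kg" %in% names(ancestors)) {
    grid <- dplyr::filter(grid, .data$descendant_body_kg == .data$body_kg)
  }
  purrr::pmap_dfr(grid, function(ancestor, brain_g, body_g, body_kg, ...) {
    evaluate_scenario(ancestor, brain_g, body_g,
                      descendant_brain_g, body_kg * 1000, line, envelope)
  })
}

#' Brain-mass decrease expected from a body-mass decrease
#'
#' Applies observed brain/body scaling ratios to a candidate body-mass
#' decrease: `predicted delta_log_brain = ratio * delta_log_body` per ratio,
#' with a min/mean/max summary.
#'
#' @param delta_log_body Change in log10 body mass (must be negative).
#' @param ratios Numeric vector of per-branch brain/body ratios.
#' @return List with `predictions` tibble and `summary` (min/mean/max).
#' @export
expected_brain_decrease <- function(delta_log_body, ratios) {
  if (delta_log_body >= 0) abort("expected a body-mass decrease (delta_log_body < 0)")
  pred <- ratios * delta_log_body
  list(
    predictions = tibble(ratio = ratios, predicted_delta_log_brain = pred),
    summary = c(min = min(pred), mean = mean(pred), max = max(pred))
  )
}
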