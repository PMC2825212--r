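#' Plot ancestral estimates against node age
#'
#' Node estimates (with SE bars or credible ribbons when available) versus
#' node age: the classic "deeper nodes are more uncertain" picture.
#'
#' @param estimates A node-estimate tibble from [asr_parsimony()], [asr_ml()]
#'   or [asr_mcmc()] (or several row-bound together; colour maps `method`).
#' @return A ggplot object.
#' @export
plot_asr <- function(estimates) {
  p <- ggplot2::ggplot(estimates, ggplot2::aes(x = .data$age, y = .data$estimate,
                                               colour = .data$method)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "node age (Ma)", y = "estimated state",
                  title = "Ancestral state estimates") +
    ggplot2::theme_minimal()
  if ("se" %in% names(estimates)) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$estimate - .data$se, ymax = .data$estimate + .data$se),
      width = 0, na.rm = TRUE
    )
  }
  if ("ci95_low" %in% names(estimates)) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci95_low, ymax = .data$ci95_high),
      width = 0, na.rm = TRUE
    )
  }
  p
}

#' Trace and marginal-likelihood plot for an MCMC run
#'
#' @param object An `mcmc_run`.
#' @param ... Unused.
#' @return A ggplot object (log-likelihood trace).
#' @export
autoplot.mcmc_run <- function(object, ...) {
  ggplot2::ggplot(object$trace, ggplot2::aes(x = .data$iteration, y = .data$loglik)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "iteration (post burn-in)", y = "log-likelihood",
                  title = sprintf("MCMC trace: %s (%s model)", object$trait,
                                  if (object$directional) "directional" else "constant")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Histogram of per-branch changes with the upper-quartile threshold
#'
#' @param changes A [branch_changes()] tibble.
#' @param value Column to plot.
#' @return A ggplot object.
#' @export
plot_branch_changes <- function(changes, value = "delta_log") {
  qs <- quartile_summary(changes, value)
  ggplot2::ggplot(changes, ggplot2::aes(x = .data[[value]])) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = qs$upper_quartile_threshold, linetype = 2) +
    ggplot2::geom_vline(xintercept = 0, colour = "red", linewidth = 0.3) +
    ggplot2::labs(x = "change along branch (log10)", y = "branches",
                  title = "Per-branch evolutionary change") +
    ggplot2::theme_minimal()
}

#' Scenario grid against the decrease envelope
#'
#' Brain/body change ratios for each ancestor and descendant body mass, with
#' the envelope of observed decreases shaded.
#'
#' @param grid A [scenario_grid()] tibble.
#' @param envelope Optional [decrease_envelope()] to shade.
#' @return A ggplot object.
#' @export
plot_scenarios <- function(grid, envelope = NULL) {
  p <- ggplot2::ggplot(grid, ggplot2::aes(x = .data$descendant_body_kg, y = .data$ratio,
                                          colour = .data$ancestor)) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::labs(x = "descendant body mass (kg)", y = "brain/body log-change ratio",
                  title = "Dwarfism scenarios vs observed decrease envelope") +
    ggplot2::theme_minimal()
  if (!is.null(envelope)) {
    p <- p + ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                               ymin = envelope$ratio_min, ymax = envelope$ratio_max,
                               alpha = 0.15, fill = "steelblue")
  }
  p
}
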