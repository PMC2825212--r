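#' Per-branch evolutionary change statistics
#'
#' For every branch (parent -> child) of the tree, computes the change in a
#' log10 trait between consecutive nodes: `delta_log` (a proportional change
#' in mass), `prop_change = 10^delta_log - 1` (the "% increase" reading),
#' `delta_abs` (change in raw mass units, when the trait is a log10 mass),
#' and rates per Myr. `decrease` flags `delta_log < 0`; zero-length branches
#' get `NA` rates and a `zero_length` flag.
#'
#' @param node_values Tibble with `node` and `value` covering *every* node
#'   (observed tips and estimated internals), values on the log10 scale.
#' @param tree A `phylo` object.
#' @param raw Is the trait a log10 mass, so that `10^value` is meaningful?
#'   Set `FALSE` for residual (relative brain size) traits.
#' @return Tibble, one row per branch: `parent`, `child`, `child_label`,
#'   `length_myr`, `delta_log`, `prop_change`, `delta_abs`, `rate_log`,
#'   `rate_abs`, `decrease`, `zero_length`.
#' @export
branch_changes <- function(node_values, tree, raw = TRUE) {
  n_all <- ape::Ntip(tree) + tree$Nnode
  v <- rep(NA_real_, n_all)
  v[node_values$node] <- node_values$value
  need <- unique(as.integer(tree$edge))
  if (anyNA(v[need])) {
    abort(sprintf("missing values for nodes: %s", paste(need[is.na(v[need])], collapse = ", ")))
  }
  parent <- tree$edge[, 1]; child <- tree$edge[, 2]
  len <- tree$edge.length
  delta_log <- v[child] - v[parent]
  zero <- len <= 1e-12
  out <- tibble(
    parent = parent, child = child,
    child_label = ifelse(child <= ape::Ntip(tree), tree$tip.label[child], as.character(child)),
    length_myr = len,
    delta_log = delta_log,
    prop_change = 10^delta_log - 1,
    delta_abs = if (raw) 10^v[child] - 10^v[parent] else NA_real_,
    rate_log = ifelse(zero, NA_real_, delta_log / len),
    rate_abs = if (raw) ifelse(zero, NA_real_, (10^v[child] - 10^v[parent]) / len) else NA_real_,
    decrease = delta_log < 0,
    zero_length = zero
  )
  out
}

#' Mean and upper-quartile summary of branch changes
#'
#' The upper-quartile threshold uses linear interpolation between closest
#' ranks (R's default quantile type 7); branches strictly above it are listed
#' in decreasing order.
#'
#' @param changes A [branch_changes()] tibble (>= 4 branches).
#' @param value Column to summarise (default `delta_log`).
#' @return List with `mean`, `upper_quartile_threshold`, and `upper_branches`
#'   (tibble in rank order).
#' @export
quartile_summary <- function(changes, value = "delta_log") {
  x <- changes[[value]]
  if (length(x) < 4) abort("need at least 4 branches for a quartile summary")
  thr <- unname(quantile(x, 0.75))
  upper <- dplyr::arrange(changes[x > thr, ], dplyr::desc(.data[[value]]))
  list(mean = mean(x), upper_quartile_threshold = thr, upper_branches = upper)
}

#' Ratio of log brain change to log body change along a branch
#'
#' `(log brain_child - log brain_parent) / (log body_child - log body_parent)`;
#' unit-invariant because log differences cancel unit constants.
#'
#' @param delta_log_brain,delta_log_body Log10 changes; vectorised.
#' @return The ratio.
#' @export
decrease_ratio <- function(delta_log_brain, delta_log_body) {
  if (any(delta_log_body == 0)) abort("ratio undefined: zero body-mass change")
  delta_log_brain / delta_log_body
}

#' Census of branches on which brain mass decreases
#'
#' Counts decreasing branches per trait, the fraction of branches and of
#' total evolutionary time they represent, and (for brain-decrease branches)
#' the brain/body change ratio used to build a decrease envelope. Zero-length
#' branches are excluded from rate statistics upstream but included in the
#' branch counts; both all-branch and positive-length denominators are
#' reported.
#'
#' @param brain_changes,body_changes [branch_changes()] tibbles on aligned
#'   branch sets.
#' @param rel_changes Optional changes tibble for relative brain size.
#' @return A list of class `decrease_census`: `summary` (per-trait tibble),
#'   `ratios` (per brain-decrease branch), `ratio_mean`, `ratio_range`.
#' @export
decrease_census <- function(brain_changes, body_changes, rel_changes = NULL) {
  if (!identical(brain_changes$child, body_changes$child)) {
    abort("brain and body change tables must cover the same branches in the same order")
  }
  total_time <- sum(brain_changes$length_myr)
  one <- function(ch, trait) {
    dec <- ch$decrease
    tibble(
      trait = trait,
      n_decreasing = sum(dec),
      n_branches = nrow(ch),
      n_branches_positive_length = sum(!ch$zero_length),
      fraction_branches = mean(dec),
      fraction_time = sum(ch$length_myr[dec]) / total_time
    )
  }
  summary <- dplyr::bind_rows(
    one(brain_changes, "brain"),
    one(body_changes, "body"),
    if (!is.null(rel_changes)) one(rel_changes, "relative_brain")
  )
  dec <- brain_changes$decrease
  ratios <- tibble(
    parent = brain_changes$parent[dec],
    child = brain_changes$child[dec],
    child_label = brain_changes$child_label[dec],
    delta_log_brain = brain_changes$delta_log[dec],
    delta_log_body = body_changes$delta_log[dec]
  )
  ratios$ratio <- ifelse(ratios$delta_log_body == 0, NA_real_,
                         ratios$delta_log_brain / ratios$delta_log_body)
  structure(
    list(
      summary = summary, ratios = ratios,
      ratio_mean = mean(ratios$ratio, na.rm = TRUE),
      ratio_range = if (nrow(ratios)) range(ratios$ratio, na.rm = TRUE) else c(NA_real_, NA_real_)
    ),
    class = "decrease_census"
  )
}

#' @export
print.decrease_census <- function(x, ...) {
  print(x$summary)
  if (nrow(x$ratios)) {
    cat(sprintf("brain/body decrease ratio: mean %.3f, range %.3f to %.3f (%d branches)\n",
                x$ratio_mean, x$ratio_range[1], x$ratio_range[2], nrow(x$ratios)))
  } else cat("no decreasing brain-mass branches\n")
  invisible(x)
}
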