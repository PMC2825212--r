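#' Simulation configuration for primate-like brain/body datasets
#'
#' Defaults emulate the structure of a genus-level primate dataset: a deep
#' (77.5 Myr) ultrametric pure-birth tree of 37 extant taxa with 23 fossil
#' tips grafted at interior nodes; log10 body mass evolving by Brownian
#' motion from a ~49 g root with a rate giving a 10 g-100 kg extant spread;
#' brain mass generated from body mass through the allometric line
#' (slope 0.684, intercept 2.18 on the mg-brain scale) plus a Brownian
#' residual, optionally drifting (a directional trend in encephalization
#' but not body size).
#'
#' @param n_extant Number of extant tips (>= 2).
#' @param n_fossils Number of fossil tips grafted at interior nodes.
#' @param height Tree height in Myr.
#' @param birth Pure-birth speciation rate (shape only; the tree is rescaled
#'   to `height`).
#' @param alpha_body BM rate of log10 body mass (per Myr).
#' @param alpha_resid BM rate of the brain residual (per Myr).
#' @param beta_brain Directional trend of the residual per Myr (0 = none).
#' @param slope,intercept,brain_unit Allometric line (see [allometry_line()]).
#' @param root_log_body log10 body mass (grams) at the root.
#' @param seed Integer seed; recorded in every output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_extant = 37, n_fossils = 23, height = 77.5, birth = 0.1,
                       alpha_body = 0.013, alpha_resid = 0.001, beta_brain = 0,
                       slope = 0.684, intercept = 2.18, brain_unit = "mg",
                       root_log_body = 1.69, seed = 1L) {
  stopifnot(n_extant >= 2, n_fossils >= 0, height > 0, birth > 0,
            alpha_body > 0, alpha_resid > 0)
  structure(
    list(n_extant = as.integer(n_extant), n_fossils = as.integer(n_fossils),
         height = height, birth = birth, alpha_body = alpha_body,
         alpha_resid = alpha_resid, beta_brain = beta_brain,
         line = allometry_line(intercept, slope, brain_unit = brain_unit),
         root_log_body = root_log_body, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate a time-calibrated tree with optional fossil tips
#'
#' A seeded pure-birth (Yule) tree of `n_extant` tips, rescaled to the
#' requested height (ultrametric; all extant path lengths equal `height`).
#' Fossils are then grafted with [graft_fossil()] at uniformly sampled
#' interior nodes, with last occurrence uniform on (0, node age).
#'
#' @param config A [sim_config()].
#' @return A `phylo` object; fossil tips are labelled `fossil_i`.
#' @export
simulate_tree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    tree <- ape::rphylo(config$n_extant, birth = config$birth, death = 0)
    tree$tip.label <- sprintf("t%d", seq_len(config$n_extant))
    tree$edge.length <- tree$edge.length * (config$height / tree_height(tree))
    # snap terminal edges so every extant tip depth is exactly `height`
    d <- node_depths(tree)
    tip_edges <- match(seq_len(ape::Ntip(tree)), tree$edge[, 2])
    tree$edge.length[tip_edges] <- tree$edge.length[tip_edges] +
      (config$height - d[seq_len(ape::Ntip(tree))])
    attr(tree, "root_age") <- config$height
    if (config$n_fossils > 0) {
      for (i in seq_len(config$n_fossils)) {
        ages <- node_ages(tree)
        internal <- ages[ages$node > ape::Ntip(tree) & ages$age > 1e-6, ]
        row <- internal[sample.int(nrow(internal), 1), ]
        last_occ <- runif(1, 0, row$age)
        tree <- graft_fossil(tree, row$node, sprintf("fossil_%d", i), last_occ)
      }
    }
    tree
  })
}

# BM (with drift) simulated edge-by-edge in preorder; returns states for all
# nodes, root included
sim_bm_states <- function(tree, alpha, root_state, beta = 0) {
  n_tip <- ape::Ntip(tree)
  n_all <- n_tip + tree$Nnode
  s <- rep(NA_real_, n_all)
  s[n_tip + 1L] <- root_state
  ord <- ape::reorder.phylo(tree, "postorder")
  edges <- ord$edge[rev(seq_len(nrow(ord$edge))), , drop = FALSE] # preorder
  lens <- ord$edge.length[rev(seq_len(nrow(ord$edge)))]
  for (k in seq_len(nrow(edges))) {
    p <- edges[k, 1]; ch <- edges[k, 2]; l <- lens[k]
    s[ch] <- s[p] + beta * l + rnorm(1, 0, sqrt(alpha * l))
  }
  s
}

#' Simulate a single Brownian (optionally directional) trait on a tree
#'
#' @param tree A `phylo` object.
#' @param alpha BM rate (trait^2 per Myr).
#' @param root_state Trait value at the root.
#' @param beta Drift per Myr.
#' @param seed Integer seed.
#' @return List: `tips` (tibble `taxon`, `value`) and `nodes` (tibble over
#'   all nodes, the simulation truth).
#' @export
simulate_bm <- function(tree, alpha = 1, root_state = 0, beta = 0, seed = 1L) {
  s <- withr::with_seed(seed, sim_bm_states(tree, alpha, root_state, beta))
  n_tip <- ape::Ntip(tree)
  list(
    tips = tibble(taxon = tree$tip.label, value = s[seq_len(n_tip)]),
    nodes = tibble(node = seq_along(s), value = s)
  )
}

#' Simulate allometrically coupled brain and body masses on a tree
#'
#' log10 body mass evolves by Brownian motion from `root_log_body`; the brain
#' residual evolves by (optionally drifting) Brownian motion from 0; brain is
#' `line(body) + residual` at every node. Tip values in the returned truth
#' equal the emitted trait table exactly.
#'
#' @param tree A `phylo` object (e.g. from [simulate_tree()]).
#' @param config A [sim_config()].
#' @return List of class `sim_traits`: `traits` (trait tibble ready for the
#'   loaders: `taxon`, `brain_g`, `body_g`, `extant`, log10 columns) and
#'   `truth` (`node_states` tibble with log10 body/brain and residual at every
#'   node, plus `params`).
#' @export
simulate_traits <- function(tree, config) {
  stopifnot(inherits(config, "sim_config"))
  states <- withr::with_seed(config$seed + 1L, {
    body <- sim_bm_states(tree, config$alpha_body, config$root_log_body, beta = 0)
    resid <- sim_bm_states(tree, config$alpha_resid, 0, beta = config$beta_brain)
    list(body = body, resid = resid)
  })
  line <- config$line
  brain <- line$intercept + line$slope * states$body + states$resid
  n_tip <- ape::Ntip(tree)
  ages <- node_ages(tree)
  extant <- ages$age[seq_len(n_tip)] < 1e-6
  traits <- tibble(
    taxon = tree$tip.label,
    brain_g = 10^brain[seq_len(n_tip)],
    body_g = 10^states$body[seq_len(n_tip)],
    extant = extant
  )
  traits <- prepare_traits(traits)
  structure(
    list(
      traits = traits,
      truth = list(
        node_states = tibble(
          node = seq_along(brain),
          log10_body = states$body,
          log10_brain = brain,
          residual = states$resid
        ),
        params = config
      )
    ),
    class = "sim_traits"
  )
}

#' Deterministic primate-like fixture dataset
#'
#' A fixed-seed dataset with 37 extant and 23 fossil tips whose mass spans
#' resemble the primate radiation (brain roughly 2 g-1.3 kg, body roughly
#' 10 g-100 kg across extant taxa). Identical on every call and platform.
#'
#' @param beta_brain Optional residual drift per Myr (default 0).
#' @return List with `tree`, `traits`, `truth`, and `config`.
#' @export
primate_fixture <- function(beta_brain = 0) {
  cfg <- sim_config(beta_brain = beta_brain, seed = 4217L)
  tree <- simulate_tree(cfg)
  sim <- simulate_traits(tree, cfg)
  list(tree = tree, traits = sim$traits, truth = sim$truth, config = cfg)
}
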