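#' Read a time-calibrated phylogeny from a Newick string or file
#'
#' Trees are plain `ape::phylo` objects throughout the package. Branch lengths
#' are interpreted as millions of years (Myr); node ages (Ma before present)
#' are derived from root-to-node path lengths, with the deepest tip taken as
#' extant (age 0) unless `age_calibration` pins the root age explicitly.
#'
#' @param source Newick text (a string containing `";"`) or a file path.
#' @param age_calibration Optional root age in Ma. Defaults to tree height, so
#'   the deepest tips sit at the present.
#' @return A `phylo` object with a `root_age` attribute.
#' @export
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' node_ages(tr)
read_newick <- function(source, age_calibration = NULL) {
  txt <- grepl(";", source, fixed = TRUE)
  tree <- if (txt) ape::read.tree(text = source) else ape::read.tree(source)
  if (is.null(tree)) abort("malformed Newick: ape could not parse the input")
  if (is.null(tree$edge.length)) {
    abort("Newick input has no branch lengths; time-calibrated branches are required")
  }
  if (any(tree$edge.length < 0)) {
    bad <- which(tree$edge.length < 0)[1]
    abort(sprintf("negative branch length on edge %d (%.6g Myr)", bad, tree$edge.length[bad]))
  }
  validate_tree(tree)
  attr(tree, "root_age") <- age_calibration %||% tree_height(tree)
  tree
}

#' Write a phylogeny to Newick
#'
#' @param tree A `phylo` object.
#' @param file Optional path; if `NULL` the Newick string is returned.
#' @export
write_newick <- function(tree, file = NULL) {
  if (is.null(file)) ape::write.tree(tree) else ape::write.tree(tree, file = file)
}

validate_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  # structural check (ape::is.rooted treats a basal polytomy as unrooted,
  # but a fossil grafted at the root legitimately creates one)
  roots <- setdiff(tree$edge[, 1], tree$edge[, 2])
  if (length(unique(roots)) != 1) abort("tree must have exactly one root")
  if (is.null(tree$edge.length)) abort("tree must have branch lengths")
  invisible(tree)
}

root_node <- function(tree) ape::Ntip(tree) + 1L

#' Root-to-node path lengths ("depths") for every node
#'
#' @param tree A `phylo` object.
#' @return Numeric vector over all nodes (tips first, ape numbering).
#' @export
node_depths <- function(tree) ape::node.depth.edgelength(tree)

tree_height <- function(tree) max(node_depths(tree)[seq_len(ape::Ntip(tree))])

# no usable root-to-tip variation (relative tolerance absorbs float error
# accumulated by pruning/rescaling)
paths_ultrametric <- function(p) diff(range(p)) <= 1e-7 * max(p)

#' Node ages in Ma before present
#'
#' Age = root age minus root-to-node path length. Extant tips have age 0;
#' fossil tips retain positive ages and make the tree non-ultrametric.
#'
#' @param tree A `phylo` object (optionally carrying a `root_age` attribute).
#' @param root_age Root age in Ma; defaults to the tree's `root_age` attribute
#'   or, failing that, the tree height.
#' @return A tibble with `node`, `label` (tips only), `depth`, and `age`.
#' @export
node_ages <- function(tree, root_age = NULL) {
  depth <- node_depths(tree)
  root_age <- root_age %||% attr(tree, "root_age") %||% tree_height(tree)
  n_tip <- ape::Ntip(tree)
  lab <- c(tree$tip.label, rep(NA_character_, tree$Nnode))
  tibble(
    node = seq_along(depth),
    label = lab,
    depth = depth,
    age = root_age - depth
  )
}

#' Phylogenetic variance-covariance matrix
#'
#' Converts the phylogeny into the covariance matrix of a Brownian process:
#' entry (i, j) is the shared root-to-MRCA path length of tips i and j, and
#' the diagonal holds root-to-tip path lengths. Assembly is delegated to
#' [ape::vcv.phylo()].
#'
#' @param tree A `phylo` object.
#' @param taxa Optional character vector restricting (and ordering) the tips.
#' @return A symmetric positive semi-definite matrix in Myr.
#' @export
phylo_vcv <- function(tree, taxa = NULL) {
  C <- ape::vcv.phylo(tree)
  if (!is.null(taxa)) {
    missing <- setdiff(taxa, rownames(C))
    if (length(missing)) {
      abort(sprintf("unknown taxa: %s", paste(missing, collapse = ", ")))
    }
    C <- C[taxa, taxa, drop = FALSE]
  }
  C
}

#' Root-to-tip path lengths
#'
#' Equals the diagonal of [phylo_vcv()]. On an ultrametric tree all values
#' equal the tree height; fossil tips are shorter. Root-to-tip variation is
#' what makes a directional (drift) model identifiable.
#'
#' @param tree A `phylo` object.
#' @param taxa Optional tip subset/ordering.
#' @return Named numeric vector of path lengths (Myr).
#' @export
path_lengths <- function(tree, taxa = NULL) {
  d <- node_depths(tree)[seq_len(ape::Ntip(tree))]
  names(d) <- tree$tip.label
  if (!is.null(taxa)) {
    missing <- setdiff(taxa, names(d))
    if (length(missing)) abort(sprintf("unknown taxa: %s", paste(missing, collapse = ", ")))
    d <- d[taxa]
  }
  d
}

#' Randomly resolve polytomies with zero-length branches
#'
#' Multifurcations are resolved into bifurcations by a seeded random choice of
#' pairing order; every inserted branch has length zero, so all pairwise
#' covariances (and hence every downstream estimate) are unchanged.
#'
#' @param tree A `phylo` object.
#' @param seed Integer seed controlling the resolution order.
#' @return A fully bifurcating `phylo` object.
#' @export
resolve_polytomies <- function(tree, seed = 1L) {
  validate_tree(tree)
  if (ape::is.binary(tree)) return(tree)
  root_age <- attr(tree, "root_age")
  out <- withr::with_seed(seed, ape::multi2di(tree, random = TRUE))
  out$edge.length[is.na(out$edge.length)] <- 0
  attr(out, "root_age") <- root_age
  out
}

#' Graft a fossil tip onto an interior node
#'
#' Attaches an extinct taxon as a new child of `at_node` (creating a polytomy
#' there), with branch length equal to the node's age minus the fossil's last
#' occurrence, so the tip sits at its last-occurrence age.
#'
#' @param tree A `phylo` object.
#' @param at_node Internal node id (ape numbering) to attach to.
#' @param label Taxon label for the new tip.
#' @param last_occurrence_ma Last occurrence of the fossil, Ma before present.
#' @return The augmented `phylo` object. Zero-length tip branches (fossil last
#'   seen exactly at the node age) are permitted but trigger a warning.
#' @export
graft_fossil <- function(tree, at_node, label, last_occurrence_ma) {
  validate_tree(tree)
  ages <- node_ages(tree)
  if (at_node <= ape::Ntip(tree) || at_node > ape::Ntip(tree) + tree$Nnode) {
    abort(sprintf("at_node %d is not an internal node", at_node))
  }
  node_age <- ages$age[ages$node == at_node]
  len <- node_age - last_occurrence_ma
  if (len < -1e-9) {
    abort(sprintf(
      "fossil '%s' last occurs at %.4g Ma but attachment node is younger (%.4g Ma): negative branch",
      label, last_occurrence_ma, node_age
    ))
  }
  len <- max(len, 0)
  if (len == 0) {
    warn(sprintf("fossil '%s' grafted with a zero-length branch (last seen at node age)", label))
  }
  root_age <- attr(tree, "root_age")
  out <- phytools::bind.tip(tree, label, edge.length = len, where = at_node, position = 0)
  attr(out, "root_age") <- root_age
  out
}

#' Graft several fossils from a placement table
#'
#' @param tree A `phylo` object.
#' @param placements Data frame with columns `taxon`, `attach_node` (internal
#'   node id in the *current* tree as fossils are added; clade labels are not
#'   tracked across grafts, so placements are applied in row order against the
#'   MRCA of the extant clade each node subtends), and `last_occurrence_ma`.
#'   `attach_node` may alternatively be a list-column of extant tip labels
#'   whose MRCA is used, which is stable under repeated grafting.
#' @return The augmented tree.
#' @export
graft_fossils <- function(tree, placements) {
  stopifnot(all(c("taxon", "attach_node", "last_occurrence_ma") %in% names(placements)))
  for (i in seq_len(nrow(placements))) {
    at <- placements$attach_node[[i]]
    node <- if (is.character(at) && length(at) > 1) ape::getMRCA(tree, at) else as.integer(at)
    tree <- graft_fossil(tree, node, placements$taxon[[i]], placements$last_occurrence_ma[[i]])
  }
  tree
}

#' Drop extinct tips from a tree/trait pair
#'
#' @param tree A `phylo` object.
#' @param traits Trait tibble with `taxon` and logical `extant` columns.
#' @return List with the pruned `tree` and filtered `traits`.
#' @export
drop_fossils <- function(tree, traits) {
  extinct <- traits$taxon[!traits$extant]
  out <- if (length(extinct)) ape::drop.tip(tree, intersect(extinct, tree$tip.label)) else tree
  attr(out, "root_age") <- attr(tree, "root_age")
  list(tree = out, traits = dplyr::filter(traits, .data$extant))
}

#' Match internal nodes between a fossil-bearing tree and its extant-only tree
#'
#' Fossil grafting preserves every extant clade, so a node in the full tree is
#' identified with the MRCA of its extant descendants in the pruned tree.
#' Nodes subtending fewer than two extant tips have no counterpart.
#'
#' @param full_tree Tree with fossils.
#' @param extant_tree Tree pruned to extant tips.
#' @return Tibble with `node_full`, `node_extant`.
#' @export
match_nodes_by_extant_clade <- function(full_tree, extant_tree) {
  n_tip <- ape::Ntip(full_tree)
  internal <- n_tip + seq_len(full_tree$Nnode)
  rows <- purrr::map(internal, function(nd) {
    desc <- tips_below(full_tree, nd)
    desc <- intersect(desc, extant_tree$tip.label)
    if (length(desc) < 2) return(NULL)
    tibble(node_full = nd, node_extant = ape::getMRCA(extant_tree, desc))
  })
  out <- dplyr::bind_rows(rows)
  # several full-tree nodes can collapse onto one extant node once fossil-only
  # splits are removed; keep the oldest (first in ape preorder is not
  # guaranteed, so pick the one with the most extant descendants)
  dplyr::distinct(out, .data$node_extant, .keep_all = TRUE)
}

tips_below <- function(tree, node) {
  n_tip <- ape::Ntip(tree)
  if (node <= n_tip) return(tree$tip.label[node])
  tree$tip.label[unlist(phangorn_descendants(tree, node))]
}

# minimal descendant-tip walker (avoids a phangorn dependency)
phangorn_descendants <- function(tree, node) {
  n_tip <- ape::Ntip(tree)
  kids <- tree$edge[, 2][tree$edge[, 1] == node]
  out <- integer(0)
  stack <- kids
  while (length(stack)) {
    nd <- stack[[1]]; stack <- stack[-1]
    if (nd <= n_tip) out <- c(out, nd) else stack <- c(stack, tree$edge[, 2][tree$edge[, 1] == nd])
  }
  list(out)
}

#' Read a trait table (TSV)
#'
#' Expected columns: `taxon`, `body_g`, `extant`, and either `brain_g` or
#' `cranial_capacity_cc` (converted to brain mass via
#' [brain_mass_from_cranial_capacity()], with a message). Adds `log10_brain`
#' and `log10_body` columns (grams).
#'
#' @param path TSV file path.
#' @return A tibble, one row per taxon.
#' @export
read_traits <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE)
  prepare_traits(raw)
}

#' Prepare a raw trait data frame
#'
#' @param raw Data frame with `taxon`, `body_g`, `extant`, and `brain_g`
#'   and/or `cranial_capacity_cc`.
#' @return Tibble with validated masses and log10 columns.
#' @export
prepare_traits <- function(raw) {
  stopifnot(all(c("taxon", "body_g", "extant") %in% names(raw)))
  out <- as_tibble(raw)
  if (!"brain_g" %in% names(out)) {
    if (!"cranial_capacity_cc" %in% names(out)) {
      abort("trait table needs a brain_g or cranial_capacity_cc column")
    }
    message("converting cranial_capacity_cc to brain_g")
    out$brain_g <- brain_mass_from_cranial_capacity(out$cranial_capacity_cc)
  } else if ("cranial_capacity_cc" %in% names(out)) {
    miss <- is.na(out$brain_g)
    out$brain_g[miss] <- brain_mass_from_cranial_capacity(out$cranial_capacity_cc[miss])
  }
  if (anyDuplicated(out$taxon)) abort("duplicate taxa in trait table")
  if (any(!is.finite(out$brain_g)) || any(!is.finite(out$body_g))) {
    abort("non-finite masses in trait table")
  }
  if (any(out$brain_g <= 0) || any(out$body_g <= 0)) abort("masses must be positive")
  out$extant <- as.logical(out$extant)
  out$log10_brain <- log10(out$brain_g)
  out$log10_body <- log10(out$body_g)
  out
}

check_tree_traits <- function(tree, traits) {
  missing <- setdiff(traits$taxon, tree$tip.label)
  if (length(missing)) {
    abort(sprintf("taxa absent from tree: %s", paste(missing, collapse = ", ")))
  }
  invisible(TRUE)
}
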