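#' Build an ordinal constraint tree
#'
#' Replaces each tip of the ordinal backbone by a polytomy of that order's
#' included species (within-order relationships are deliberately left
#' unresolved so the sequence data can resolve them), prunes orders with no
#' included species, and leaves single-species orders as pendant tips.
#'
#' @param backbone Rooted `phylo` whose tips are order names.
#' @param taxonomy A `community_taxonomy`.
#' @param included_species Character vector of species codes to place.
#' @return A rooted `phylo` over `included_species` with class attribute
#'   `constraint_tree`; internal backbone nodes are labelled with nothing,
#'   order polytomies with the order name.
#' @export
build_constraint <- function(backbone, taxonomy, included_species) {
  validate_backbone(backbone)
  missing_sp <- setdiff(included_species, taxonomy$species)
  if (length(missing_sp)) {
    stop("species not in taxonomy: ", paste(missing_sp, collapse = ", "),
         call. = FALSE)
  }
  tax <- taxonomy[taxonomy$species %in% included_species, , drop = FALSE]
  bad <- setdiff(unique(tax$order), backbone$tip.label)
  if (length(bad)) {
    offenders <- tax$species[tax$order %in% bad]
    stop("order(s) absent from backbone: ", paste(bad, collapse = ", "),
         " (species: ", paste(offenders, collapse = ", "), ")", call. = FALSE)
  }
  if (length(included_species) < 2L) {
    stop("need at least two included species", call. = FALSE)
  }
  members <- split(sort(tax$species), tax$order)

  present <- intersect(backbone$tip.label, names(members))
  if (length(present) == 1L) {
    sp <- members[[present]]
    txt <- paste0("(", paste(sp, collapse = ","), ")", present, ";")
    tree <- ape::read.tree(text = txt)
  } else {
    pruned <- ape::keep.tip(backbone, present)
    txt <- backbone_newick(pruned, members)
    tree <- ape::read.tree(text = txt)
  }
  class(tree) <- c("constraint_tree", "phylo")
  tree
}

# recursive Newick over a backbone, substituting species polytomies for tips
backbone_newick <- function(tree, members) {
  ntip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  rec <- function(v) {
    if (v <= ntip) {
      ord <- tree$tip.label[v]
      sp <- members[[ord]]
      if (length(sp) == 1L) sp
      else paste0("(", paste(sp, collapse = ","), ")", ord)
    } else {
      paste0("(", paste(vapply(kids[[as.character(v)]], rec, character(1)),
                        collapse = ","), ")")
    }
  }
  paste0(rec(ntip + 1L), ";")
}

# parent vector (1-based, 0 = root) from a phylo, in ape node numbering
phylo_parent <- function(tree) {
  M <- length(tree$tip.label) + tree$Nnode
  parent <- integer(M)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  parent
}

# list of tip-index vectors, one per internal node (including root)
phylo_clades <- function(tree) {
  pp <- ape::prop.part(tree)
  lapply(pp, as.integer)
}

# non-trivial clades of `tree` as tip-index sets in `ref_labels` numbering
clades_in_ref <- function(tree, ref_labels) {
  idx <- match(tree$tip.label, ref_labels)
  lapply(phylo_clades(tree), function(cl) sort(idx[cl]))
}

#' Does a candidate tree refine a constraint?
#'
#' `TRUE` iff every non-trivial clade of the constraint is a clade of the
#' candidate, i.e. the candidate can be obtained by resolving the
#' constraint's polytomies. Both trees are treated as rooted.
#'
#' @param candidate A rooted `phylo`.
#' @param constraint A rooted `phylo` (typically from [build_constraint()]).
#' @return Logical.
#' @export
is_compatible <- function(candidate, constraint) {
  extra <- setdiff(candidate$tip.label, constraint$tip.label)
  miss <- setdiff(constraint$tip.label, candidate$tip.label)
  if (length(extra) || length(miss)) {
    stop("tip sets differ; only in candidate: {",
         paste(extra, collapse = ", "), "}; only in constraint: {",
         paste(miss, collapse = ", "), "}", call. = FALSE)
  }
  clades <- clades_in_ref(constraint, candidate$tip.label)
  is_refinement_cpp(phylo_parent(candidate), length(candidate$tip.label),
                    clades)
}

#' Contract a species tree to one tip per order
#'
#' Monophyletic orders are collapsed to a single tip carrying the order name.
#' A non-monophyletic order is represented by its MRCA-exemplar: the tip with
#' the fewest edges to the order's most recent common ancestor (ties broken
#' alphabetically), and the order is flagged as inherently misplaced.
#'
#' @param tree Rooted `phylo` over species.
#' @param taxonomy A `community_taxonomy` covering all tips.
#' @return List with `tree` (ordinal `phylo`) and `inherently_misplaced`
#'   (character vector of non-monophyletic orders).
#' @export
contract_to_orders <- function(tree, taxonomy) {
  missing <- setdiff(tree$tip.label, taxonomy$species)
  if (length(missing)) {
    stop("tips not in taxonomy: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ord_of <- stats::setNames(taxonomy$order, taxonomy$species)
  orders <- split(tree$tip.label, ord_of[tree$tip.label])
  if (length(orders) < 2L) stop("need at least two orders", call. = FALSE)

  depth <- node_depths(tree)
  exemplar <- character(length(orders))
  flagged <- character(0)
  names(exemplar) <- names(orders)
  for (ord in names(orders)) {
    tips <- orders[[ord]]
    if (length(tips) == 1L) {
      exemplar[ord] <- tips
      next
    }
    mrca <- ape::getMRCA(tree, tips)
    clade_tips <- tips_below(tree, mrca)
    if (length(clade_tips) == length(tips)) {
      exemplar[ord] <- sort(tips)[1L]
    } else {
      flagged <- c(flagged, ord)
      hops <- depth[match(tips, tree$tip.label)] - depth[mrca]
      exemplar[ord] <- sort(tips[hops == min(hops)])[1L]
    }
  }
  reduced <- ape::keep.tip(tree, unname(exemplar))
  reduced$tip.label <- names(exemplar)[match(reduced$tip.label, exemplar)]
  reduced$node.label <- NULL
  list(tree = reduced, inherently_misplaced = sort(flagged))
}

# edge-count depth of every node from the root
node_depths <- function(tree) {
  M <- length(tree$tip.label) + tree$Nnode
  depth <- integer(M)
  # tree$edge rows are in preorder for trees read/written by ape only after
  # reordering; enforce it
  eo <- ape::reorder.phylo(tree, "cladewise")
  for (i in seq_len(nrow(eo$edge))) {
    depth[eo$edge[i, 2]] <- depth[eo$edge[i, 1]] + 1L
  }
  depth
}

tips_below <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  acc <- character(0)
  stack <- node
  while (length(stack)) {
    v <- stack[[1L]]
    stack <- stack[-1L]
    if (v <= ntip) acc <- c(acc, tree$tip.label[v])
    else stack <- c(stack, kids[[as.character(v)]])
  }
  acc
}
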