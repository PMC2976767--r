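#' Percentage of resolved nodes in a rooted tree
#'
#' Uses `100 * (I - 1) / (n - 2)` with `I` the internal node count
#' (including the root) and `n` the number of tips: 100 for a fully binary
#' tree, 0 for a star. This normalises the number of realised internal
#' splits against the maximum a rooted binary tree can have.
#'
#' @param tree Rooted `phylo` with at least 3 tips.
#' @return Percentage in `[0, 100]`.
#' @export
resolution_fraction <- function(tree) {
  n <- length(tree$tip.label)
  if (n < 3L) stop("resolution needs at least 3 tips", call. = FALSE)
  100 * (tree$Nnode - 1) / (n - 2)
}

#' Bin node supports into the six cumulative support categories
#'
#' Reports the percentage of scored internal nodes with support `<50`,
#' `>=50`, in `[50,70)`, `>=70`, in `[70,85)`, and `>=85` — the overlapping
#' cumulative layout conventional for ratchet support summaries (so
#' `<50 + >50 = 100` and `50-70 + >70 = >50`, within rounding).
#'
#' @param tree Rooted `phylo` whose internal nodes all carry numeric
#'   supports in `[0, 100]` (consense first).
#' @return A one-row `support_bins` tibble with columns `n_nodes`, `lt50`,
#'   `ge50`, `b50_70`, `ge70`, `b70_85`, `ge85` (percentages to 1 decimal).
#' @export
support_bins <- function(tree) {
  # the root subtends all tips and is not a scored node; every other
  # internal node must carry a numeric support
  if (tree$Nnode > 1L) {
    if (is.null(tree$node.label)) {
      stop("tree has internal nodes without support; build a consensus first",
           call. = FALSE)
    }
    scored <- suppressWarnings(as.numeric(tree$node.label[-1L]))
    if (any(is.na(scored))) {
      stop("tree has internal nodes without numeric support; ",
           "build a consensus first", call. = FALSE)
    }
  } else {
    scored <- numeric(0)  # star tree: only the root
  }
  nn <- length(scored)
  pct <- function(x) if (nn == 0L) 0 else round(100 * sum(x) / nn, 1)
  out <- tibble::tibble(
    n_nodes = nn,
    lt50 = pct(scored < 50),
    ge50 = pct(scored >= 50),
    b50_70 = pct(scored >= 50 & scored < 70),
    ge70 = pct(scored >= 70),
    b70_85 = pct(scored >= 70 & scored < 85),
    ge85 = pct(scored >= 85)
  )
  class(out) <- c("support_bins", class(out))
  out
}

#' Monophyly status of every taxon at a rank
#'
#' A taxon is monophyletic iff the smallest clade containing all its tips
#' contains no other tips; single-tip taxa are reported as singletons
#' (trivially monophyletic).
#'
#' @param tree Rooted `phylo` over species.
#' @param taxonomy A `community_taxonomy` covering every tip.
#' @param rank `"genus"`, `"family"`, or `"order"`.
#' @return A `monophyly_report` tibble: `rank`, `taxon`, `n_tips`, `status`.
#' @export
monophyly_report <- function(tree, taxonomy,
                             rank = c("genus", "family", "order")) {
  rank <- match.arg(rank)
  missing <- setdiff(tree$tip.label, taxonomy$species)
  if (length(missing)) {
    stop("tips not in taxonomy: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  grp <- stats::setNames(taxonomy[[rank]], taxonomy$species)
  groups <- split(tree$tip.label, grp[tree$tip.label])
  status <- vapply(groups, function(tips) {
    if (length(tips) == 1L) return("singleton")
    mrca <- ape::getMRCA(tree, tips)
    if (length(tips_below(tree, mrca)) == length(tips)) "monophyletic"
    else "non-monophyletic"
  }, character(1))
  out <- tibble::tibble(rank = rank, taxon = names(groups),
                        n_tips = vapply(groups, length, integer(1)),
                        status = unname(status))
  class(out) <- c("monophyly_report", class(out))
  out
}

#' Count orders misplaced relative to a reference backbone
#'
#' The species tree is contracted to one tip per order (see
#' [contract_to_orders()]); the function then finds a maximum-cardinality
#' subset of orders whose induced topologies agree between the contracted
#' tree and the backbone. The misplaced orders are the complement of that
#' subset, plus any order that was not monophyletic to begin with.
#' Exhaustive search is used up to `exhaustive_limit` orders; beyond that a
#' seeded greedy-removal/re-insertion heuristic is used.
#'
#' @param tree Rooted `phylo` over species.
#' @param backbone Rooted `phylo` over order names.
#' @param taxonomy A `community_taxonomy` covering every tip.
#' @param exhaustive_limit Largest order count solved exactly.
#' @param seed Seed for the heuristic used above the exhaustive limit.
#' @return List with `n_misplaced` and `misplaced` (order names).
#' @export
misplaced_orders <- function(tree, backbone, taxonomy,
                             exhaustive_limit = 12L, seed = 1L) {
  red <- contract_to_orders(tree, taxonomy)
  ords <- red$tree$tip.label
  bad <- setdiff(ords, backbone$tip.label)
  if (length(bad)) {
    stop("orders absent from backbone: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  bb <- if (length(setdiff(backbone$tip.label, ords))) {
    ape::keep.tip(backbone, ords)
  } else backbone
  forced_out <- red$inherently_misplaced
  candidates <- setdiff(ords, forced_out)

  agree <- function(sub) {
    if (length(sub) < 3L) return(TRUE)
    same_topology(ape::keep.tip(red$tree, sub), ape::keep.tip(bb, sub))
  }

  if (agree(candidates)) {
    keep <- candidates
  } else if (length(candidates) <= exhaustive_limit) {
    keep <- character(0)
    found <- FALSE
    for (k in seq(length(candidates) - 1L, 1L)) {
      combs <- utils::combn(candidates, k, simplify = FALSE)
      for (sub in combs) {
        if (agree(sub)) { keep <- sub; found <- TRUE; break }
      }
      if (found) break
    }
  } else {
    keep <- with_seed(seed, mast_heuristic(candidates, agree))
  }
  misplaced <- sort(c(forced_out, setdiff(candidates, keep)))
  list(n_misplaced = length(misplaced), misplaced = misplaced)
}

# greedy removal until agreement, then attempted re-insertions; repeated
# from random removal orders, best subset kept
mast_heuristic <- function(candidates, agree, restarts = 20L) {
  best <- character(0)
  for (r in seq_len(restarts)) {
    sub <- candidates
    ord <- sample(candidates)
    i <- 1L
    while (!agree(sub) && length(sub) > 2L) {
      # remove the next order whose removal helps most (first that yields
      # agreement, else rotate)
      removed <- FALSE
      for (cand in ord[ord %in% sub]) {
        if (agree(setdiff(sub, cand))) {
          sub <- setdiff(sub, cand); removed <- TRUE; break
        }
      }
      if (!removed) sub <- setdiff(sub, ord[ord %in% sub][1L])
    }
    for (cand in setdiff(candidates, sub)) {
      if (agree(c(sub, cand))) sub <- c(sub, cand)
    }
    if (length(sub) > length(best)) best <- sub
  }
  best
}

# rooted topological identity: same tip set and same clade sets
same_topology <- function(a, b) {
  if (!setequal(a$tip.label, b$tip.label)) return(FALSE)
  ca <- lapply(clades_in_ref(a, sort(a$tip.label)), paste0, collapse = ".")
  cb <- lapply(clades_in_ref(b, sort(a$tip.label)), paste0, collapse = ".")
  setequal(unlist(ca), unlist(cb))
}
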