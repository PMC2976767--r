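## Maximum-parsimony scoring and constrained ratchet search.
##
## Trees are manipulated internally as parent vectors (tips 1..n, internals
## n+1..2n-1, root parent 0) so that NNI/SPR moves are O(1) and the C++
## scorer can walk them directly; they are converted to ape `phylo` objects
## only at module boundaries.

# run code under a temporary RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# encode supermatrix rows for `tips` (in order) into site patterns; patterns
# whose parsimony cost is the same on every topology (all entries pure bases
# or fully missing, and at most one state shared by two or more taxa) are
# pulled out of the scoring kernel and contribute a constant offset instead
encode_states <- function(sm, tips) {
  missing <- setdiff(tips, sm$species)
  if (length(missing)) {
    stop("tip(s) absent from matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  mat <- sm$matrix[tips, , drop = FALSE]
  masks <- matrix(IUPAC_MASK[mat], nrow(mat), ncol(mat))
  masks[is.na(masks)] <- 15L
  key <- apply(masks, 2L, paste0, collapse = ",")
  pat_id <- match(key, unique(key))
  npat <- max(pat_id)
  first <- match(seq_len(npat), pat_id)
  states <- t(masks[, first, drop = FALSE])  # patterns x tips
  storage.mode(states) <- "integer"

  const_cost <- rep(NA_real_, npat)
  for (p in seq_len(npat)) {
    st <- states[p, ]
    pure <- st[st %in% c(1L, 2L, 4L, 8L)]
    if (length(pure) + sum(st == 15L) < length(st)) next  # ambiguity: keep
    cnt <- table(pure)
    if (sum(cnt >= 2L) <= 1L) const_cost[p] <- max(0L, length(cnt) - 1L)
  }
  keep <- is.na(const_cost)
  list(states = states[keep, , drop = FALSE],
       base_weights = tabulate(pat_id, npat),
       keep = keep, const_cost = ifelse(keep, 0, const_cost),
       col_pattern = pat_id, tips = tips)
}

# per-pattern weights for the scoring kernel plus the constant offset
# contributed by the topology-independent patterns
pattern_weights <- function(enc, col_weights = NULL) {
  if (is.null(col_weights)) {
    w <- as.numeric(enc$base_weights)
  } else {
    if (length(col_weights) != length(enc$col_pattern)) {
      stop("weights must have one entry per matrix column", call. = FALSE)
    }
    w <- as.numeric(rowsum(as.numeric(col_weights), enc$col_pattern)[, 1L])
  }
  list(w = as.integer(w[enc$keep]),
       offset = sum(enc$const_cost * w))
}

#' Parsimony length of a tree on a supermatrix
#'
#' Minimum number of state changes summed over columns, computed with Fitch
#' counting generalised to polytomies (Hartigan). `?` and `-` carry the full
#' state set (missing); IUPAC ambiguity codes carry partial state sets.
#' Optional integer column weights multiply each column's cost.
#'
#' @param tree Rooted `phylo`; its tips must all occur in the matrix.
#' @param sm A `supermatrix`.
#' @param weights Optional per-column integer weights.
#' @return Non-negative number of changes.
#' @export
parsimony_length <- function(tree, sm, weights = NULL) {
  enc <- encode_states(sm, tree$tip.label)
  pw <- pattern_weights(enc, weights)
  pars_score_cpp(phylo_parent(tree), length(tree$tip.label), enc$states,
                 pw$w) + pw$offset
}

#' Search configuration for the constrained parsimony ratchet
#'
#' Defaults follow the classic ratchet scheme: within each random-addition
#' replicate, hill-climbing alternates between the original column weights
#' and a perturbed copy in which a random quarter of the columns count
#' double.
#'
#' @param n_addition_replicates Number of random-addition starting trees.
#' @param ratchet_iterations Perturb/restore cycles per replicate.
#' @param perturb_fraction Fraction of columns upweighted in each cycle.
#' @param perturb_weight Weight multiplier for perturbed columns.
#' @param seed Integer seed driving all randomness of the search.
#' @param max_retained Cap on the number of equally-parsimonious trees kept
#'   (first-found trees win on overflow).
#' @return A `search_config` list.
#' @export
search_config <- function(n_addition_replicates = 200L,
                          ratchet_iterations = 50L,
                          perturb_fraction = 0.25,
                          perturb_weight = 2L,
                          seed = 1L,
                          max_retained = 10000L) {
  stopifnot(n_addition_replicates >= 1L, ratchet_iterations >= 1L,
            perturb_fraction > 0, perturb_fraction < 1,
            perturb_weight >= 1L, max_retained >= 1L)
  structure(list(n_addition_replicates = as.integer(n_addition_replicates),
                 ratchet_iterations = as.integer(ratchet_iterations),
                 perturb_fraction = perturb_fraction,
                 perturb_weight = as.integer(perturb_weight),
                 seed = as.integer(seed),
                 max_retained = as.integer(max_retained)),
            class = "search_config")
}

## ---- parent-vector utilities ----------------------------------------------

children_of <- function(parent) {
  M <- length(parent)
  kids <- vector("list", M)
  for (v in seq_len(M)) {
    p <- parent[v]
    if (p > 0L) kids[[p]] <- c(kids[[p]], v)
  }
  kids
}

root_of <- function(parent, present = NULL) {
  cand <- which(parent == 0L)
  if (!is.null(present)) cand <- intersect(cand, present)
  if (length(cand) > 1L) cand <- cand[cand %in% parent]  # root has children
  cand[1L]
}

# tip sets (sorted original tip indices) below every present node
node_tipsets <- function(parent, ntip, present_tips) {
  M <- length(parent)
  sets <- vector("list", M)
  for (t in present_tips) sets[[t]] <- t
  kids <- children_of(parent)
  # reverse preorder visits every child before its parent
  rt <- root_of(parent)
  stack <- rt
  post <- integer(0)
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    post <- c(post, v)
    stack <- c(stack, kids[[v]])
  }
  for (v in rev(post)) {
    if (v > ntip || is.null(sets[[v]])) {
      if (length(kids[[v]])) {
        sets[[v]] <- sort(unlist(sets[kids[[v]]], use.names = FALSE))
      }
    }
  }
  sets
}

parent_to_newick <- function(parent, ntip, tip_labels) {
  kids <- children_of(parent)
  rec <- function(v) {
    if (v <= ntip) tip_labels[v]
    else paste0("(", paste(vapply(kids[[v]], rec, character(1)),
                           collapse = ","), ")")
  }
  paste0(rec(root_of(parent)), ";")
}

parent_to_phylo <- function(parent, ntip, tip_labels) {
  ape::read.tree(text = parent_to_newick(parent, ntip, tip_labels))
}

tree_hash <- function(parent, ntip) {
  sets <- node_tipsets(parent, ntip, seq_len(ntip))
  keys <- vapply(which(seq_along(sets) > ntip & !vapply(sets, is.null, TRUE)),
                 function(v) paste0(sets[[v]], collapse = "."), character(1))
  paste0(sort(keys), collapse = "|")
}

## ---- constrained stepwise addition ----------------------------------------

# restrict constraint clades (original tip indices) to a tip subset
restrict_clades <- function(clades, tips_present) {
  out <- lapply(clades, function(cl) cl[cl %in% tips_present])
  out[vapply(out, length, integer(1)) >= 2L]
}

# compact a partial tree to 1..m numbering for the C++ kernels
compact_tree <- function(parent, ntip, tips_present, internals_present) {
  m <- length(tips_present)
  ids <- c(tips_present, internals_present)
  map <- integer(length(parent))
  map[ids] <- seq_along(ids)
  cp <- integer(length(ids))
  for (i in seq_along(ids)) {
    p <- parent[ids[i]]
    cp[i] <- if (p == 0L) 0L else map[p]
  }
  list(parent = cp, ntip = m, map = map, tips = tips_present)
}

addition_tree_internal <- function(enc, clades, ntip, seed, pw = NULL) {
  if (is.null(pw)) pw <- pattern_weights(enc)
  order_tips <- with_seed(seed, sample.int(ntip))
  M <- 2L * ntip - 1L
  parent <- integer(M)
  rt <- ntip + 1L
  parent[order_tips[1L]] <- rt
  parent[order_tips[2L]] <- rt
  tips_in <- sort(order_tips[1:2])
  internals_in <- rt
  free <- (ntip + 2L):M

  for (i in 3:ntip) {
    t <- order_tips[i]
    tips_new <- sort(c(tips_in, t))
    rc <- restrict_clades(clades, tips_new)
    q <- free[1L]
    # candidate attachment: above any present node, or above the root
    root_now <- root_of(parent, internals_in)
    cands <- c(tips_in, internals_in)
    best <- NULL
    for (v in cands) {
      p2 <- parent
      if (v == root_now) {
        p2[q] <- 0L; p2[v] <- q; p2[t] <- q
      } else {
        p2[q] <- p2[v]; p2[v] <- q; p2[t] <- q
      }
      cmp <- compact_tree(p2, ntip, tips_new, c(internals_in, q))
      rc_c <- lapply(rc, function(cl) sort(cmp$map[cl]))
      if (!is_refinement_cpp(cmp$parent, cmp$ntip, rc_c)) next
      sc <- pars_score_cpp(cmp$parent, cmp$ntip,
                           enc$states[, tips_new, drop = FALSE], pw$w)
      if (is.null(best) || sc < best$sc) best <- list(sc = sc, parent = p2)
    }
    if (is.null(best)) stop("no constraint-compatible insertion point found")
    parent <- best$parent
    tips_in <- tips_new
    internals_in <- c(internals_in, q)
    free <- free[-1L]
  }
  parent
}

#' Constraint-compatible random-addition starting tree
#'
#' Taxa are added in seeded random order, each at the insertion point with
#' the smallest parsimony length among positions that keep the growing tree
#' compatible with the constraint. The result is binary and compatible.
#'
#' @param sm A `supermatrix` covering all constraint tips.
#' @param constraint A rooted constraint tree.
#' @param seed Integer seed.
#' @return A rooted binary `phylo`.
#' @export
random_addition_tree <- function(sm, constraint, seed = 1L) {
  tip_labels <- sort(constraint$tip.label)
  enc <- encode_states(sm, tip_labels)
  clades <- clades_in_ref(constraint, tip_labels)
  parent <- addition_tree_internal(enc, clades, length(tip_labels), seed)
  parent_to_phylo(parent, length(tip_labels), tip_labels)
}

## ---- hill climbing ---------------------------------------------------------

# NNI+SPR hill-climb under the constraint, with exact incremental
# rescoring in C++ (the SPR neighbourhood of a rooted binary tree contains
# every NNI). Returns the local optimum and its full parsimony score.
hillclimb <- function(parent, enc, pw, clades) {
  if (nrow(enc$states) == 0L) {
    return(list(parent = parent, score = pw$offset))
  }
  res <- spr_hillclimb_cpp(parent, length(enc$tips), enc$states, pw$w, clades)
  list(parent = res$parent, score = res$score + pw$offset)
}

## ---- ratchet search --------------------------------------------------------

#' Constrained maximum-parsimony ratchet search
#'
#' For each random-addition replicate the search alternates NNI+SPR
#' hill-climbing on the original column weights with hill-climbing on a
#' seeded perturbation in which a fraction of columns is upweighted, keeping
#' only constraint-compatible trees throughout. All distinct trees attaining
#' the best score found across replicates are returned.
#'
#' @param sm A `supermatrix`.
#' @param constraint A rooted constraint tree whose tips are the taxa to
#'   place.
#' @param config A [search_config()].
#' @return A `tree_set`: list with `trees` (list of `phylo`), `score`, and
#'   the `config` used.
#' @export
ratchet_search <- function(sm, constraint, config = search_config()) {
  tip_labels <- sort(constraint$tip.label)
  ntip <- length(tip_labels)
  enc <- encode_states(sm, tip_labels)
  clades <- clades_in_ref(constraint, tip_labels)
  base_w <- pattern_weights(enc)
  ncols <- length(enc$col_pattern)

  rep_seeds <- with_seed(config$seed,
                         sample.int(.Machine$integer.max - 1L,
                                    config$n_addition_replicates *
                                      (1L + config$ratchet_iterations)))
  rs <- matrix(rep_seeds, nrow = config$n_addition_replicates)

  best_score <- Inf
  pool <- list()
  pool_hashes <- character(0)

  offer <- function(parent, score) {
    if (score > best_score) return(invisible())
    if (score < best_score) {
      best_score <<- score
      pool <<- list()
      pool_hashes <<- character(0)
    }
    if (length(pool) >= config$max_retained) return(invisible())
    h <- tree_hash(parent, ntip)
    if (!h %in% pool_hashes) {
      pool[[length(pool) + 1L]] <<- parent
      pool_hashes <<- c(pool_hashes, h)
    }
    invisible()
  }

  for (r in seq_len(config$n_addition_replicates)) {
    parent <- addition_tree_internal(enc, clades, ntip, rs[r, 1L], base_w)
    hc <- hillclimb(parent, enc, base_w, clades)
    offer(hc$parent, hc$score)
    cur <- hc
    for (it in seq_len(config$ratchet_iterations)) {
      sel <- with_seed(rs[r, 1L + it],
                       sample.int(ncols, max(1L, round(config$perturb_fraction * ncols))))
      cw <- rep(1L, ncols)
      cw[sel] <- config$perturb_weight
      wpert <- pattern_weights(enc, cw)
      h1 <- hillclimb(cur$parent, enc, wpert, clades)
      h2 <- hillclimb(h1$parent, enc, base_w, clades)
      if (h2$score <= cur$score) cur <- h2
      offer(h2$parent, h2$score)
    }
  }

  trees <- lapply(pool, parent_to_phylo, ntip = ntip, tip_labels = tip_labels)
  for (tr in trees) stopifnot(is_compatible(tr, constraint))
  structure(list(trees = trees, score = best_score, tip_labels = tip_labels,
                 config = config),
            class = "tree_set")
}

#' @export
print.tree_set <- function(x, ...) {
  cat("<tree_set> ", length(x$trees), " equally parsimonious tree(s), score ",
      x$score, ", ", length(x$tip_labels), " tips\n", sep = "")
  invisible(x)
}

#' One-row summary of a parsimony search
#'
#' @param x A `tree_set`.
#' @param ... Unused.
#' @return A tibble with the shared score, tree count and tip count.
#' @export
#' @importFrom generics glance
glance.tree_set <- function(x, ...) {
  tibble::tibble(score = x$score, n_trees = length(x$trees),
                 n_tips = length(x$tip_labels))
}

#' Write a tree set as multi-tree Newick
#' @param x A `tree_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tree_set <- function(x, path) {
  ape::write.tree(structure(x$trees, class = "multiPhylo"), path)
  invisible(path)
}

## ---- consensus -------------------------------------------------------------

#' Majority-rule consensus with clade-frequency supports
#'
#' Clades occurring in more than `threshold` of the input trees are
#' retained; each retained node is labelled with `round(100 * frequency)`.
#' With `extended = TRUE`, remaining clades are added greedily by descending
#' frequency when compatible (majority-rule-extended).
#'
#' @param trees A `tree_set`, `multiPhylo`, or list of `phylo` trees on one
#'   tip set.
#' @param threshold Retention threshold as a frequency (default 0.5).
#' @param extended Add compatible minority clades greedily.
#' @return A rooted `phylo` with integer supports in `$node.label`.
#' @export
majority_consensus <- function(trees, threshold = 0.5, extended = FALSE) {
  if (inherits(trees, "tree_set")) trees <- trees$trees
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (length(trees) == 0L) stop("empty tree set", call. = FALSE)
  class(trees) <- "multiPhylo"
  n <- length(trees)
  labels <- sort(trees[[1L]]$tip.label)
  ntip <- length(labels)

  tally <- new.env(parent = emptyenv())
  for (tr in trees) {
    for (cl in clades_in_ref(tr, labels)) {
      if (length(cl) < 2L || length(cl) > ntip) next
      key <- paste0(cl, collapse = ".")
      tally[[key]] <- (tally[[key]] %||% 0L) + 1L
    }
  }
  keys <- ls(tally)
  counts <- vapply(keys, function(k) tally[[k]], integer(1))
  freq <- counts / n
  sets <- lapply(strsplit(keys, ".", fixed = TRUE), as.integer)
  sizes <- vapply(sets, length, integer(1))

  keep <- freq > threshold
  # the full tip set is always a clade
  if (!any(keep & sizes == ntip)) {
    sets <- c(sets, list(seq_len(ntip)))
    freq <- c(freq, 1)
    sizes <- c(sizes, ntip)
    keep <- c(keep, TRUE)
  }
  sel <- which(keep)
  if (extended) {
    rest <- setdiff(order(-freq), sel)
    for (i in rest) {
      compat_all <- all(vapply(sel, function(j) {
        a <- sets[[i]]; b <- sets[[j]]
        ab <- length(intersect(a, b))
        ab == 0L || ab == length(a) || ab == length(b)
      }, logical(1)))
      if (compat_all) sel <- c(sel, i)
    }
  }
  sel <- sel[order(-sizes[sel], vapply(sets[sel], paste0, character(1),
                                       collapse = "."))]
  csets <- sets[sel]
  csupp <- round(100 * freq[sel])

  build <- function(i) {
    mine <- csets[[i]]
    inner <- which(vapply(seq_along(csets), function(j)
      j != i && length(csets[[j]]) < length(mine) &&
        all(csets[[j]] %in% mine), logical(1)))
    # maximal proper sub-clades
    childi <- inner[vapply(inner, function(j)
      !any(vapply(inner, function(k)
        k != j && all(csets[[j]] %in% csets[[k]]) &&
          length(csets[[k]]) > length(csets[[j]]), logical(1))), logical(1))]
    covered <- unlist(csets[childi])
    loose <- setdiff(mine, covered)
    parts <- c(vapply(childi, build, character(1)), labels[sort(loose)])
    paste0("(", paste(parts, collapse = ","), ")", csupp[i])
  }
  rooti <- which(vapply(csets, length, integer(1)) == ntip)[1L]
  tree <- ape::read.tree(text = paste0(build(rooti), ";"))
  tree$node.label <- as.numeric(tree$node.label)
  tree
}

#' Node supports of a consensus tree as a tibble
#'
#' @param x A `phylo` with numeric node labels.
#' @param ... Unused.
#' @return Tibble with one row per internal node: node id, support, and the
#'   tips it subtends (as a list column).
#' @export
#' @importFrom generics tidy
tidy.phylo <- function(x, ...) {
  ntip <- length(x$tip.label)
  nodes <- ntip + seq_len(x$Nnode)
  tibble::tibble(
    node = nodes,
    support = if (is.null(x$node.label)) NA_real_ else as.numeric(x$node.label),
    tips = lapply(nodes, function(v) tips_below(x, v))
  )
}
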