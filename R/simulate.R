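#' Default locus models for the simulator
#'
#' Three loci mirroring the barcode trio: a slow indel-free coding locus
#' (rbcLa-like), a fast intergenic spacer accumulating indels
#' (trnH-psbA-like), and an intermediate coding locus (matK-like).
#' `rate_scale` multiplies branch lengths (expected substitutions/site);
#' `indel_rate` is the expected number of indel events per 100 sites per
#' unit branch length.
#'
#' @return Named list of per-locus parameter lists.
#' @export
default_loci <- function() {
  list(
    "rbcLa" = list(length = 520L, model = "JC69", kappa = 2,
                   rate_scale = 0.6, indel_rate = 0, coding = TRUE),
    "trnH-psbA" = list(length = 450L, model = "K2P", kappa = 2,
                       rate_scale = 2.5, indel_rate = 0.2, coding = FALSE),
    "matK" = list(length = 800L, model = "K2P", kappa = 2,
                  rate_scale = 1.5, indel_rate = 0, coding = TRUE)
  )
}

#' Simulation configuration
#'
#' Defaults describe a mid-sized tropical community sample: 60 species in 20
#' genera, 10 families and 5 orders, a root-to-tip depth of 0.15 expected
#' substitutions per site at the base rate, the three standard barcode loci,
#' and per-marker dropout probabilities matching the failure rates typical
#' of plot-scale barcoding (about 10% for rbcLa, 8% for trnH-psbA, 30% for
#' matK).
#'
#' @param n_orders Number of orders.
#' @param families_per_order,genera_per_family,species_per_genus Integer or
#'   integer vector (recycled across parents) of child counts.
#' @param tree_height Root-to-tip depth in expected substitutions/site.
#' @param depth_fractions Fractions of `tree_height` at which order, family
#'   and genus crowns start (descending).
#' @param loci Per-locus parameters, see [default_loci()].
#' @param dropout Named per-marker removal probabilities.
#' @param discordance Number of species regrafted outside their genus to
#'   break monophyly.
#' @param seed Integer seed.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_orders = 5L, families_per_order = 2L,
                              genera_per_family = 2L, species_per_genus = 3L,
                              tree_height = 0.15,
                              depth_fractions = c(order = 0.55,
                                                  family = 0.30,
                                                  genus = 0.12),
                              loci = default_loci(),
                              dropout = c("rbcLa" = 0.10,
                                          "trnH-psbA" = 0.08,
                                          "matK" = 0.30),
                              discordance = 0L, seed = 1L) {
  stopifnot(n_orders >= 1L, all(families_per_order >= 1L),
            all(genera_per_family >= 1L), all(species_per_genus >= 1L),
            tree_height > 0, all(dropout >= 0 & dropout <= 1),
            all(diff(depth_fractions) < 0), discordance >= 0L)
  for (lc in loci) stopifnot(lc$length > 0L, lc$rate_scale > 0,
                             lc$indel_rate >= 0)
  structure(list(n_orders = as.integer(n_orders),
                 families_per_order = as.integer(families_per_order),
                 genera_per_family = as.integer(genera_per_family),
                 species_per_genus = as.integer(species_per_genus),
                 tree_height = tree_height,
                 depth_fractions = depth_fractions,
                 loci = loci, dropout = dropout,
                 discordance = as.integer(discordance),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Generate a nested taxonomy from child counts
#'
#' Child counts are recycled across parents, so mixed genus sizes (e.g.
#' alternating monotypic and speciose genera) can be requested with a
#' vector.
#'
#' @inheritParams simulation_config
#' @return A `community_taxonomy` tibble.
#' @export
simulate_taxonomy <- function(n_orders, families_per_order,
                              genera_per_family, species_per_genus) {
  orders <- sprintf("Ord%02d", seq_len(n_orders))
  fpo <- rep_len(families_per_order, n_orders)
  fams <- sprintf("Fam%02d", seq_len(sum(fpo)))
  fam_order <- rep(orders, fpo)
  gpf <- rep_len(genera_per_family, length(fams))
  gens <- sprintf("Gen%03d", seq_len(sum(gpf)))
  gen_family <- rep(fams, gpf)
  spg <- rep_len(species_per_genus, length(gens))
  species <- unlist(lapply(seq_along(gens), function(i)
    sprintf("%ssp%d", gens[i], seq_len(spg[i]))))
  sp_genus <- rep(gens, spg)
  as_community_taxonomy(data.frame(
    species = species,
    genus = sp_genus,
    family = gen_family[match(sp_genus, gens)],
    order = fam_order[match(gen_family[match(sp_genus, gens)], fams)]
  ))
}

#' Generate a taxonomy with exact totals per rank
#'
#' Distributes children as evenly as possible so that the four rank totals
#' are hit exactly (e.g. the 143/108/50/24 shape of a real plot checklist).
#'
#' @param n_species,n_genera,n_families,n_orders Exact totals, each at least
#'   the next rank up.
#' @return A `community_taxonomy` tibble.
#' @export
simulate_taxonomy_totals <- function(n_species, n_genera, n_families,
                                     n_orders) {
  stopifnot(n_species >= n_genera, n_genera >= n_families,
            n_families >= n_orders, n_orders >= 1L)
  spread <- function(n_children, n_parents) {
    base <- n_children %/% n_parents
    extra <- n_children %% n_parents
    c(rep(base + 1L, extra), rep(base, n_parents - extra))
  }
  orders <- sprintf("Ord%02d", seq_len(n_orders))
  fpo <- spread(n_families, n_orders)
  fams <- sprintf("Fam%02d", seq_len(n_families))
  gpf <- spread(n_genera, n_families)
  gens <- sprintf("Gen%03d", seq_len(n_genera))
  spg <- spread(n_species, n_genera)
  species <- unlist(lapply(seq_len(n_genera), function(i)
    sprintf("%ssp%d", gens[i], seq_len(spg[i]))))
  as_community_taxonomy(data.frame(
    species = species,
    genus = rep(gens, spg),
    family = rep(rep(fams, gpf), spg),
    order = rep(rep(orders, fpo), tapply(spg, rep(seq_len(n_families), gpf), sum))
  ))
}

# Yule-shape ultrametric tree over `labels`, rescaled to `height`
yule_scaled <- function(labels, height) {
  n <- length(labels)
  if (n == 1L) return(NULL)
  tr <- ape::rphylo(n, birth = 1, death = 0)
  tr$tip.label <- labels[sample.int(n)]
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length * height / depth
  tr
}

# recursive Newick of `shape` with tips replaced by pre-built subtree strings
newick_substitute <- function(shape, repl) {
  ntip <- length(shape$tip.label)
  kids <- split(shape$edge[, 2], shape$edge[, 1])
  elen <- stats::setNames(shape$edge.length, shape$edge[, 2])
  rec <- function(v) {
    body <- if (v <= ntip) {
      repl[[shape$tip.label[v]]]
    } else {
      paste0("(", paste(vapply(kids[[as.character(v)]], rec, character(1)),
                        collapse = ","), ")")
    }
    if (v == ntip + 1L) body else paste0(body, ":", format(elen[[as.character(v)]], digits = 12))
  }
  rec(ntip + 1L)
}

# subtree string for one group: children glued under a Yule shape spanning
# the band [crown_to, crown_from]; singletons pass through with a longer stem
glue_level <- function(child_strings, crown_from, crown_to) {
  if (length(child_strings) == 1L) {
    return(child_strings[[1L]])  # stem handled by the caller's band
  }
  shape <- yule_scaled(names(child_strings), crown_from - crown_to)
  newick_substitute(shape, child_strings)
}

#' Simulate the true community: taxonomy, dated tree, and backbone
#'
#' Builds nested Yule-shaped trees per taxonomic rank and glues them
#' hierarchically, with order stems deepest: order crowns start at
#' `depth_fractions["order"]` of the total height, family crowns below
#' them, then genus crowns. All branch lengths are in expected
#' substitutions per site at the base rate. Every rank is monophyletic by
#' construction; `discordance` then regrafts that many species from
#' monotypic genera into foreign genera (preferring the same family) so that
#' exactly that many genera become non-monophyletic.
#'
#' @param config A [simulation_config()].
#' @return A `synthetic_truth` list: `taxonomy`, `tree` (species `phylo`),
#'   `backbone` (order `phylo`), `moved_species`, `config`.
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  taxonomy <- simulate_taxonomy(config$n_orders, config$families_per_order,
                                config$genera_per_family,
                                config$species_per_genus)
  H <- config$tree_height
  d <- config$depth_fractions * H

  with_seed(config$seed, {
    # each rank's subtree string spans from that rank's crown depth to the
    # present; the enclosing shape's tip edge supplies the stem above it,
    # and singleton groups get the band width appended explicitly
    gen_map <- split(taxonomy$species, taxonomy$genus)
    gen_str <- lapply(names(gen_map), function(g) {
      sp <- gen_map[[g]]
      if (length(sp) == 1L) paste0(sp, ":", format(d[["genus"]], digits = 12))
      else paste0(newick_substitute(yule_scaled(sp, d[["genus"]]),
                                    stats::setNames(as.list(sp), sp)))
    })
    names(gen_str) <- names(gen_map)

    fam_map <- split(unique(taxonomy$genus),
                     taxonomy$family[match(unique(taxonomy$genus),
                                           taxonomy$genus)])
    fam_str <- lapply(names(fam_map), function(f) {
      gs <- gen_str[fam_map[[f]]]
      if (length(gs) == 1L) {
        paste0(gs[[1L]], ":", format(d[["family"]] - d[["genus"]], digits = 12))
      } else {
        shape <- yule_scaled(names(gs), d[["family"]] - d[["genus"]])
        newick_substitute(shape, gs)
      }
    })
    names(fam_str) <- names(fam_map)

    ord_map <- split(unique(taxonomy$family),
                     taxonomy$order[match(unique(taxonomy$family),
                                          taxonomy$family)])
    ord_str <- lapply(names(ord_map), function(o) {
      fs <- fam_str[ord_map[[o]]]
      if (length(fs) == 1L) {
        paste0(fs[[1L]], ":", format(d[["order"]] - d[["family"]], digits = 12))
      } else {
        shape <- yule_scaled(names(fs), d[["order"]] - d[["family"]])
        newick_substitute(shape, fs)
      }
    })
    names(ord_str) <- names(ord_map)

    if (length(ord_str) == 1L) {
      tree <- ape::read.tree(text = paste0(ord_str[[1L]], ";"))
      backbone <- NULL
    } else {
      bb_shape <- yule_scaled(names(ord_str), H - d[["order"]])
      tree <- ape::read.tree(
        text = paste0(newick_substitute(bb_shape, ord_str), ";"))
      backbone <- bb_shape
    }

    moved <- character(0)
    if (config$discordance > 0L) {
      inj <- inject_discordance(tree, taxonomy, config$discordance)
      tree <- inj$tree
      moved <- inj$moved
    }

    structure(list(taxonomy = taxonomy, tree = tree, backbone = backbone,
                   moved_species = moved, config = config),
              class = "synthetic_truth")
  })
}

# regraft `n` species from monotypic genera into foreign genera (same
# family preferred), each move rendering exactly one target genus
# non-monophyletic
inject_discordance <- function(tree, taxonomy, n) {
  counts <- table(taxonomy$genus)
  donors_pool <- taxonomy$species[taxonomy$genus %in%
                                    names(counts)[counts == 1L]]
  if (length(donors_pool) < n) {
    stop("discordance injection needs at least ", n,
         " monotypic genera (found ", length(donors_pool), ")",
         call. = FALSE)
  }
  donors <- sample(sort(donors_pool), n)
  targets_pool <- names(counts)[counts >= 2L]
  if (length(targets_pool) < n) {
    stop("discordance injection needs at least ", n,
         " genera with two or more species", call. = FALSE)
  }
  moved <- character(0)
  used_targets <- character(0)
  for (sp in donors) {
    fam <- taxonomy$family[taxonomy$species == sp]
    cands <- setdiff(targets_pool, used_targets)
    same_fam <- cands[taxonomy$family[match(cands, taxonomy$genus)] == fam]
    target <- if (length(same_fam)) sample(sort(same_fam), 1L)
              else sample(sort(cands), 1L)
    used_targets <- c(used_targets, target)
    # attach inside the target genus: midpoint of a random member's
    # terminal edge
    member <- sample(sort(taxonomy$species[taxonomy$genus == target]), 1L)
    tree <- ape::drop.tip(tree, sp)
    mi <- which(tree$tip.label == member)
    elen <- tree$edge.length[tree$edge[, 2] == mi]
    graft <- ape::read.tree(text = paste0("(", sp, ":",
                                          format(elen / 2, digits = 12), ");"))
    tree <- ape::bind.tree(tree, graft, where = mi, position = elen / 2)
    moved <- c(moved, sp)
  }
  list(tree = tree, moved = moved)
}

## ---- sequence evolution ----------------------------------------------------

# uniform root sequence; coding loci are built from sense codons (in frame,
# no internal stops) so back-translation alignment sees realistic input
root_sequence <- function(length, coding) {
  if (!coding) return(sample.int(4L, length, replace = TRUE))
  codons <- expand.grid(1:4, 1:4, 1:4)
  bases <- c("A", "C", "G", "T")
  keys <- apply(codons, 1L, function(x) paste0(bases[x], collapse = ""))
  sense <- as.matrix(codons[!keys %in% c("TAA", "TAG", "TGA"), ])
  pick <- sense[sample.int(nrow(sense), ceiling(length / 3),
                           replace = TRUE), , drop = FALSE]
  as.integer(t(pick))[seq_len(length)]
}

# instantaneous rate matrix with unit mean rate, equal base frequencies
model_Q <- function(model, kappa = 2) {
  if (model == "JC69") {
    Q <- matrix(1 / 3, 4, 4)
  } else if (model == "K2P") {
    beta <- 1 / (kappa + 2)
    Q <- matrix(beta, 4, 4)
    # order A, C, G, T: transitions are A<->G and C<->T
    Q[1, 3] <- Q[3, 1] <- beta * kappa
    Q[2, 4] <- Q[4, 2] <- beta * kappa
  } else stop("unknown substitution model: ", model, call. = FALSE)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

# exact transition probabilities P = exp(Q d) via eigendecomposition
model_P <- function(Q, d) {
  e <- eigen(Q)
  P <- e$vectors %*% diag(exp(e$values * d)) %*% solve(e$vectors)
  P[P < 0] <- 0
  P / rowSums(P)
}

sim_branch <- function(seq_int, d, Q) {
  if (d <= 0) return(seq_int)
  P <- model_P(Q, d)
  out <- integer(length(seq_int))
  for (s in 1:4) {
    idx <- which(seq_int == s)
    if (length(idx)) out[idx] <- sample.int(4L, length(idx), replace = TRUE,
                                            prob = P[s, ])
  }
  out
}

apply_indels <- function(seq_int, n_events) {
  for (e in seq_len(n_events)) {
    len <- stats::rgeom(1L, 0.5) + 1L
    L <- length(seq_int)
    if (stats::runif(1) < 0.5 && L > len + 1L) {
      pos <- sample.int(L - len, 1L)
      seq_int <- seq_int[-(pos:(pos + len - 1L))]
    } else {
      pos <- sample.int(L, 1L)
      seq_int <- append(seq_int, sample.int(4L, len, replace = TRUE), pos)
    }
  }
  seq_int
}

#' Evolve barcode sequences along the true tree
#'
#' The root sequence is uniform over bases; substitutions are applied per
#' branch with exact transition probabilities (matrix exponential of the
#' model's rate matrix, times the scaled branch length). Spacer loci with a
#' positive `indel_rate` additionally accumulate geometric-length
#' insertions/deletions (Poisson number of events per branch).
#'
#' @param truth A `synthetic_truth`.
#' @param loci Per-locus parameter list; defaults to the configuration in
#'   `truth`.
#' @param seed Integer seed (defaults to the configuration seed + 1).
#' @return Tibble of records across markers (one per species and marker).
#' @export
evolve_sequences <- function(truth, loci = NULL, seed = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  loci <- loci %||% truth$config$loci
  seed <- seed %||% (truth$config$seed + 1L)
  tree <- ape::reorder.phylo(truth$tree, "cladewise")
  ntip <- length(tree$tip.label)
  bases <- c("A", "C", "G", "T")

  all_rec <- with_seed(seed, {
    out <- list()
    for (m in names(loci)) {
      lc <- loci[[m]]
      Q <- model_Q(lc$model, lc$kappa %||% 2)
      seqs <- vector("list", ntip + tree$Nnode)
      seqs[[ntip + 1L]] <- root_sequence(lc$length, isTRUE(lc$coding))
      for (i in seq_len(nrow(tree$edge))) {
        par <- tree$edge[i, 1L]
        child <- tree$edge[i, 2L]
        dscaled <- tree$edge.length[i] * lc$rate_scale
        s <- sim_branch(seqs[[par]], dscaled, Q)
        if (lc$indel_rate > 0) {
          lambda <- lc$indel_rate * dscaled * length(s) / 100
          s <- apply_indels(s, stats::rpois(1L, lambda))
        }
        seqs[[child]] <- s
      }
      out[[m]] <- tibble::tibble(
        sample_id = tree$tip.label,
        species_code = tree$tip.label,
        marker = m,
        bases = vapply(seq_len(ntip), function(t)
          paste0(bases[seqs[[t]]], collapse = ""), character(1))
      )
    }
    dplyr::bind_rows(out)
  })
  all_rec
}

#' Apply per-marker sequence dropout
#'
#' Independent Bernoulli removal per (species, marker). The flag table is
#' exactly what [recovery_table()] consumes.
#'
#' @param records Tibble of sequence records.
#' @param probs Named per-marker removal probabilities (markers absent from
#'   `probs` are never dropped).
#' @param seed Integer seed.
#' @return List with `records` (survivors) and `flags` (tibble `sample_id`,
#'   `marker`, `success`).
#' @export
apply_dropout <- function(records, probs, seed = 1L) {
  stopifnot(all(probs >= 0 & probs <= 1))
  p <- unname(probs[records$marker])
  p[is.na(p)] <- 0
  keep <- with_seed(seed, stats::runif(nrow(records)) >= p)
  list(records = records[keep, , drop = FALSE],
       flags = tibble::tibble(sample_id = records$sample_id,
                              marker = records$marker,
                              success = keep))
}

#' Simulate a complete community data set
#'
#' Convenience wrapper: [simulate_truth()], [evolve_sequences()], and
#' [apply_dropout()] in sequence, optionally writing the same FASTA, TSV and
#' Newick files the pipeline consumes.
#'
#' @param config A [simulation_config()].
#' @param out_dir Optional directory to write `<marker>.fasta`,
#'   `taxonomy.tsv`, `backbone.nwk`, `true_tree.nwk` and `flags.csv` into.
#' @return List with `truth`, `records` (post-dropout), `flags`.
#' @export
simulate_community <- function(config, out_dir = NULL) {
  truth <- simulate_truth(config)
  records <- evolve_sequences(truth)
  drop <- apply_dropout(records, config$dropout, seed = config$seed + 2L)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (m in unique(drop$records$marker)) {
      write_fasta(drop$records[drop$records$marker == m, ],
                  file.path(out_dir, paste0(gsub("[^A-Za-z]", "_", m), ".fasta")))
    }
    write_taxonomy(truth$taxonomy, file.path(out_dir, "taxonomy.tsv"))
    if (!is.null(truth$backbone)) {
      ape::write.tree(truth$backbone, file.path(out_dir, "backbone.nwk"))
    }
    ape::write.tree(truth$tree, file.path(out_dir, "true_tree.nwk"))
    utils::write.csv(drop$flags, file.path(out_dir, "flags.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  list(truth = truth, records = drop$records, flags = drop$flags)
}
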