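# shared fixtures: small supermatrices, tree enumeration oracles, taxonomies

make_sm <- function(mat, label = "x") {
  structure(list(species = rownames(mat), matrix = mat,
                 partitions = tibble::tibble(label = label, start = 0L,
                                             end = ncol(mat)),
                 excluded_species = character(0)),
            class = "supermatrix")
}

random_sm <- function(labels, ncols, seed) {
  set.seed(seed)
  mat <- matrix(sample(c("A", "C", "G", "T"), length(labels) * ncols,
                       replace = TRUE),
                length(labels), ncols, dimnames = list(labels, NULL))
  make_sm(mat)
}

star_tree <- function(labels) {
  ape::read.tree(text = paste0("(", paste(labels, collapse = ","), ");"))
}

# all rooted binary tree shapes over `labels`, by stepwise insertion into
# every edge plus above the root (independent enumeration oracle)
enum_rooted_shapes <- function(labels) {
  stopifnot(length(labels) >= 2)
  trees <- list(ape::read.tree(text = paste0("(", labels[1], ",",
                                             labels[2], ");")))
  if (length(labels) == 2) return(trees)
  for (i in 3:length(labels)) {
    nxt <- list()
    for (tr in trees) {
      for (e in seq_len(nrow(tr$edge))) {
        tr$edge.length <- rep(1, nrow(tr$edge))
        tr2 <- suppressWarnings(
          ape::bind.tree(tr, ape::read.tree(text = paste0("(", labels[i],
                                                          ":1);")),
                         where = tr$edge[e, 2], position = 0.5))
        tr2$edge.length <- NULL
        nxt[[length(nxt) + 1L]] <- tr2
      }
      tr$edge.length <- NULL
      nxt[[length(nxt) + 1L]] <- ape::read.tree(
        text = paste0("(", labels[i], ",",
                      sub(";$", "", ape::write.tree(tr)), ");"))
    }
    trees <- nxt
  }
  trees
}

# independent parsimony oracle (phangorn's Fitch implementation)
phangorn_scores <- function(trees, sm) {
  dat <- phangorn::phyDat(sm$matrix, type = "DNA")
  if (inherits(trees, "phylo")) trees <- list(trees)
  class(trees) <- "multiPhylo"
  phangorn::parsimony(trees, dat)
}

# two-order community used by several search tests
two_order_fixture <- function() {
  tax <- as_community_taxonomy(data.frame(
    species = c(paste0("a", 1:4), paste0("b", 1:4)),
    genus = rep(c("GA", "GB"), each = 4),
    family = rep(c("FA", "FB"), each = 4),
    order = rep(c("OA", "OB"), each = 4)))
  backbone <- ape::read.tree(text = "(OA,OB);")
  constraint <- build_constraint(backbone, tax, tax$species)
  list(taxonomy = tax, backbone = backbone, constraint = constraint)
}

write_tmp_fasta <- function(lines) {
  f <- tempfile(fileext = ".fa")
  writeLines(lines, f)
  f
}
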