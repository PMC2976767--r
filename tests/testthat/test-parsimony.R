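test_that("parsimony length handles trivial and hand-computed cases", {
  labs <- c("a1", "a2", "t1", "t2")
  constant <- make_sm(matrix("A", 4, 5, dimnames = list(labs, NULL)))
  tr <- ape::read.tree(text = "((a1,a2),(t1,t2));")
  expect_equal(parsimony_length(tr, constant), 0)

  one_col <- make_sm(matrix(c("A", "A", "T", "T"), 4, 1,
                            dimnames = list(labs, NULL)))
  expect_equal(parsimony_length(tr, one_col), 1)
  anti <- ape::read.tree(text = "((a1,t1),(a2,t2));")
  expect_equal(parsimony_length(anti, one_col), 2)

  # Hartigan at a hard polytomy: star on A,A,T,T needs 2 changes
  expect_equal(parsimony_length(star_tree(labs), one_col), 2)

  # missing data and ambiguity carry partial state sets
  amb <- make_sm(matrix(c("R", "A", "T", "?"), 4, 1,
                        dimnames = list(labs, NULL)))
  expect_equal(parsimony_length(tr, amb), 1)  # R={A,G} matches A; T differs
})

test_that("column weights multiply per-column cost", {
  labs <- c("a1", "a2", "t1", "t2")
  sm <- make_sm(matrix(c("A", "A", "T", "T", "A", "C", "A", "C"), 4, 2,
                       dimnames = list(labs, NULL)))
  tr <- ape::read.tree(text = "((a1,a2),(t1,t2));")
  expect_equal(parsimony_length(tr, sm), 1 + 2)
  expect_equal(parsimony_length(tr, sm, weights = c(3L, 10L)), 3 + 20)
})

test_that("score is invariant under re-rooting and padding taxa", {
  set.seed(7)
  labs <- paste0("t", 1:6)
  sm <- random_sm(labs, 30, seed = 7)
  tr <- enum_rooted_shapes(labs)[[17]]
  s0 <- parsimony_length(tr, sm)
  for (og in c("t1", "t4", "t6")) {
    rr <- ape::root(ape::unroot(tr), outgroup = og, resolve.root = TRUE)
    expect_equal(parsimony_length(rr, sm), s0)
  }
  # an all-missing taxon never changes the score
  sm2 <- make_sm(rbind(sm$matrix, t7 = rep("?", 30)))
  tr2 <- ape::read.tree(text = paste0("(t7,", sub(";$", "", ape::write.tree(tr)), ");"))
  expect_equal(parsimony_length(tr2, sm2), s0)
})

test_that("scores agree with phangorn on random binary trees", {
  for (seed in 1:5) {
    labs <- paste0("t", 1:7)
    sm <- random_sm(labs, 25, seed = 100 + seed)
    set.seed(seed)
    trees <- replicate(4, ape::rtree(7, tip.label = labs), simplify = FALSE)
    trees <- lapply(trees, function(tr) { tr$edge.length <- NULL; tr })
    mine <- vapply(trees, parsimony_length, numeric(1), sm = sm)
    oracle <- phangorn_scores(trees, sm)
    expect_equal(unname(mine), unname(oracle))
  }
})

test_that("random addition is deterministic and respects the constraint", {
  fx <- two_order_fixture()
  sm <- random_sm(sort(fx$taxonomy$species), 40, seed = 11)
  t1 <- random_addition_tree(sm, fx$constraint, seed = 5)
  t2 <- random_addition_tree(sm, fx$constraint, seed = 5)
  expect_equal(ape::write.tree(t1), ape::write.tree(t2))
  expect_true(is_compatible(t1, fx$constraint))
  # orders never mix: every tree from different seeds keeps the split
  for (s in 1:5) {
    tr <- random_addition_tree(sm, fx$constraint, seed = s)
    expect_true(is_compatible(tr, fx$constraint))
    expect_true(ape::is.binary(tr))
  }
})

test_that("ratchet improves on (or matches) its starting trees", {
  fx <- two_order_fixture()
  sm <- random_sm(sort(fx$taxonomy$species), 40, seed = 23)
  start <- random_addition_tree(sm, fx$constraint, seed = 1)
  ts <- ratchet_search(sm, fx$constraint,
                       search_config(n_addition_replicates = 2,
                                     ratchet_iterations = 2, seed = 1))
  expect_lte(ts$score, parsimony_length(start, sm))
  for (tr in ts$trees) expect_true(is_compatible(tr, fx$constraint))
  expect_true(all(vapply(ts$trees, parsimony_length, numeric(1), sm = sm) ==
                    ts$score))
})

test_that("majority consensus keeps clades above threshold with rounded supports", {
  t_ab <- ape::read.tree(text = "((A,B),(C,D));")
  t_ac <- ape::read.tree(text = "((A,C),(B,D));")
  # 10 identical trees -> same tree, all supports 100
  cons <- majority_consensus(rep(list(t_ab), 10))
  expect_true(ape::all.equal.phylo(cons, t_ab, use.edge.length = FALSE))
  expect_true(all(as.numeric(cons$node.label) == 100))

  # {AB x2, AC x1}: AB clade at 67
  cons2 <- majority_consensus(list(t_ab, t_ab, t_ac))
  lab <- cons2$tip.label
  cl <- lapply(ape::prop.part(cons2), function(i) sort(lab[i]))
  ab <- which(vapply(cl, function(x) identical(x, c("A", "B")), logical(1)))
  expect_length(ab, 1L)
  expect_equal(as.numeric(cons2$node.label)[ab], 67)

  # maximally conflicting pair -> star
  cons3 <- majority_consensus(list(t_ab, t_ac))
  expect_equal(cons3$Nnode, 1L)
})

test_that("consensus supports take only attainable frequency values", {
  set.seed(31)
  labs <- paste0("t", 1:6)
  trees <- replicate(7, {
    tr <- ape::rtree(6, tip.label = labs); tr$edge.length <- NULL; tr
  }, simplify = FALSE)
  cons <- majority_consensus(trees)
  supp <- as.numeric(cons$node.label)
  attainable <- round(100 * (1:7) / 7)
  expect_true(all(supp %in% attainable))
})

test_that("tree-set summaries and consensus tidiers work", {
  fx <- two_order_fixture()
  sm <- random_sm(sort(fx$taxonomy$species), 30, seed = 3)
  ts <- ratchet_search(sm, fx$constraint,
                       search_config(n_addition_replicates = 1,
                                     ratchet_iterations = 1, seed = 2))
  g <- generics::glance(ts)
  expect_equal(g$n_tips, 8L)
  expect_equal(g$n_trees, length(ts$trees))
  cons <- majority_consensus(ts)
  td <- generics::tidy(cons)
  expect_equal(nrow(td), cons$Nnode)
  expect_true(all(lengths(td$tips) >= 2))
})
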