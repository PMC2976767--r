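test_that("resolution percentage spans binary to star", {
  expect_equal(resolution_fraction(
    ape::read.tree(text = "((A,B),(C,D));")), 100)
  expect_equal(resolution_fraction(
    ape::read.tree(text = "(A,B,(C,D));")), 50)
  expect_equal(resolution_fraction(star_tree(paste0("t", 1:10))), 0)
  expect_error(resolution_fraction(star_tree(c("A", "B"))), "3 tips")
})

test_that("resolution never decreases as polytomies are refined", {
  t0 <- star_tree(paste0("t", 1:6))
  t1 <- ape::read.tree(text = "((t1,t2),t3,t4,t5,t6);")
  t2 <- ape::read.tree(text = "((t1,t2),(t3,t4),(t5,t6));")
  t3 <- ape::read.tree(text = "(((t1,t2),(t3,t4)),(t5,t6));")
  r <- vapply(list(t0, t1, t2, t3), resolution_fraction, numeric(1))
  expect_true(all(diff(r) >= 0))
})

test_that("support bins follow the cumulative boundary rules", {
  # root is unscored; scored internal labels are 90, 40, 60
  tr <- ape::read.tree(text = "(((A,B)40,(C,D)60)90,E);")
  b <- support_bins(tr)
  expect_equal(b$n_nodes, 3L)
  expect_equal(unlist(b[c("lt50", "ge50", "b50_70", "ge70", "b70_85",
                          "ge85")], use.names = FALSE),
               c(33.3, 66.7, 33.3, 33.3, 0, 33.3))
  # row-sum identities within rounding
  expect_equal(b$lt50 + b$ge50, 100, tolerance = 0.11)
  expect_equal(b$b50_70 + b$ge70, b$ge50, tolerance = 0.11)

  all100 <- ape::read.tree(text = "(((A,B)100,(C,D)100)100,E);")
  expect_equal(unlist(support_bins(all100)[-1], use.names = FALSE),
               c(0, 100, 0, 100, 0, 100))

  star <- star_tree(paste0("t", 1:5))
  bs <- support_bins(star)
  expect_equal(bs$n_nodes, 0L)
  expect_true(all(unlist(bs[-1]) == 0))

  unsup <- ape::read.tree(text = "(((A,B),C),D);")
  expect_error(support_bins(unsup), "consensus")
})

test_that("monophyly is judged by the smallest containing clade", {
  tax <- as_community_taxonomy(data.frame(
    species = c("g1a", "g1b", "g2a", "g2b", "solo"),
    genus = c("G1", "G1", "G2", "G2", "G3"),
    family = "F", order = "O"))
  good <- ape::read.tree(text = "(((g1a,g1b),(g2a,g2b)),solo);")
  rep1 <- monophyly_report(good, tax, "genus")
  expect_equal(rep1$status[rep1$taxon == "G1"], "monophyletic")
  expect_equal(rep1$status[rep1$taxon == "G3"], "singleton")

  tangled <- ape::read.tree(text = "(((g1a,g2a),(g1b,g2b)),solo);")
  rep2 <- monophyly_report(tangled, tax, "genus")
  expect_equal(rep2$status[rep2$taxon %in% c("G1", "G2")],
               rep("non-monophyletic", 2))

  # invariant under re-rooting outside the taxon's subtree
  rr <- ape::root(ape::unroot(good), outgroup = "solo",
                  resolve.root = TRUE)
  rep3 <- monophyly_report(rr, tax, "genus")
  expect_equal(rep3$status, rep1$status)
})

test_that("misplaced orders counts the complement of the best agreeing subset", {
  # 8 orders, one species each, balanced backbone
  tax <- as_community_taxonomy(data.frame(
    species = paste0("s", 1:8), genus = paste0("g", 1:8),
    family = paste0("f", 1:8), order = paste0("O", 1:8)))
  bb <- ape::read.tree(
    text = "(((O1,O2),(O3,O4)),((O5,O6),(O7,O8)));")
  tree_ok <- ape::read.tree(
    text = "(((s1,s2),(s3,s4)),((s5,s6),(s7,s8)));")
  expect_equal(misplaced_orders(tree_ok, bb, tax)$n_misplaced, 0L)

  # regraft O1 next to O7
  tree_moved <- ape::read.tree(
    text = "((s2,(s3,s4)),((s5,s6),((s7,s1),s8)));")
  mo <- misplaced_orders(tree_moved, bb, tax)
  expect_equal(mo$n_misplaced, 1L)
  expect_equal(mo$misplaced, "O1")
})

test_that("non-monophyletic orders are inherently misplaced", {
  tax <- as_community_taxonomy(data.frame(
    species = c("a1", "a2", "b1", "b2", "c1"),
    genus = c("ga", "ga", "gb", "gb", "gc"),
    family = c("fa", "fa", "fb", "fb", "fc"),
    order = c("OA", "OA", "OB", "OB", "OC")))
  bb <- ape::read.tree(text = "((OA,OB),OC);")
  tangled <- ape::read.tree(text = "(((a1,b1),(a2,b2)),c1);")
  mo <- misplaced_orders(tangled, bb, tax)
  expect_true(all(c("OA", "OB") %in% mo$misplaced))
})
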