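test_that("truth simulation is deterministic and counts multiply out", {
  cfg <- simulation_config(n_orders = 3L, families_per_order = 2L,
                           genera_per_family = 2L, species_per_genus = 2L,
                           seed = 4)
  t1 <- simulate_truth(cfg)
  t2 <- simulate_truth(cfg)
  expect_equal(ape::write.tree(t1$tree), ape::write.tree(t2$tree))
  expect_equal(nrow(t1$taxonomy), 3 * 2 * 2 * 2)
  expect_setequal(t1$backbone$tip.label, unique(t1$taxonomy$order))

  # every rank is monophyletic on the true tree
  for (rk in c("genus", "family", "order")) {
    rep <- monophyly_report(t1$tree, t1$taxonomy, rk)
    expect_true(all(rep$status != "non-monophyletic"))
  }
  # order stems are deepest: tree is ultrametric with the configured height
  depths <- ape::node.depth.edgelength(t1$tree)
  ntip <- length(t1$tree$tip.label)
  expect_equal(unname(depths[1:ntip]), rep(cfg$tree_height, ntip),
               tolerance = 1e-8)
})

test_that("discordance injection breaks exactly the requested genera", {
  cfg <- simulation_config(n_orders = 2L, families_per_order = 2L,
                           genera_per_family = 2L,
                           species_per_genus = c(1L, 3L),
                           discordance = 2L, seed = 9)
  truth <- simulate_truth(cfg)
  rep <- monophyly_report(truth$tree, truth$taxonomy, "genus")
  expect_equal(sum(rep$status == "non-monophyletic"), 2L)
  expect_length(truth$moved_species, 2L)
})

test_that("substitution counts match the JC69 closed form", {
  Q <- barcomm:::model_Q("JC69")
  d <- 0.1
  L <- 100000L
  set.seed(12)
  anc <- sample.int(4L, L, replace = TRUE)
  der <- barcomm:::sim_branch(anc, d, Q)
  p_obs <- mean(anc != der)
  p_exp <- 0.75 * (1 - exp(-4 * d / 3))
  se <- sqrt(p_exp * (1 - p_exp) / L)
  expect_lt(abs(p_obs - p_exp), 3 * se)
})

test_that("K2P transitions outnumber transversions per closed form", {
  Q <- barcomm:::model_Q("K2P", kappa = 5)
  P <- barcomm:::model_P(Q, 0.2)
  expect_equal(rowSums(P), rep(1, 4), tolerance = 1e-12)
  # A->G (transition) more likely than A->C (transversion) for kappa > 1
  expect_gt(P[1, 3], P[1, 2])
  # rate 0 -> identity
  expect_equal(barcomm:::model_P(Q, 0), diag(4), tolerance = 1e-12)
})

test_that("zero rate and zero indel rate leave sequences identical", {
  cfg <- simulation_config(n_orders = 2L, families_per_order = 1L,
                           genera_per_family = 2L, species_per_genus = 2L,
                           seed = 2)
  truth <- simulate_truth(cfg)
  loci <- list("rbcLa" = list(length = 60L, model = "JC69",
                              rate_scale = 1e-12, indel_rate = 0,
                              coding = FALSE))
  rec <- evolve_sequences(truth, loci = loci, seed = 5)
  expect_equal(length(unique(rec$bases)), 1L)
  expect_true(all(nchar(rec$bases) == 60L))

  spacer <- list("trnH-psbA" = list(length = 80L, model = "JC69",
                                    rate_scale = 2, indel_rate = 0,
                                    coding = FALSE))
  rec2 <- evolve_sequences(truth, loci = spacer, seed = 6)
  expect_true(all(nchar(rec2$bases) == 80L))
  spacer$`trnH-psbA`$indel_rate <- 25
  rec3 <- evolve_sequences(truth, loci = spacer, seed = 6)
  expect_gt(length(unique(nchar(rec3$bases))), 1L)
})

test_that("dropout removal is Bernoulli with the requested rate and seeded", {
  rec <- tibble::tibble(sample_id = paste0("s", 1:1000),
                        species_code = paste0("s", 1:1000),
                        marker = "matK",
                        bases = "ACGT")
  d1 <- apply_dropout(rec, c("matK" = 0.3), seed = 8)
  d2 <- apply_dropout(rec, c("matK" = 0.3), seed = 8)
  expect_identical(d1$flags, d2$flags)
  removed <- sum(!d1$flags$success)
  expect_lt(abs(removed - 300), 3 * sqrt(1000 * 0.3 * 0.7))
  expect_equal(nrow(d1$records), 1000 - removed)

  d0 <- apply_dropout(rec, c("matK" = 0), seed = 8)
  expect_equal(nrow(d0$records), 1000L)
})

test_that("simulate_community writes the formats the pipeline consumes", {
  cfg <- simulation_config(n_orders = 2L, families_per_order = 1L,
                           genera_per_family = 2L, species_per_genus = 2L,
                           seed = 3,
                           loci = default_loci()[c("rbcLa")],
                           dropout = c("rbcLa" = 0))
  dir <- tempfile()
  sim <- simulate_community(cfg, out_dir = dir)
  rec <- read_fasta(file.path(dir, "rbcLa.fasta"), "rbcLa")
  expect_equal(sort(rec$species_code), sort(sim$records$species_code))
  tax <- read_taxonomy(file.path(dir, "taxonomy.tsv"))
  expect_equal(as.data.frame(tax), as.data.frame(sim$truth$taxonomy))
  bb <- read_backbone(file.path(dir, "backbone.nwk"), tax)
  expect_setequal(bb$tip.label, unique(tax$order))
})
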