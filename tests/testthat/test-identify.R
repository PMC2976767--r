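small_tax <- function() {
  as_community_taxonomy(data.frame(
    species = c("sp1", "sp2", "sp3"),
    genus = c("G1", "G1", "G2"),
    family = c("F1", "F1", "F1"),
    order = "O1"))
}

test_that("recovery table rolls success up the hierarchy", {
  tax <- small_tax()
  s2s <- tibble::tibble(sample_id = c("a", "b", "c", "d"),
                        species = c("sp1", "sp1", "sp2", "sp3"))
  flags <- tibble::tibble(
    sample_id = rep(c("a", "b", "c", "d"), each = 2),
    marker = rep(c("rbcLa", "matK"), 4),
    success = c(FALSE, TRUE,  TRUE, FALSE,  FALSE, FALSE,  TRUE, TRUE))
  rt <- recovery_table(flags, s2s, tax)

  cell <- function(level, column, what = "successes") {
    rt[[what]][rt$level == level & rt$column == column]
  }
  # sp1 has one failed and one successful rbcLa sample -> species succeeds
  expect_equal(cell("species", "rbcLa"), 2L)
  expect_equal(cell("species", "matK"), 2L)
  expect_equal(cell("sample", "rbcLa"), 2L)
  # union column: any marker per sample before rollup
  expect_equal(cell("sample", "rbcLa+matK"), 3L)
  expect_equal(cell("genus", "rbcLa+matK"), 2L)
  expect_equal(cell("order", "rbcLa+matK"), 1L)
  # totals come from the taxonomy
  expect_equal(cell("species", "rbcLa", "total"), 3L)
  expect_equal(cell("order", "rbcLa", "total"), 1L)

  # success at a level implies success at every coarser level
  for (col in unique(rt$column)) {
    sub <- rt[rt$column == col, ]
    sp <- sub$successes[sub$level == "species"]
    expect_gte(sub$successes[sub$level == "genus"] > 0, sp > 0)
  }

  expect_error(recovery_table(flags, s2s[1:2, ], tax), "not mapped")
})

test_that("all-true flags give 100% everywhere", {
  tax <- small_tax()
  s2s <- tibble::tibble(sample_id = c("a", "b", "c"),
                        species = c("sp1", "sp2", "sp3"))
  flags <- tidyr::expand_grid(sample_id = c("a", "b", "c"),
                              marker = c("rbcLa", "matK")) |>
    dplyr::mutate(success = TRUE)
  rt <- recovery_table(flags, s2s, tax)
  expect_true(all(rt$pct == 100))
})

test_that("leave-one-out identification applies the conservative tie rule", {
  tax <- small_tax()
  base <- strrep("ACGTTGCAAC", 20)
  mutate_at <- function(s, pos, to) {
    substr(s, pos, pos) <- to
    s
  }
  sp2 <- base
  for (p in c(1, 11, 21)) sp2 <- mutate_at(sp2, p, "T")      # A -> T
  sp3 <- base
  for (p in c(2, 12, 22, 32, 42)) sp3 <- mutate_at(sp3, p, "G")  # C -> G
  # one sequence plus an exact duplicate per species -> species CI 100%
  rec <- tibble::tibble(
    sample_id = paste0("q", 1:6),
    species_code = rep(c("sp1", "sp2", "sp3"), each = 2),
    marker = "rbcLa",
    bases = rep(c(base, sp2, sp3), each = 2))
  rep1 <- loo_identify(rec, tax)
  expect_equal(rep1$ci[rep1$rank == "species"], 1)

  # two congeneric species with identical sequences: wrong at species,
  # right at genus
  rec2 <- tibble::tibble(
    sample_id = paste0("q", 1:3),
    species_code = c("sp1", "sp2", "sp3"),
    marker = "rbcLa",
    bases = c(base, base, sp3))
  rep2 <- loo_identify(rec2, tax)
  oc <- attr(rep2, "outcomes")
  expect_setequal(oc$hit_species[[1]], "sp2")  # sp1's best hit is identical sp2
  expect_equal(rep2$n_correct[rep2$rank == "species"], 0L)
  # sp1 and sp2 are congeneric, so their queries are genus-correct; sp3's
  # best hit is a different genus
  expect_equal(rep2$n_correct[rep2$rank == "genus"], 2L)
  expect_equal(rep2$ci[rep2$rank == "family"], 1)
})

test_that("a pair of identical sister species yields 80% species CI", {
  # 10 species, 2 sequences each; one congeneric pair identical
  tax <- as_community_taxonomy(data.frame(
    species = paste0("sp", 1:10),
    genus = c("G1", "G1", paste0("G", 2:9)),
    family = "F1", order = "O1"))
  set.seed(99)
  base <- paste0(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  seqs <- character(10)
  seqs[1] <- base
  seqs[2] <- base  # identical sisters sp1/sp2 (same genus)
  for (i in 3:10) {
    s <- strsplit(base, "")[[1]]
    pos <- sample(300, 25 + i)
    s[pos] <- sample(c("A", "C", "G", "T"), length(pos), TRUE)
    seqs[i] <- paste0(s, collapse = "")
  }
  rec <- tibble::tibble(
    sample_id = paste0("s", 1:20),
    species_code = rep(paste0("sp", 1:10), each = 2),
    marker = "trnH-psbA",
    bases = rep(seqs, each = 2))
  out <- loo_identify(rec, tax, ranks = c("species", "genus"))
  expect_equal(out$ci[out$rank == "species"], 0.8)
  expect_equal(out$ci[out$rank == "genus"], 1)
})

test_that("CI at a coarser rank is never below CI at a finer rank", {
  cfg <- simulation_config(n_orders = 2L, families_per_order = 2L,
                           genera_per_family = 2L, species_per_genus = 2L,
                           discordance = 0L, seed = 17,
                           dropout = c("rbcLa" = 0))
  truth <- simulate_truth(cfg)
  rec <- evolve_sequences(truth,
                          loci = default_loci()["rbcLa"], seed = 18)
  out <- loo_identify(rec, truth$taxonomy)
  ci <- setNames(out$ci, out$rank)
  expect_true(ci["genus"] >= ci["species"])
  expect_true(ci["family"] >= ci["genus"])
  expect_true(ci["order"] >= ci["family"])
})

test_that("recovery times CI rounds half away from zero on proportions", {
  rec <- recovery_table_from_counts(tibble::tibble(
    level = c("species", "species", "species"),
    column = c("matK", "mk2", "mk3"),
    successes = c(100, 1, 50), total = c(143, 2, 100)))
  rep <- tibble::tibble(marker = c("matK", "mk2", "mk3"),
                        rank = "species",
                        n_queries = 10L, n_correct = 10L,
                        ci = c(1, 0.5, 0))
  class(rep) <- c("identification_report", class(rep))
  out <- recovery_times_ci(rec, rep)
  expect_equal(out$recovery_times_ci[out$marker == "matK"], 70)   # .6993 -> 70
  expect_equal(out$recovery_times_ci[out$marker == "mk2"], 25)    # .5 x .5
  expect_equal(out$recovery_times_ci[out$marker == "mk3"], 0)     # CI 0
  # a report key with no recovery entry errors
  rep2 <- rep
  rep2$marker[1] <- "nope"
  expect_error(recovery_times_ci(rec, rep2), "nope")
})
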