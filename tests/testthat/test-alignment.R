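rec_tbl <- function(seqs, marker = "rbcLa") {
  tibble::tibble(sample_id = names(seqs), species_code = names(seqs),
                 marker = marker, bases = unname(seqs))
}

test_that("indel-free equal-length input aligns as a plain stack", {
  seqs <- setNames(rep(strrep("ACGTA", 6), 5), paste0("sp", 1:5))
  aln <- align_coding_global(rec_tbl(seqs))
  expect_equal(alignment_ncol(aln), 30L)
  expect_false(any(grepl("-", aln$seqs)))

  two <- c(a = "ACGTACGTAC", b = "ACCTACGTAT")  # 2 substitutions, no indel
  aln2 <- align_coding_global(rec_tbl(two))
  expect_equal(alignment_ncol(aln2), 10L)
  expect_equal(unname(aln2$seqs[c("a", "b")]), unname(two))
})

test_that("pairwise alignment matches an independent dynamic-programming oracle", {
  # match +1, mismatch -1, gap open -2, extend -1 (length-L gap costs L+1)
  out <- progressive_align(c(x = "ACGTACGT", y = "ACGACGT"), "dna")
  expect_equal(unname(out["x"]), "ACGTACGT")
  expect_equal(sum(strsplit(out[["y"]], "")[[1]] == "-"), 1L)

  score_of <- function(a, b) {
    ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
    s <- 0; run <- 0
    for (i in seq_along(ca)) {
      if (ca[i] == "-" || cb[i] == "-") {
        s <- s - (if (run == 0) 2 else 1); run <- run + 1
      } else {
        s <- s + (if (ca[i] == cb[i]) 1 else -1); run <- 0
      }
    }
    s
  }
  my_score <- score_of(out[["x"]], out[["y"]])
  oracle <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString("ACGTACGT"), Biostrings::DNAString("ACGACGT"),
    type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = TRUE),
    gapOpening = 1, gapExtension = 1)
  expect_equal(my_score, Biostrings::score(oracle))
})

test_that("removing gaps from any aligned row reproduces its input", {
  set.seed(42)
  seqs <- vapply(1:6, function(i) {
    n <- sample(40:60, 1)
    paste0(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
  }, character(1))
  names(seqs) <- paste0("sp", 1:6)
  aln <- align_coding_global(rec_tbl(seqs))
  expect_gte(alignment_ncol(aln), max(nchar(seqs)))
  for (sp in names(seqs)) {
    expect_equal(ungapped_row(aln, sp), seqs[[sp]])
  }
})

test_that("back-translation aligns in codons and detects reading frames", {
  base <- "ATGAAACCCGGGTTTATGAAACCCGGGTTTATGAAACCC"  # 13 codons, no stops
  same <- rec_tbl(c(a = base, b = base), "matK")
  aln <- align_backtranslate(same)
  expect_false(any(grepl("-", aln$seqs)))
  expect_equal(unname(attr(aln, "frame_offsets")), c(0L, 0L))
  expect_equal(alignment_ncol(aln) %% 3L, 0L)

  # one whole codon deleted -> exactly one 3-column gap block
  del <- paste0(substr(base, 1, 15), substr(base, 19, nchar(base)))
  aln2 <- align_backtranslate(rec_tbl(c(ref = base, del = del), "matK"))
  gaps <- gregexpr("-+", aln2$seqs[["del"]])[[1]]
  expect_equal(length(gaps), 1L)
  expect_equal(attr(gaps, "match.length"), 3L)

  # leading frame shift of one base -> offset 1 picked by stop counting
  # (frame 0 of the shifted read contains a TAA; frame 1 is stop-free)
  fs_base <- paste0("ATGAATAA", strrep("CCCGGG", 5))
  shifted <- paste0("G", fs_base)
  aln3 <- align_backtranslate(rec_tbl(c(ref = fs_base, shift = shifted), "matK"))
  expect_equal(attr(aln3, "frame_offsets")[["shift"]], 1L)
  expect_equal(ungapped_row(aln3, "shift"), shifted)
  expect_equal(alignment_ncol(aln3) %% 3L, 0L)
})

test_that("sequences with excess stops in every frame are excluded with a reason", {
  good <- "ATGAAACCCGGGTTTATGAAACCCGGGTTTATGAAACCC"
  stops <- strrep("TAAC", 15)  # ~25% stop codons in every reading frame
  expect_message(
    aln <- align_backtranslate(rec_tbl(c(g = good, g2 = good, bad = stops),
                                       "matK")),
    "bad")
  expect_false("bad" %in% aln$taxa)
  expect_equal(attr(aln, "excluded")$species_code, "bad")
})

test_that("spacer alignment partitions by rank and omits singleton groups", {
  tax <- as_community_taxonomy(data.frame(
    species = paste0("sp", 1:6),
    genus = paste0("g", 1:6),
    family = c("F1", "F1", "F1", "F2", "F3", "F3"),
    order = c("O1", "O1", "O1", "O1", "O2", "O2")))
  seqs <- setNames(vapply(1:6, function(i)
    paste0(sample(c("A", "C", "G", "T"), 50, TRUE), collapse = ""),
    character(1)), paste0("sp", 1:6))
  blocks <- align_partitioned(rec_tbl(seqs, "trnH-psbA"), tax, "family")
  expect_equal(length(blocks), 2L)  # F2 is a singleton -> omitted
  expect_equal(vapply(blocks, function(b) b$partition_label, character(1)),
               c("F1", "F3"))
  expect_equal(length(blocks[[1]]$taxa), 3L)
  expect_true(all(vapply(blocks, function(b) b$partitioned, logical(1))))

  # all singleton families -> empty list
  tax1 <- as_community_taxonomy(data.frame(
    species = paste0("sp", 1:3), genus = paste0("g", 1:3),
    family = paste0("f", 1:3), order = "O1"))
  expect_equal(length(align_partitioned(rec_tbl(seqs[1:3], "trnH-psbA"),
                                        tax1, "family")), 0L)
})
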