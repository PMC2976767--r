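two_block_fixture <- function() {
  sp10 <- paste0("sp", sprintf("%02d", 1:10))
  a <- new_alignment("rbcLa", "global",
                     setNames(rep(strrep("A", 100), 10), sp10))
  b <- new_alignment("matK", "global",
                     setNames(rep(strrep("C", 50), 4), sp10[1:4]))
  list(a = a, b = b, sp10 = sp10)
}

test_that("assembly concatenates blocks over the species union with ? fill", {
  fx <- two_block_fixture()
  sm <- assemble_supermatrix(list(fx$a, fx$b))
  expect_equal(dim(sm$matrix), c(10L, 150L))
  expect_equal(sm$partitions$label, c("rbcLa", "matK"))
  expect_equal(sm$partitions$start, c(0L, 100L))
  expect_equal(sm$partitions$end, c(100L, 150L))
  # six species lack the second block: 50 '?' columns each
  q <- rowSums(sm$matrix == "?")
  expect_equal(sort(unname(q)), c(rep(0, 4), rep(50, 6)))
  expect_equal(missing_fraction(sm), 300 / 1500)
})

test_that("a single global block passes through unchanged", {
  fx <- two_block_fixture()
  sm <- assemble_supermatrix(list(fx$a))
  expect_equal(dim(sm$matrix), c(10L, 100L))
  expect_equal(nrow(sm$partitions), 1L)
  expect_equal(missing_fraction(sm), 0)
})

test_that("species with only partitioned-spacer data are excluded", {
  fx <- two_block_fixture()
  spacer <- new_alignment("trnH-psbA", "F1",
                          setNames(rep(strrep("G", 30), 3),
                                   c("sp01", "sp02", "lonely")),
                          partitioned = TRUE)
  sm <- assemble_supermatrix(list(fx$a, spacer))
  expect_false("lonely" %in% sm$species)
  expect_equal(sm$excluded_species, "lonely")
  # but a spacer-only analysis keeps everyone
  sm2 <- assemble_supermatrix(list(spacer))
  expect_setequal(sm2$species, c("sp01", "sp02", "lonely"))
})

test_that("duplicate species within one block is an error", {
  dup <- new_alignment("rbcLa", "global", c(x = "AAAA", y = "AAAA"))
  dup$taxa <- c("x", "x")
  names(dup$seqs) <- c("x", "x")
  expect_error(assemble_supermatrix(list(dup)), "duplicate")
})

test_that("missing fraction is permutation invariant and bounded below", {
  fx <- two_block_fixture()
  sm <- assemble_supermatrix(list(fx$a, fx$b))
  perm <- sample(nrow(sm$matrix))
  sm2 <- sm
  sm2$matrix <- sm$matrix[perm, sample(ncol(sm$matrix)), drop = FALSE]
  sm2$species <- sm$species[perm]
  expect_equal(missing_fraction(sm2), missing_fraction(sm))

  allq <- sm
  allq$matrix[1, ] <- "?"
  expect_gte(missing_fraction(allq), 1 / nrow(allq$matrix))
})

test_that("NEXUS export writes 1-based inclusive charsets and round-trips", {
  fx <- two_block_fixture()
  sm <- assemble_supermatrix(list(fx$a, fx$b))
  f <- tempfile(fileext = ".nex")
  write_supermatrix(sm, f, "nexus")
  lines <- readLines(f)
  expect_true(any(grepl("CHARSET rbcLa = 1-100;", lines)))
  expect_true(any(grepl("CHARSET matK = 101-150;", lines)))
  back <- read_supermatrix(f, "nexus")
  expect_equal(back$matrix, sm$matrix)
  expect_equal(back$species, sm$species)
  expect_equal(back$partitions$start, sm$partitions$start)
  expect_equal(back$partitions$end, sm$partitions$end)
  # byte-identical serialization
  f2 <- tempfile()
  write_supermatrix(sm, f2, "nexus")
  expect_identical(readLines(f), readLines(f2))
})

test_that("PHYLIP and CSV exports round-trip the character matrix", {
  fx <- two_block_fixture()
  sm <- assemble_supermatrix(list(fx$a, fx$b))
  for (fmt in c("phylip", "csv")) {
    f <- tempfile()
    write_supermatrix(sm, f, fmt)
    back <- read_supermatrix(f, fmt)
    expect_equal(back$matrix, sm$matrix)
  }
  expect_error(write_supermatrix(sm, tempfile(), "nexml"))
})
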