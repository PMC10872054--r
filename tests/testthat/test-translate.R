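test_that("normalization maps non-standard codes and rejects everything else", {
  expect_identical(normalize_sequence("UOX"), "CKX")
  expect_identical(normalize_sequence("ABZ"), "AXX")
  expect_identical(normalize_sequence("ACDEFG"), "ACDEFG")
  expect_identical(normalize_sequence(" acd\nefg "), "ACDEFG")
  expect_error(normalize_sequence("AC1D"), class = "redalph_parse_error",
               regexp = "'1' at position 3")
  expect_error(normalize_sequence("AJD"), class = "redalph_parse_error",
               regexp = "'J' at position 2")
  expect_error(normalize_sequence("  "), class = "redalph_validation_error")
})

test_that("tokenization assigns 0-based cluster indices", {
  expect_identical(tokenize("ALMS", "MMSEQS12"), c(0L, 1L, 1L, 0L))
  expect_identical(tokenize(strrep("X", 5), "GBMR4"), rep(4L, 5L))
  # full alphabet: bijective letter <-> index encoding
  s <- paste(redalph:::AA_STANDARD, collapse = "")
  expect_identical(tokenize(s, "UNIPROT20"), 0:19)
  long <- tokenize_records(tibble::tibble(id = "a", seq = "ALMS"), "MMSEQS12")
  expect_identical(long$cluster_index, c(0L, 1L, 1L, 0L))
  expect_identical(long$position, 1:4)
})

test_that("representative translation follows the scheme and preserves clusters", {
  expect_identical(to_representative_sequence("LM", "MMSEQS12"), "LL")
  s <- "ARNDCQEGHILKMFPSTWYVX"
  expect_identical(to_representative_sequence(s, "UNIPROT20"), s)
  # idempotence and cluster preservation across alphabets
  withr::local_seed(42)
  for (ab in builtin_alphabets()) {
    for (rep_ in 1:5) {
      x <- random_standard_seq(30)
      tr <- to_representative_sequence(x, ab)
      expect_identical(nchar(tr), nchar(x))
      expect_identical(to_representative_sequence(tr, ab), tr)
      expect_identical(tokenize(tr, ab), tokenize(x, ab))
    }
  }
})

test_that("random representative schemes are reproducible and stay within clusters", {
  ab <- builtin_alphabets()$MMSEQS12
  s1 <- representative_scheme(ab, "seeded_random", seed = 9)
  s2 <- representative_scheme(ab, "seeded_random", seed = 9)
  expect_identical(s1$assignment, s2$assignment)
  for (k in seq_along(ab$clusters)) {
    expect_true(s1$assignment[k] %in% ab$clusters[[k]])
  }
  expect_error(
    representative_scheme(ab, "explicit",
                          assignment = c("A", rep("C", 11))),
    class = "redalph_validation_error"
  )
  # per-position mode keeps cluster identity at each site
  x <- random_standard_seq(50)
  sch <- representative_scheme(ab, "per_position_random", seed = 3)
  tr <- to_representative_sequence(x, ab, sch)
  expect_identical(tokenize(tr, ab), tokenize(x, ab))
  expect_identical(to_representative_sequence(x, ab, sch), tr)
})

test_that("representative assignments enumerate the per-cluster Cartesian product", {
  e20 <- enumerate_representative_assignments("UNIPROT20")
  expect_identical(nrow(e20), 1L)
  expect_identical(attr(e20, "total_assignments"), 1)

  # one two-member cluster, the rest singletons: exactly two assignments
  ab <- parse_alphabet("TOY19", "AR N D C Q E G H I L K M F P S T W Y V")
  e <- enumerate_representative_assignments(ab)
  expect_identical(nrow(e), 2L)
  expect_identical(attr(e, "total_assignments"), 2)
  expect_identical(e$representatives[[1]][1], "A")
  expect_identical(e$representatives[[2]][1], "R")
  expect_identical(e$representatives[[1]][-1], e$representatives[[2]][-1])

  g4 <- enumerate_representative_assignments("GBMR4", cap = 10)
  expect_identical(attr(g4, "total_assignments"), 9 * 9 * 1 * 1)
  expect_identical(nrow(g4), 10L)
  # lexicographic: last cluster fastest; first rows vary the final
  # multi-member cluster (cluster 2, YFLIVMCWH)
  expect_identical(g4$representatives[[1]], c("A", "Y", "G", "P"))
  expect_identical(g4$representatives[[2]], c("A", "F", "G", "P"))
})

test_that("identity and similarity follow the positionwise BLOSUM62 rule", {
  self <- identity_and_similarity("ACDEFGHIKL", "ACDEFGHIKL")
  expect_equal(self$identity, 100)
  expect_equal(self$similarity, 100)
  lm <- identity_and_similarity("LL", "MM")
  expect_equal(lm$identity, 0)
  expect_equal(lm$similarity, 100)
  gp <- identity_and_similarity("GG", "PP")
  expect_equal(gp$identity, 0)
  expect_equal(gp$similarity, 0)
  expect_error(identity_and_similarity("AA", "AAA"),
               class = "redalph_validation_error")
  # identity <= similarity on standard-letter sequences
  withr::local_seed(1)
  for (i in 1:20) {
    x <- random_standard_seq(40)
    y <- to_representative_sequence(x, "WWMJ5")
    r <- identity_and_similarity(x, y)
    expect_gte(r$similarity, r$identity)
  }
})

test_that("the bundled BLOSUM62 matches the Biostrings reference on standard residues", {
  # distributions differ in their B/Z/X ambiguity-row conventions, so the
  # cross-check is over the 20 standard letters, where the matrix is unique
  m <- blosum62()
  ref <- local({
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62
  })
  std <- redalph:::AA_STANDARD
  expect_identical(m[std, std], ref[std, std])
  expect_identical(dim(m), c(24L, 24L))
  expect_true(all(diag(m[std, std]) > 0))
})

test_that("translation fidelity table covers alphabets and is 100/100 on the full alphabet", {
  recs <- tibble::tibble(id = c("a", "b"),
                         seq = c("ACDEFGHIKLMNPQRSTVWY", "LLLLMMMM"))
  tab <- translation_fidelity(recs, c("UNIPROT20", "MMSEQS12"))
  expect_identical(nrow(tab), 4L)
  u20 <- dplyr::filter(tab, alphabet == "UNIPROT20")
  expect_true(all(u20$identity == 100 & u20$similarity == 100))
})

test_that("FASTA round trips through Biostrings wrappers", {
  recs <- tibble::tibble(id = c("s1", "s2"),
                         seq = c(strrep("ACDEFGHIKL", 9), "MNPQRSTVWY"))
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(recs, path)
  back <- read_fasta(path)
  expect_equal(as.data.frame(back), as.data.frame(recs))
  # 60-column wrapping
  expect_true(all(nchar(readLines(path)) <= 60))
})
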