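test_that("substitutions are extracted per mismatching position", {
  subs <- extract_substitutions("ACD", c("AVD", "ACD", "VCE"))
  expect_identical(nrow(subs), 3L)
  expect_identical(subs$position, c(2L, 1L, 3L))
  expect_identical(subs$wt_residue, c("C", "A", "D"))
  expect_identical(subs$variant_residue, c("V", "V", "E"))
  expect_identical(attr(subs, "skipped"), 0L)

  withx <- extract_substitutions("AXD", c("AVD", "GXD"))
  expect_identical(nrow(withx), 1L) # X-containing mismatch skipped
  expect_identical(attr(withx, "skipped"), 1L)

  expect_error(extract_substitutions("ACD", c(bad = "ACDE")),
               class = "redalph_validation_error")
})

test_that("distinguishability reflects cluster membership", {
  expect_false(is_distinguishable("L", "V", "GBMR4"))
  expect_true(is_distinguishable("G", "P", "GBMR4"))
  # the full alphabet distinguishes every pair
  pairs <- expand.grid(a = redalph:::AA_STANDARD, b = redalph:::AA_STANDARD,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$a != pairs$b, ]
  expect_true(all(is_distinguishable(pairs$a, pairs$b, "UNIPROT20")))
  expect_false(any(is_distinguishable(pairs$a, pairs$b,
                                      single_cluster_alphabet())))
})

test_that("error rates hit the analytic extremes and the GBMR4 midpoint", {
  two <- tibble::tibble(wt_residue = c("L", "G"),
                        variant_residue = c("V", "P"))
  expect_equal(error_rate(two, "GBMR4")$error_rate_percent, 50)
  expect_equal(error_rate(two, "UNIPROT20")$error_rate_percent, 0)
  expect_equal(error_rate(two, single_cluster_alphabet())$error_rate_percent,
               100)
  expect_error(error_rate(two[0, ], "GBMR4"),
               class = "redalph_validation_error")
})

test_that("error rate is order-invariant and supports unique-pair weighting", {
  withr::local_seed(5)
  vs <- generate_variant_set(wild_type_length = 60, n_variants = 80,
                             n_substitutions = 2, seed = 5)
  subs <- extract_substitutions(vs$wild_type, vs$variants)
  r1 <- error_rate(subs, "WWMJ5")
  r2 <- error_rate(subs[sample.int(nrow(subs)), ], "WWMJ5")
  expect_equal(r1$error_rate_percent, r2$error_rate_percent)
  ru <- error_rate(subs, "WWMJ5", unique_pairs = TRUE)
  expect_lte(ru$n_pairs, r1$n_pairs)
  tab <- error_rate_table(subs)
  expect_identical(nrow(tab), 9L)
  expect_equal(tab$error_rate_percent[tab$alphabet == "UNIPROT20"], 0)
})

test_that("merging clusters never decreases the error rate", {
  withr::local_seed(17)
  vs <- generate_variant_set(wild_type_length = 80, n_variants = 60,
                             n_substitutions = 1, seed = 17)
  subs <- extract_substitutions(vs$wild_type, vs$variants)
  for (trial in 1:25) {
    ab <- builtin_alphabets()[[sample(9, 1)]]
    k <- cluster_count(ab)
    if (k < 2) next
    pick <- sort(sample.int(k, 2))
    merged <- ab$clusters
    merged[[pick[1]]] <- c(merged[[pick[1]]], merged[[pick[2]]])
    merged <- merged[-pick[2]]
    ab2 <- parse_alphabet(
      "MERGED0",
      paste(vapply(merged, paste, "", collapse = ""), collapse = " ")
    ) |> suppressWarnings()
    expect_gte(error_rate(subs, ab2)$error_rate_percent,
               error_rate(subs, ab)$error_rate_percent)
  }
})
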