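test_that("ca_trace validates identifiers and coordinates", {
  expect_error(
    ca_trace(tibble::tibble(resno = c(1, 1), x = 0, y = 0, z = 0)),
    class = "redalph_validation_error", regexp = "duplicate"
  )
  expect_error(
    ca_trace(tibble::tibble(resno = 1, x = NA_real_, y = 0, z = 0)),
    class = "redalph_validation_error", regexp = "finite"
  )
  # same number, different insertion codes, is fine
  tr <- ca_trace(tibble::tibble(resno = c(1, 1), ins = c("", "A"),
                                x = c(0, 1), y = 0, z = 0))
  expect_identical(nrow(tr$residues), 2L)
})

test_that("PDB round trip preserves coordinates and numbering", {
  h <- ideal_helix(12)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_ca_pdb(h, path)
  back <- read_ca_trace(path, chain = "A")
  expect_identical(back$residues$resno, h$residues$resno)
  expect_equal(back$residues$x, h$residues$x, tolerance = 1e-3)
  expect_equal(back$residues$z, h$residues$z, tolerance = 1e-3)
  expect_error(read_ca_trace(path, chain = "B"),
               class = "redalph_validation_error")
})

test_that("altloc pairs resolve by occupancy and CA-less residues are counted", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1       9.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CA  ALA A   2       3.800   0.000   0.000  1.00  0.00           C",
    "ATOM      4  N   ALA A   3       5.000   1.000   0.000  1.00  0.00           N",
    "ATOM      5  CA  ALA A   4       7.600   0.000   0.000  1.00  0.00           C",
    "END"
  ), path)
  expect_message(tr <- read_ca_trace(path, chain = "A"),
                 regexp = "1 residue")
  expect_identical(tr$residues$resno, c(1L, 2L, 4L))
  expect_equal(tr$residues$x[1], 9) # higher-occupancy altloc B
  expect_identical(attr(tr, "n_skipped"), 1L)
})

test_that("domain parsing and cropping use inclusive author numbering", {
  tr <- ideal_helix(100)
  cropped <- crop_to_domain(tr, "A:10-20")
  expect_identical(nrow(cropped$residues), 11L)
  expect_identical(range(cropped$residues$resno), c(10L, 20L))

  full <- crop_to_domain(tr, domain_range("A", cbind(1, 100)))
  expect_identical(full$residues, tr$residues)

  two <- crop_to_domain(tr, "A:1-5,90-95")
  expect_identical(nrow(two$residues), 11L)
  expect_identical(two$residues$resno, c(1:5, 90:95))

  expect_error(crop_to_domain(tr, "A:200-300"),
               class = "redalph_validation_error", regexp = "\\[200,300\\]")
  expect_error(crop_to_domain(tr, "B:10-20"),
               class = "redalph_validation_error", regexp = "chain")
  expect_error(parse_domain_range("A10-20"), class = "redalph_parse_error")
  expect_error(domain_range("A", rbind(c(1, 10), c(5, 20))),
               class = "redalph_validation_error", regexp = "overlap")
})

test_that("identity and rigid transforms score exactly 100", {
  h <- ideal_helix(20)
  res <- lddt_ca(h, h)
  expect_equal(res$global, 100)
  expect_equal(res$per_residue$score, rep(100, 20))

  rigid <- generate_structure_pair(structure_spec(n_residues = 20,
                                                  noise_sd = 0,
                                                  rigid_transform = TRUE,
                                                  seed = 31))
  expect_equal(lddt_ca(rigid$reference, rigid$model)$global, 100,
               tolerance = 1e-9)
})

test_that("lddt_ca agrees bit for bit with the brute-force oracle", {
  withr::local_seed(14)
  for (trial in 1:50) {
    n <- sample(4:20, 1)
    pair <- generate_structure_pair(structure_spec(
      n_residues = n, noise_sd = stats::runif(1, 0, 2), seed = trial
    ))
    model <- pair$model
    # occasionally drop residues from the model to exercise missing pairs
    if (trial %% 5 == 0) {
      keep <- sort(sample(n, max(2, n - 3)))
      model$residues <- model$residues[keep, , drop = FALSE]
    }
    got <- lddt_ca(pair$reference, model)
    expect_identical(got$global, lddt_oracle(pair$reference, model))
    expect_true(all(got$per_residue$score >= 0 &
                    got$per_residue$score <= 100, na.rm = TRUE))
  }
})

test_that("growing coordinate noise degrades the mean score monotonically", {
  grid <- c(0.1, 0.5, 2.0)
  means <- vapply(grid, function(sd) {
    mean(vapply(1:20, function(r) {
      pair <- generate_structure_pair(structure_spec(
        n_residues = 25, noise_sd = sd, seed = 1000 + r
      ))
      lddt_ca(pair$reference, pair$model)$global
    }, 0))
  }, 0)
  expect_true(all(diff(means) < 0))
})

test_that("alphabet prediction comparison reports deltas against the baseline", {
  ref <- ideal_helix(25)
  noisy <- function(sd, seed) {
    generate_structure_pair(structure_spec(n_residues = 25, noise_sd = sd,
                                           seed = seed))$model
  }
  preds <- list(
    UNIPROT20 = noisy(0.8, 1),
    SDM12 = ref,           # perfect prediction: should be flagged
    GBMR4 = noisy(2.5, 2)
  )
  tab <- compare_alphabet_predictions(ref, preds)
  expect_identical(tab$delta[tab$alphabet == "UNIPROT20"], 0)
  expect_true(tab$improved[tab$alphabet == "SDM12"])
  expect_lt(tab$delta[tab$alphabet == "GBMR4"], 0)
  expect_identical(attr(tab, "best")$alphabet, "SDM12")

  same <- compare_alphabet_predictions(ref, list(UNIPROT20 = preds$UNIPROT20,
                                                 HSDM17 = preds$UNIPROT20))
  expect_equal(same$delta, c(0, 0))
  expect_error(compare_alphabet_predictions(ref, list(SDM12 = ref)),
               class = "redalph_validation_error", regexp = "baseline")
})

test_that("lddt tidiers expose the per-residue profile and the summary", {
  pair <- generate_structure_pair(structure_spec(n_residues = 15,
                                                 noise_sd = 0.5, seed = 2))
  res <- lddt_ca(pair$reference, pair$model)
  expect_identical(nrow(tidy(res)), 15L)
  g <- glance(res)
  expect_identical(g$n_reference, 15L)
  expect_equal(g$lddt_ca, res$global)
})
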