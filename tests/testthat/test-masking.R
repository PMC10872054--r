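uniform_bg <- function(v) c(rep(1 / (v - 1), v - 1), 0)

test_that("background distributions are empirical frequencies with zero unknown mass", {
  # single-token corpus on a 2+unknown vocabulary
  p <- build_background_distribution(list(rep(0L, 10)), 3L, smooth = 0)
  expect_equal(p, c(1, 0, 0))
  p2 <- build_background_distribution(list(c(0L, 1L), c(1L, 0L)), 3L,
                                      smooth = 0)
  expect_equal(p2, c(0.5, 0.5, 0))
  # unknown tokens are dropped from the mass
  p3 <- build_background_distribution(list(c(0L, 1L, 2L, 2L)), 3L,
                                      smooth = 0)
  expect_equal(p3, c(0.5, 0.5, 0))
  expect_error(build_background_distribution(list(c(2L, 2L)), 3L),
               class = "redalph_validation_error")
  # large uniform draw is near-uniform within Monte-Carlo error
  withr::local_seed(8)
  corpus <- replicate(200, sample(0L:19L, 100, replace = TRUE),
                      simplify = FALSE)
  p4 <- build_background_distribution(corpus, 21L)
  expect_true(all(abs(p4[1:20] - 0.05) < 0.005))
  expect_identical(p4[21], 0)
})

test_that("masking selects at the configured rate and never self-replaces", {
  cfg <- masking_config(uniform_bg(21L), seed = 123)
  batch <- replicate(200, sample(0L:19L, 500, replace = TRUE),
                     simplify = FALSE)
  cor <- apply_masking(batch, cfg)
  n_pos <- sum(lengths(batch))
  frac <- sum(unlist(cor$mask)) / n_pos
  se <- sqrt(0.1 * 0.9 / n_pos)
  expect_lt(abs(frac - 0.1), 3 * se)
  # no corrupted token equals its original at masked positions
  for (i in seq_along(batch)) {
    sel <- cor$mask[[i]]
    expect_false(any(cor$corrupted[[i]][sel] == batch[[i]][sel]))
    expect_identical(cor$targets[[i]][sel], batch[[i]][sel])
    expect_true(all(is.na(cor$targets[[i]][!sel])))
    expect_identical(cor$corrupted[[i]][!sel], batch[[i]][!sel])
  }
})

test_that("unknown positions are never selected and exact-count mode hits floor(pL)", {
  cfg <- masking_config(uniform_bg(4L), mask_probability = 0.5, seed = 1)
  batch <- list(rep(3L, 50), c(rep(0L, 25), rep(3L, 25)))
  cor <- apply_masking(batch, cfg)
  expect_false(any(cor$mask[[1]]))
  expect_false(any(cor$mask[[2]][26:50]))

  cfg_ex <- masking_config(uniform_bg(21L), mask_probability = 0.1,
                           exact_count = TRUE, seed = 2)
  batch2 <- replicate(20, sample(0L:19L, 57, replace = TRUE),
                      simplify = FALSE)
  cor2 <- apply_masking(batch2, cfg_ex)
  expect_true(all(vapply(cor2$mask, sum, 0L) == floor(0.1 * 57)))
})

test_that("a fixed seed reproduces the documented draw order exactly", {
  cfg <- masking_config(uniform_bg(8L), mask_probability = 0.2, seed = 77)
  batch <- replicate(10, sample(0L:6L, 40, replace = TRUE), simplify = FALSE)
  cor <- apply_masking(batch, cfg)
  oracle <- masking_oracle(batch, cfg)
  for (i in seq_along(batch)) {
    expect_identical(cor$mask[[i]], oracle[[i]]$mask)
    expect_identical(cor$corrupted[[i]], oracle[[i]]$corrupted)
  }
  # replay is also self-consistent
  expect_identical(apply_masking(batch, cfg), cor)
})

test_that("masking configs validate their distribution", {
  expect_error(masking_config(c(0.5, 0.5, 0.1)),
               class = "redalph_validation_error", regexp = "sum to 1")
  expect_error(masking_config(c(0.5, 0, 0.5, 0)),
               class = "redalph_validation_error", regexp = "support")
  expect_error(masking_config(c(0.5, 0.3, 0.2)),
               class = "redalph_validation_error", regexp = "unknown")
})
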