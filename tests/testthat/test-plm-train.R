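# Desk-scale behaviour of the training loop itself; the full study-scale
# training check lives in the acceptance suite.

small_corpus <- function(n = 80, seed = 21) {
  corpus <- generate_corpus(corpus_spec(
    n_sequences = n, length_min = 15, length_max = 20,
    motif = "CWHPDK", seed = seed
  ))
  lapply(corpus$seq, tokenize, alphabet = "UNIPROT20")
}

tiny_cfg <- function() {
  lm_config(21L, embedding_dim = 8L, hidden_dim = 8L, num_layers = 2L)
}

test_that("identical seeds give identical loss traces and snapshots", {
  toks <- small_corpus()
  tc <- desk_train_config(max_steps = 25L, checkpoint_every = 10L, seed = 99)
  m1 <- train_masked_lm(toks, tiny_cfg(), train_cfg = tc, quiet = TRUE)
  m2 <- train_masked_lm(toks, tiny_cfg(), train_cfg = tc, quiet = TRUE)
  expect_identical(m1$log, m2$log)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$snapshots, m2$snapshots)
  # and a different seed gives a different trajectory
  tc2 <- desk_train_config(max_steps = 25L, checkpoint_every = 10L,
                           seed = 100)
  m3 <- train_masked_lm(toks, tiny_cfg(), train_cfg = tc2, quiet = TRUE)
  expect_false(identical(m1$log$loss, m3$log$loss))
})

test_that("an untrained model scores near the uniform limit and training reduces loss", {
  toks <- small_corpus(n = 120, seed = 31)
  tc <- desk_train_config(max_steps = 120L, checkpoint_every = 60L,
                          seed = 31)
  m <- train_masked_lm(toks, tiny_cfg(), train_cfg = tc, quiet = TRUE)
  ppl0 <- m$log$val_perplexity[1] # evaluated before any update
  expect_equal(ppl0, 21, tolerance = 0.15)
  final <- utils::tail(stats::na.omit(m$log$val_perplexity), 1)
  expect_lt(final, ppl0)
  # log bookkeeping
  expect_identical(nrow(m$log), 121L)
  expect_equal(m$log$lr[2], scheduled_lr(tc, 1L))
  expect_identical(
    vapply(m$snapshots, function(s) s$step, 0L),
    c(0L, 60L, 120L)
  )
})

test_that("a zero-entropy language drives held-out perplexity toward 1", {
  one <- tokenize(strrep("A", 18), "UNIPROT20")
  toks <- replicate(60, one, simplify = FALSE)
  tc <- desk_train_config(max_steps = 150L, checkpoint_every = 150L,
                          learning_rate = 5e-3, seed = 13)
  m <- train_masked_lm(toks, tiny_cfg(), train_cfg = tc, quiet = TRUE)
  final <- utils::tail(stats::na.omit(m$log$val_perplexity), 1)
  expect_lt(final, 1.6)
})

test_that("training accepts sequence tibbles and records vocabulary-sized outputs", {
  corpus <- generate_corpus(corpus_spec(n_sequences = 40, length_min = 12,
                                        length_max = 15, motif = NULL,
                                        seed = 41))
  m <- train_masked_lm(
    corpus, lm_config(13L, embedding_dim = 8L, hidden_dim = 8L,
                      num_layers = 1L),
    train_cfg = desk_train_config(max_steps = 10L, checkpoint_every = 5L,
                                  seed = 1),
    alphabet = "MMSEQS12", quiet = TRUE
  )
  expect_identical(m$config$vocab_size, 13L)
  pr <- token_probs(m, list(tokenize("ALMSX", "MMSEQS12")))
  expect_identical(ncol(pr[[1]]), 13L)
  expect_equal(rowSums(pr[[1]]), rep(1, 5), tolerance = 1e-9)
})
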