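# Shared fixtures and independent oracles used across test files.

single_cluster_alphabet <- function() {
  parse_alphabet("ONE1",
                 "ARNDCQEGHILKMFPSTWYV")
}

random_standard_seq <- function(n) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
               n, replace = TRUE), collapse = "")
}

# Brute-force LDDT-Calpha oracle: explicit loops over residue pairs and
# thresholds, no vectorization shared with the implementation.
lddt_oracle <- function(reference, model, params = lddt_params()) {
  rr <- reference$residues
  mr <- model$residues
  key <- function(df) paste0(df$resno, df$ins)
  mpos <- match(key(rr), key(mr))
  n <- nrow(rr)
  th <- params$thresholds
  preserved <- 0
  total <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dref <- sqrt(sum((c(rr$x[i], rr$y[i], rr$z[i]) -
                        c(rr$x[j], rr$y[j], rr$z[j]))^2))
      if (dref >= params$inclusion_radius) next
      total <- total + 1
      if (is.na(mpos[i]) || is.na(mpos[j])) next
      a <- mpos[i]
      b <- mpos[j]
      dmod <- sqrt(sum((c(mr$x[a], mr$y[a], mr$z[a]) -
                        c(mr$x[b], mr$y[b], mr$z[b]))^2))
      for (t in th) {
        if (abs(dref - dmod) < t) preserved <- preserved + 1
      }
    }
  }
  100 * preserved / (length(th) * total)
}

# Independent replay of the documented masking draw order: one runif per
# position of each sequence in input order, then one categorical draw
# (sample.int with the renormalized background) per selected position.
masking_oracle <- function(batch, cfg) {
  v <- length(cfg$background)
  unk <- v - 1L
  seed <- redalph:::substream_seed(cfg$seed, "masking")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  out <- vector("list", length(batch))
  for (s in seq_along(batch)) {
    x <- batch[[s]]
    u <- runif(length(x))
    sel <- (x != unk) & u < cfg$mask_probability
    y <- x
    for (p in which(sel)) {
      bg <- cfg$background
      if (cfg$exclude_original) bg[x[p] + 1L] <- 0
      y[p] <- sample.int(v, 1L, prob = bg) - 1L
    }
    out[[s]] <- list(corrupted = y, mask = sel)
  }
  out
}

# Small cached trained model so scoring/PCA tests don't retrain each time.
tiny_model_env <- new.env()
tiny_trained_model <- function() {
  if (is.null(tiny_model_env$model)) {
    corpus <- generate_corpus(corpus_spec(
      n_sequences = 200L, length_min = 15L, length_max = 25L,
      motif = "CWHPDK", seed = 7L
    ))
    toks <- lapply(corpus$seq, tokenize, alphabet = "UNIPROT20")
    tiny_model_env$model <- train_masked_lm(
      toks,
      lm_config(21L, embedding_dim = 12L, hidden_dim = 12L,
                num_layers = 2L),
      train_cfg = desk_train_config(max_steps = 40L,
                                    checkpoint_every = 20L, seed = 7L),
      quiet = TRUE
    )
  }
  tiny_model_env$model
}
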