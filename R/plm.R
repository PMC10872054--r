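#' Masked language model configuration
#'
#' Encoder shape for the bidirectional-LSTM masked language model. The
#' `desk` preset (embedding 32, hidden 64 per direction, 3 layers) trains
#' in minutes on one CPU; the `paper` preset (embedding 512, hidden 512
#' per direction, 3 layers) matches the scale of a ~14M-parameter
#' pretraining run — the realized parameter count is printed when
#' training starts. Token convention throughout: 0-based token ids
#' `0..vocab_size-1`, with the unknown token always the highest id.
#'
#' @param vocab_size Token vocabulary size (cluster count + 1 unknown).
#' @param preset `"desk"` or `"paper"`; sets the dimension defaults.
#' @param embedding_dim,hidden_dim,num_layers,bidirectional Override the
#'   preset's architecture.
#' @return An `lm_config` object.
#' @export
lm_config <- function(vocab_size, preset = c("desk", "paper"),
                      embedding_dim = NULL, hidden_dim = NULL,
                      num_layers = 3L, bidirectional = TRUE) {
  preset <- match.arg(preset)
  stopifnot(vocab_size >= 2L, num_layers >= 1L)
  dims <- switch(preset,
    desk = list(embedding_dim = 32L, hidden_dim = 64L),
    paper = list(embedding_dim = 512L, hidden_dim = 512L)
  )
  structure(
    list(vocab_size = as.integer(vocab_size),
         embedding_dim = as.integer(embedding_dim %||% dims$embedding_dim),
         hidden_dim = as.integer(hidden_dim %||% dims$hidden_dim),
         num_layers = as.integer(num_layers),
         bidirectional = isTRUE(bidirectional),
         preset = preset),
    class = "lm_config"
  )
}

#' Masking (corruption) configuration
#'
#' The corruption scheme has no designated mask token: each non-unknown
#' position is independently selected with `mask_probability` (default
#' 10%) and the selected tokens are replaced by draws from a background
#' token distribution — by default excluding the original token, reading
#' "substitute the masked residues with tokens from other residues"
#' literally. Unknown-token positions are never selected.
#'
#' @param background Probability vector over the token vocabulary
#'   (0-based token i at element i+1). Must sum to 1; the unknown (last)
#'   token must carry zero mass. See [build_background_distribution()].
#' @param mask_probability Per-position selection probability in (0, 1).
#' @param exclude_original Renormalize the background to exclude the
#'   original token at each masked position.
#' @param exact_count Select exactly `floor(mask_probability * n_eligible)`
#'   positions per sequence instead of Bernoulli sampling.
#' @param seed Integer seed for the masking stream.
#' @return A `masking_config` object.
#' @export
masking_config <- function(background, mask_probability = 0.10,
                           exclude_original = TRUE, exact_count = FALSE,
                           seed = 1L) {
  stopifnot(mask_probability > 0, mask_probability < 1)
  v <- length(background)
  stopifnot(v >= 2L)
  if (abs(sum(background) - 1) > 1e-8) {
    abort_redalph("background distribution must sum to 1",
                  "redalph_validation_error")
  }
  if (background[v] != 0) {
    abort_redalph("background mass on the unknown (last) token must be 0",
                  "redalph_validation_error")
  }
  if (any(background[-v] < 0) || any(background[-v] == 0)) {
    abort_redalph("background support must cover all non-unknown tokens",
                  "redalph_validation_error")
  }
  structure(
    list(background = as.numeric(background),
         mask_probability = mask_probability,
         exclude_original = isTRUE(exclude_original),
         exact_count = isTRUE(exact_count),
         seed = as.integer(seed)),
    class = "masking_config"
  )
}

#' Training configuration
#'
#' The pretraining recipe: Adam with library-default moments, a learning
#' rate decaying linearly to a tenth of its initial value at `max_steps`,
#' and cross-entropy on the masked positions only. The default rate 2e-4
#' matches the full pretraining recipe; [desk_train_config()] is the
#' package's short-schedule preset.
#'
#' @param learning_rate Initial Adam learning rate.
#' @param batch_size Sequences per step.
#' @param max_steps Total optimization steps.
#' @param checkpoint_every Steps between embedding snapshots and held-out
#'   perplexity evaluations.
#' @param val_fraction Fraction of the corpus held out for validation.
#' @param l2_weight_decay Optional literal L2 weight decay (default 0; the
#'   "decay" of the recipe is read as the learning-rate schedule).
#' @param seed Run seed; all random sub-streams (init, shuffling, masking
#'   draws, validation split) derive from it.
#' @return A `train_config` object.
#' @export
train_config <- function(learning_rate = 2e-4, batch_size = 16L,
                         max_steps = 2000L, checkpoint_every = 200L,
                         val_fraction = 0.1, l2_weight_decay = 0,
                         seed = 1L) {
  stopifnot(learning_rate > 0, batch_size >= 1L, max_steps >= 1L,
            checkpoint_every >= 1L, val_fraction > 0, val_fraction < 1)
  structure(
    list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
         max_steps = as.integer(max_steps),
         checkpoint_every = as.integer(checkpoint_every),
         val_fraction = val_fraction, l2_weight_decay = l2_weight_decay,
         seed = as.integer(seed)),
    class = "train_config"
  )
}

#' @rdname train_config
#' @param ... Overrides passed to [train_config()].
#' @export
desk_train_config <- function(...) {
  args <- list(...)
  defaults <- list(learning_rate = 1e-3, batch_size = 16L,
                   max_steps = 2000L, checkpoint_every = 200L)
  do.call(train_config, utils::modifyList(defaults, args))
}

#' Scheduled learning rate
#'
#' Linear decay from `learning_rate` at step 0 to `learning_rate / 10` at
#' `max_steps`.
#'
#' @param cfg A [train_config()].
#' @param step Step number (vectorized).
#' @return Learning rate(s).
#' @export
scheduled_lr <- function(cfg, step) {
  cfg$learning_rate * (1 - 0.9 * pmin(step, cfg$max_steps) / cfg$max_steps)
}

#' Empirical background token distribution
#'
#' Token frequencies over a corpus, normalized to 1, with the unknown
#' (highest) token's mass forced to 0 and the remainder renormalized —
#' replacement draws should never introduce unknowns.
#'
#' @param corpus List of 0-based integer token vectors.
#' @param vocab_size Vocabulary size.
#' @param smooth Additive pseudocount applied to non-unknown tokens so the
#'   support always covers the vocabulary (default 0.5).
#' @return Numeric probability vector of length `vocab_size`.
#' @export
build_background_distribution <- function(corpus, vocab_size, smooth = 0.5) {
  stopifnot(length(corpus) > 0L)
  all_tok <- unlist(corpus)
  stopifnot(all(all_tok >= 0L), all(all_tok < vocab_size))
  unk <- vocab_size - 1L
  counts <- tabulate(all_tok + 1L, nbins = vocab_size)
  if (sum(counts[-vocab_size]) == 0L) {
    abort_redalph("corpus contains only unknown tokens",
                  "redalph_validation_error")
  }
  counts[vocab_size] <- 0
  p <- counts + c(rep(smooth, vocab_size - 1L), 0)
  p / sum(p)
}

#' Apply the masking corruption scheme to a batch
#'
#' Each non-unknown position is selected independently with
#' `mask_probability` (or exactly `floor(p * n)` positions with
#' `exact_count`); selected tokens are replaced by a draw from the
#' background distribution, renormalized to exclude the original token
#' when `exclude_original` is on. The draw order is fixed and documented:
#' sequences in input order; per sequence one `runif` per position (or one
#' `sample.int` for exact counts), then one categorical draw per selected
#' position in position order — so a replay with the same seed and
#' generator reproduces the corruption exactly.
#'
#' @param batch List of 0-based integer token vectors.
#' @param cfg A [masking_config()].
#' @return A list with `corrupted` (list of token vectors), `mask` (list
#'   of logical vectors) and `targets` (list of integer vectors holding
#'   the original token at masked positions, `NA` elsewhere).
#' @export
apply_masking <- function(batch, cfg) {
  stopifnot(inherits(cfg, "masking_config"))
  v <- length(cfg$background)
  unk <- v - 1L
  with_seed(substream_seed(cfg$seed, "masking"), {
    corrupted <- vector("list", length(batch))
    mask <- vector("list", length(batch))
    targets <- vector("list", length(batch))
    for (s in seq_along(batch)) {
      x <- batch[[s]]
      eligible <- x != unk
      sel <- logical(length(x))
      if (cfg$exact_count) {
        n_el <- sum(eligible)
        k <- floor(cfg$mask_probability * n_el)
        if (k > 0L) {
          sel[which(eligible)[sample.int(n_el, k)]] <- TRUE
        }
      } else {
        u <- stats::runif(length(x))
        sel <- eligible & u < cfg$mask_probability
      }
      y <- x
      for (p in which(sel)) {
        bg <- cfg$background
        if (cfg$exclude_original) bg[x[p] + 1L] <- 0
        y[p] <- sample.int(v, 1L, prob = bg) - 1L
      }
      tg <- rep(NA_integer_, length(x))
      tg[sel] <- x[sel]
      corrupted[[s]] <- y
      mask[[s]] <- sel
      targets[[s]] <- tg
    }
    list(corrupted = corrupted, mask = mask, targets = targets)
  })
}

# Pad a list of token vectors into (tokens, validity) matrices. 1-based
# internal ids; pads use token 1 and validity 0.
pad_batch <- function(batch) {
  B <- length(batch)
  T_ <- max(lengths(batch))
  tokens <- matrix(1L, B, T_)
  vm <- matrix(0, B, T_)
  for (i in seq_len(B)) {
    L <- length(batch[[i]])
    tokens[i, seq_len(L)] <- batch[[i]] + 1L
    vm[i, seq_len(L)] <- 1
  }
  list(tokens = tokens, vm = vm)
}

#' Per-position predictive token distributions
#'
#' Generic scoring interface of masked language models: given (possibly
#' corrupted) token sequences, return each position's predicted
#' distribution over the vocabulary. Methods exist for fitted
#' [train_masked_lm()] models and the toy reference models
#' ([toy_uniform_model()], [toy_recall_model()]) used to calibrate the
#' scoring functions.
#'
#' @param model A model object.
#' @param batch List of 0-based integer token vectors.
#' @param ... Method-specific arguments.
#' @return List (one per sequence) of `L x vocab_size` probability
#'   matrices; column `i` is token `i - 1`.
#' @export
token_probs <- function(model, batch, ...) UseMethod("token_probs")

#' @export
token_probs.masked_lm <- function(model, batch, ...) {
  pd <- pad_batch(batch)
  fw <- encoder_forward(model$params, model$config, pd$tokens, pd$vm,
                        keep_cache = FALSE)
  B <- nrow(pd$tokens)
  probs <- row_softmax(add_bias(fw$outputs %*% model$params$Wo,
                                model$params$bo))
  lapply(seq_along(batch), function(i) {
    L <- length(batch[[i]])
    rows <- (seq_len(L) - 1L) * B + i
    probs[rows, , drop = FALSE]
  })
}

#' Toy reference models for scoring calibration
#'
#' `toy_uniform_model()` predicts the uniform distribution at every
#' position (its perplexity is exactly the vocabulary size);
#' `toy_recall_model()` memorizes one token sequence and predicts it with
#' probability `1 - epsilon` regardless of the input (perplexity
#' approaches 1). Both implement the [token_probs()] interface.
#'
#' @param vocab_size Vocabulary size.
#' @return A model object usable with [perplexity()] and
#'   [pseudo_perplexity()].
#' @export
toy_uniform_model <- function(vocab_size) {
  structure(list(vocab_size = as.integer(vocab_size)),
            class = "uniform_lm")
}

#' @export
token_probs.uniform_lm <- function(model, batch, ...) {
  lapply(batch, function(x) {
    matrix(1 / model$vocab_size, length(x), model$vocab_size)
  })
}

#' @rdname toy_uniform_model
#' @param truth 0-based token vector to recall.
#' @param epsilon Probability mass spread over the other tokens.
#' @export
toy_recall_model <- function(truth, vocab_size, epsilon = 0) {
  stopifnot(all(truth >= 0L), all(truth < vocab_size))
  structure(list(truth = as.integer(truth),
                 vocab_size = as.integer(vocab_size),
                 epsilon = epsilon),
            class = "recall_lm")
}

#' @export
token_probs.recall_lm <- function(model, batch, ...) {
  lapply(batch, function(x) {
    stopifnot(length(x) == length(model$truth))
    v <- model$vocab_size
    m <- matrix(model$epsilon / max(1L, v - 1L), length(x), v)
    m[cbind(seq_along(x), model$truth + 1L)] <- 1 - model$epsilon
    m
  })
}

#' Train the masked language model
#'
#' Optimizes a bidirectional-LSTM encoder with cross-entropy on the
#' masked positions only, using the corruption scheme of
#' [apply_masking()] with fresh draws each step, Adam, and the linear
#' learning-rate schedule of [scheduled_lr()]. A validation split is held
#' out up front; held-out perplexity and an embedding snapshot are
#' recorded every `checkpoint_every` steps (plus step 0 and the final
#' step). Unknown-token and padded positions never contribute to the
#' loss. Training aborts with a diagnostic if the loss becomes
#' non-finite.
#'
#' @param corpus List of 0-based integer token vectors (a tokenized,
#'   normalized corpus under a single alphabet), or a tibble with columns
#'   `id`, `seq` together with `alphabet`.
#' @param lm_cfg An [lm_config()].
#' @param mask_cfg A [masking_config()]; if `NULL`, built from the
#'   corpus' empirical background with default settings.
#' @param train_cfg A [train_config()].
#' @param alphabet Optional alphabet (object or name) used to tokenize
#'   `corpus` when it is a tibble of sequences.
#' @param val_eval_n Held-out sequences scored per evaluation.
#' @param quiet Suppress progress messages.
#' @return An object of class `masked_lm`: fields `params`, `config`,
#'   `mask_cfg`, `train_cfg`, `background`, `log` (tibble: `step`, `lr`,
#'   `loss`, `val_perplexity`), `snapshots` (list of `(step, matrix)`),
#'   `n_parameters`. `tidy()` returns the training log; `glance()` a
#'   one-row summary.
#' @export
train_masked_lm <- function(corpus, lm_cfg, mask_cfg = NULL,
                            train_cfg = train_config(), alphabet = NULL,
                            val_eval_n = 64L, quiet = FALSE) {
  if (is.data.frame(corpus)) {
    stopifnot(!is.null(alphabet))
    alphabet <- as_alphabet(alphabet)
    corpus <- lapply(corpus$seq, tokenize, alphabet = alphabet)
  }
  stopifnot(inherits(lm_cfg, "lm_config"), inherits(train_cfg, "train_config"))
  v <- lm_cfg$vocab_size
  if (is.null(mask_cfg)) {
    mask_cfg <- masking_config(
      build_background_distribution(corpus, v),
      seed = train_cfg$seed
    )
  }
  stopifnot(length(mask_cfg$background) == v)
  n <- length(corpus)
  n_val <- max(1L, round(train_cfg$val_fraction * n))
  val_idx <- with_seed(substream_seed(train_cfg$seed, "split"), {
    sample.int(n, n_val)
  })
  train_set <- corpus[-val_idx]
  val_set <- corpus[val_idx]
  if (length(train_set) == 0L) {
    abort_redalph("no training sequences left after validation split",
                  "redalph_validation_error")
  }
  params <- with_seed(substream_seed(train_cfg$seed, "init"), {
    init_lm_params(lm_cfg)
  })
  n_par <- count_params_tree(params)
  if (!quiet) {
    message(sprintf("masked LM: %s preset, %d parameters, vocab %d",
                    lm_cfg$preset, n_par, v))
  }
  model <- structure(
    list(params = params, config = lm_cfg, mask_cfg = mask_cfg,
         train_cfg = train_cfg, background = mask_cfg$background,
         n_parameters = n_par),
    class = "masked_lm"
  )
  eval_val <- function(step) {
    idx <- seq_len(min(val_eval_n, length(val_set)))
    cfg_e <- mask_cfg
    cfg_e$seed <- substream_seed(train_cfg$seed, "valmask")
    res <- perplexity(model, val_set[idx], cfg_e, n_draws = 1L)
    res$perplexity
  }
  state <- adam_init(params)
  order_stream <- substream_seed(train_cfg$seed, "shuffle")
  epoch_order <- integer(0)
  steps <- train_cfg$max_steps
  log_step <- integer(steps)
  log_lr <- numeric(steps)
  log_loss <- rep(NA_real_, steps)
  log_val <- rep(NA_real_, steps)
  snapshots <- list(list(step = 0L, matrix = params$E))
  val0 <- eval_val(0L)
  for (step in seq_len(steps)) {
    if (length(epoch_order) < train_cfg$batch_size) {
      epoch_order <- c(epoch_order, with_seed(order_stream + step, {
        sample.int(length(train_set))
      }))
    }
    take <- epoch_order[seq_len(train_cfg$batch_size)]
    epoch_order <- epoch_order[-seq_len(train_cfg$batch_size)]
    batch <- train_set[take]
    mc <- mask_cfg
    mc$seed <- substream_seed(train_cfg$seed, paste0("step", step))
    cor <- apply_masking(batch, mc)
    pd <- pad_batch(cor$corrupted)
    fw <- encoder_forward(model$params, lm_cfg, pd$tokens, pd$vm)
    T_ <- ncol(pd$tokens)
    B <- nrow(pd$tokens)
    # gather loss positions
    Mmat <- matrix(FALSE, B, T_)
    Tmat <- matrix(NA_integer_, B, T_)
    for (i in seq_len(B)) {
      L <- length(cor$mask[[i]])
      Mmat[i, seq_len(L)] <- cor$mask[[i]]
      Tmat[i, seq_len(L)] <- cor$targets[[i]]
    }
    n_masked <- sum(Mmat)
    lr <- scheduled_lr(train_cfg, step)
    log_step[step] <- step
    log_lr[step] <- lr
    if (n_masked == 0L) next
    # time-major outputs: row index = (t-1)*B + b
    sel <- which(Mmat, arr.ind = TRUE)
    rows <- (sel[, 2L] - 1L) * B + sel[, 1L]
    Hm <- fw$outputs[rows, , drop = FALSE]
    logits <- add_bias(Hm %*% model$params$Wo, model$params$bo)
    probs <- row_softmax(logits)
    targ1 <- Tmat[sel] + 1L
    p_true <- probs[cbind(seq_len(n_masked), targ1)]
    loss <- -mean(log(p_true))
    if (!is.finite(loss)) {
      abort_redalph(sprintf("training diverged at step %d (loss %s)",
                            step, format(loss)), "redalph_training_error")
    }
    log_loss[step] <- loss
    dlogits <- probs
    dlogits[cbind(seq_len(n_masked), targ1)] <-
      dlogits[cbind(seq_len(n_masked), targ1)] - 1
    dlogits <- dlogits / n_masked
    dWo <- crossprod(Hm, dlogits)
    dbo <- colSums(dlogits)
    dHm <- dlogits %*% t(model$params$Wo)
    dout <- matrix(0, T_ * B, ncol(Hm))
    dout[rows, ] <- dHm
    grads <- encoder_backward(model$params, lm_cfg, pd$tokens, pd$vm, fw, dout)
    grads$Wo <- dWo
    grads$bo <- dbo
    upd <- adam_step(model$params, grads, state, lr,
                     weight_decay = train_cfg$l2_weight_decay)
    model$params <- upd$params
    state <- upd$state
    if (step %% train_cfg$checkpoint_every == 0L || step == steps) {
      log_val[step] <- eval_val(step)
      snapshots[[length(snapshots) + 1L]] <-
        list(step = step, matrix = model$params$E)
      if (!quiet) {
        message(sprintf("step %d/%d lr %.2e loss %.4f val ppl %.3f",
                        step, steps, lr, loss, log_val[step]))
      }
    }
  }
  model$log <- tibble::tibble(
    step = c(0L, log_step), lr = c(scheduled_lr(train_cfg, 0L), log_lr),
    loss = c(NA_real_, log_loss), val_perplexity = c(val0, log_val)
  )
  model$snapshots <- snapshots
  model
}

#' @export
print.masked_lm <- function(x, ...) {
  cat(sprintf("<masked_lm> vocab %d, %d layers%s, %d parameters\n",
              x$config$vocab_size, x$config$num_layers,
              if (x$config$bidirectional) " (bidirectional)" else "",
              x$n_parameters))
  if (!is.null(x$log)) {
    fin <- x$log[nrow(x$log), ]
    cat(sprintf("  trained %d steps; final loss %.4f, val perplexity %.3f\n",
                fin$step, fin$loss,
                utils::tail(stats::na.omit(x$log$val_perplexity), 1L)))
  }
  invisible(x)
}

#' @rdname train_masked_lm
#' @param x A `masked_lm`.
#' @param ... Unused.
#' @method tidy masked_lm
#' @export
tidy.masked_lm <- function(x, ...) x$log

#' @rdname train_masked_lm
#' @method glance masked_lm
#' @export
glance.masked_lm <- function(x, ...) {
  tibble::tibble(
    n_parameters = x$n_parameters,
    vocab_size = x$config$vocab_size,
    steps = max(x$log$step),
    final_loss = utils::tail(stats::na.omit(x$log$loss), 1L),
    final_val_perplexity = utils::tail(stats::na.omit(x$log$val_perplexity), 1L)
  )
}

#' Masked-token perplexity (Monte-Carlo)
#'
#' Draws `n_draws` random mask sets per sequence with the corruption
#' scheme, scores the original tokens at the masked positions given the
#' corrupted context, and exponentiates the mean negative log-likelihood
#' per masked token. The printed form of the definition leaves the
#' average implicit; the mean-per-masked-token reading is used so the
#' measure is consistent with [pseudo_perplexity()] and equals the
#' vocabulary size for a uniform model.
#'
#' @param model A model implementing [token_probs()].
#' @param sequences List of 0-based token vectors.
#' @param mask_cfg A [masking_config()] (defaults to the model's own).
#' @param n_draws Mask draws per sequence.
#' @return A one-row tibble: `perplexity`, `mc_se` (delta-method
#'   Monte-Carlo standard error), `n_masked`, `n_draws`.
#' @export
perplexity <- function(model, sequences, mask_cfg = NULL, n_draws = 10L) {
  if (is.null(mask_cfg)) mask_cfg <- model$mask_cfg
  stopifnot(inherits(mask_cfg, "masking_config"), n_draws >= 1L)
  nll <- numeric(0)
  for (d in seq_len(n_draws)) {
    cfg_d <- mask_cfg
    cfg_d$seed <- substream_seed(mask_cfg$seed, paste0("draw", d))
    cor <- apply_masking(sequences, cfg_d)
    if (sum(unlist(cor$mask)) == 0L) next
    pr <- token_probs(model, cor$corrupted)
    for (i in seq_along(sequences)) {
      sel <- which(cor$mask[[i]])
      if (length(sel) == 0L) next
      p <- pr[[i]][cbind(sel, cor$targets[[i]][sel] + 1L)]
      nll <- c(nll, -log(p))
    }
  }
  if (length(nll) == 0L) {
    abort_redalph(
      "no position was ever masked; increase n_draws or sequence length",
      "redalph_validation_error"
    )
  }
  m <- mean(nll)
  se <- stats::sd(nll) / sqrt(length(nll))
  if (is.na(se)) se <- 0
  tibble::tibble(
    perplexity = exp(m),
    mc_se = exp(m) * se,
    n_masked = length(nll),
    n_draws = n_draws
  )
}

#' Pseudo-perplexity (deterministic)
#'
#' Scores each position conditioned on all others: for position i the
#' input token is replaced and the model's probability of the true token
#' at i is read off. Because the corruption scheme has no designated mask
#' token, the per-position conditional is the model's prediction
#' marginalized over background replacement tokens r != x_i, which makes
#' the measure fully deterministic — repeated calls agree bit for bit.
#' Unknown-token positions are skipped (they carry no signal and never
#' contribute to training loss either).
#'
#' @param model A model implementing [token_probs()].
#' @param sequence A 0-based token vector.
#' @param background Replacement distribution (defaults to the model's
#'   background, else uniform over non-unknown tokens).
#' @param chunk_size Forward-pass batch rows per call.
#' @return The pseudo-perplexity (a single number >= 1).
#' @export
pseudo_perplexity <- function(model, sequence, background = NULL,
                              chunk_size = 512L) {
  v <- model$vocab_size %||% model$config$vocab_size
  unk <- v - 1L
  if (is.null(background)) {
    background <- model$background %||%
      c(rep(1 / (v - 1L), v - 1L), 0)
  }
  L <- length(sequence)
  stopifnot(L >= 1L)
  positions <- which(sequence != unk)
  if (length(positions) == 0L) {
    abort_redalph("sequence contains only unknown tokens",
                  "redalph_validation_error")
  }
  # build all singly-corrupted copies: position x replacement
  jobs <- list()
  job_pos <- integer(0)
  job_w <- numeric(0)
  for (i in positions) {
    bg <- background
    bg[sequence[i] + 1L] <- 0
    bg <- bg / sum(bg)
    for (r in which(bg > 0)) {
      s2 <- sequence
      s2[i] <- r - 1L
      jobs[[length(jobs) + 1L]] <- s2
      job_pos <- c(job_pos, i)
      job_w <- c(job_w, bg[r])
    }
  }
  p_true <- numeric(length(jobs))
  for (start in seq(1L, length(jobs), by = chunk_size)) {
    idx <- start:min(start + chunk_size - 1L, length(jobs))
    pr <- token_probs(model, jobs[idx])
    for (k in seq_along(idx)) {
      j <- idx[k]
      p_true[j] <- pr[[k]][job_pos[j], sequence[job_pos[j]] + 1L]
    }
  }
  p_i <- vapply(positions, function(i) {
    sum(job_w[job_pos == i] * p_true[job_pos == i])
  }, 0)
  exp(-mean(log(p_i)))
}
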