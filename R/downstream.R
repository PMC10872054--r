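# Fine-tuning head: attention pooling over per-position encoder outputs
# followed by an MLP with a single hidden layer. The encoder is kept
# frozen; only the head is trained (full-batch Adam with early stopping).

#' Attention pooling
#'
#' Learned convex combination of per-position embeddings: scores are
#' normalized with a softmax over the valid positions, invalid (padding)
#' positions receive zero weight. With all scores equal (e.g. an
#' untrained head) the result is the arithmetic mean of the valid rows.
#'
#' @param h Numeric `T x D` matrix of per-position embeddings.
#' @param valid Logical vector of length `T`; at least one `TRUE`.
#' @param scores Numeric scores of length `T`, or `NULL` for all-equal.
#' @return Numeric vector of length `D`.
#' @export
attention_pool <- function(h, valid = rep(TRUE, nrow(h)), scores = NULL) {
  h <- as.matrix(h)
  stopifnot(length(valid) == nrow(h))
  if (!any(valid)) {
    abort_redalph("attention pooling needs at least one valid position",
                  "redalph_validation_error")
  }
  if (is.null(scores)) scores <- rep(0, nrow(h))
  s <- scores[valid]
  w <- exp(s - max(s))
  w <- w / sum(w)
  as.numeric(crossprod(h[valid, , drop = FALSE], w))
}

#' Encode token sequences with a fitted masked LM
#'
#' Runs the encoder and returns the top-layer per-position outputs, the
#' "sequence of embeddings" consumed by the fine-tuning head.
#'
#' @param model A `masked_lm`.
#' @param sequences List of 0-based token vectors.
#' @return List of `L x D` matrices (D = 2 x hidden for a bidirectional
#'   encoder).
#' @export
encode_sequences <- function(model, sequences) {
  stopifnot(inherits(model, "masked_lm"))
  pd <- pad_batch(sequences)
  fw <- encoder_forward(model$params, model$config, pd$tokens, pd$vm,
                        keep_cache = FALSE)
  B <- nrow(pd$tokens)
  lapply(seq_along(sequences), function(i) {
    L <- length(sequences[[i]])
    fw$outputs[(seq_len(L) - 1L) * B + i, , drop = FALSE]
  })
}

#' Downstream head configuration
#'
#' @param hidden_dim Hidden units of the MLP.
#' @param learning_rate Adam learning rate for the head.
#' @param max_epochs Upper bound on full-batch epochs.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement).
#' @param val_fraction Fraction of examples held out for early stopping.
#' @param seed Integer seed (init + split).
#' @return A `head_config` object.
#' @export
head_config <- function(hidden_dim = 32L, learning_rate = 1e-2,
                        max_epochs = 300L, patience = 30L,
                        val_fraction = 0.2, seed = 1L) {
  stopifnot(hidden_dim >= 1L, learning_rate > 0, max_epochs >= 1L,
            patience >= 1L, val_fraction > 0, val_fraction < 1)
  structure(
    list(hidden_dim = as.integer(hidden_dim), learning_rate = learning_rate,
         max_epochs = as.integer(max_epochs), patience = as.integer(patience),
         val_fraction = val_fraction, seed = as.integer(seed)),
    class = "head_config"
  )
}

head_forward <- function(par, feats, valid) {
  n <- length(feats)
  pooled <- matrix(0, n, length(par$v))
  alphas <- vector("list", n)
  for (i in seq_len(n)) {
    h <- feats[[i]]
    s <- as.numeric(h %*% par$v) + par$bv
    s[!valid[[i]]] <- -Inf
    w <- exp(s - max(s))
    w <- w / sum(w)
    alphas[[i]] <- w
    pooled[i, ] <- as.numeric(crossprod(h, w))
  }
  z1 <- add_bias(pooled %*% par$W1, par$b1)
  a1 <- tanh(z1)
  out <- add_bias(a1 %*% par$W2, par$b2)
  list(pooled = pooled, alphas = alphas, a1 = a1, out = out)
}

head_backward <- function(par, feats, valid, fwd, dout) {
  da1 <- dout %*% t(par$W2) * (1 - fwd$a1^2)
  g <- list(
    W2 = crossprod(fwd$a1, dout), b2 = colSums(dout),
    W1 = crossprod(fwd$pooled, da1), b1 = colSums(da1),
    v = par$v * 0, bv = 0
  )
  dpooled <- da1 %*% t(par$W1)
  for (i in seq_along(feats)) {
    h <- feats[[i]]
    w <- fwd$alphas[[i]]
    proj <- as.numeric(h %*% dpooled[i, ]) # T: h_t . dpooled
    mean_proj <- sum(w * proj)
    ds <- w * (proj - mean_proj) # softmax jacobian
    g$v <- g$v + as.numeric(crossprod(h, ds))
    g$bv <- g$bv + sum(ds)
  }
  g
}

#' Fine-tune a downstream prediction head
#'
#' Trains the attention-pooling + single-hidden-layer MLP head on top of
#' frozen encoder outputs, full-batch Adam with early stopping on a
#' validation split. Classification reports accuracy, regression Pearson
#' correlation — the conventional metrics for enzyme/fold classification
#' and fitness regression benchmarks.
#'
#' @param model A fitted `masked_lm` (the frozen encoder).
#' @param sequences List of 0-based token vectors.
#' @param labels Factor/character (classification) or numeric
#'   (regression), one per sequence.
#' @param task `"classification"` or `"regression"`.
#' @param head_cfg A [head_config()].
#' @param quiet Suppress progress messages.
#' @return An object of class `downstream_fit` with the fitted head
#'   parameters, `history` (per-epoch losses), and `metrics` (one-row
#'   tibble: validation `accuracy` or `pearson`). `glance()` returns the
#'   metrics.
#' @export
train_downstream <- function(model, sequences, labels,
                             task = c("classification", "regression"),
                             head_cfg = head_config(), quiet = TRUE) {
  task <- match.arg(task)
  stopifnot(length(sequences) == length(labels))
  feats <- encode_sequences(model, sequences)
  valid <- lapply(sequences, function(s) rep(TRUE, length(s)))
  d <- ncol(feats[[1L]])
  n <- length(feats)
  if (task == "classification") {
    yfac <- factor(labels)
    if (nlevels(yfac) < 2L) {
      abort_redalph("classification needs at least two classes",
                    "redalph_validation_error")
    }
    y <- as.integer(yfac)
    n_out <- nlevels(yfac)
  } else {
    stopifnot(is.numeric(labels))
    y <- as.numeric(labels)
    n_out <- 1L
  }
  n_val <- max(1L, round(head_cfg$val_fraction * n))
  val_idx <- with_seed(substream_seed(head_cfg$seed, "headsplit"), {
    sample.int(n, n_val)
  })
  tr <- setdiff(seq_len(n), val_idx)
  par <- with_seed(substream_seed(head_cfg$seed, "headinit"), {
    m <- head_cfg$hidden_dim
    list(
      v = rep(0, d), bv = 0,
      W1 = init_matrix(d, m, 1 / sqrt(d)), b1 = rep(0, m),
      W2 = init_matrix(m, n_out, 1 / sqrt(m)), b2 = rep(0, n_out)
    )
  })
  state <- adam_init(par)
  loss_fn <- function(par, idx) {
    fwd <- head_forward(par, feats[idx], valid[idx])
    if (task == "classification") {
      p <- row_softmax(fwd$out)
      pt <- p[cbind(seq_along(idx), y[idx])]
      loss <- -mean(log(pmax(pt, 1e-12)))
      dout <- p
      dout[cbind(seq_along(idx), y[idx])] <-
        dout[cbind(seq_along(idx), y[idx])] - 1
      dout <- dout / length(idx)
    } else {
      r <- fwd$out[, 1L] - y[idx]
      loss <- mean(r^2)
      dout <- matrix(2 * r / length(idx), ncol = 1L)
    }
    list(loss = loss, fwd = fwd, dout = dout)
  }
  best <- list(loss = Inf, par = par, epoch = 0L)
  wait <- 0L
  hist_tr <- numeric(0)
  hist_val <- numeric(0)
  for (epoch in seq_len(head_cfg$max_epochs)) {
    lf <- loss_fn(par, tr)
    g <- head_backward(par, feats[tr], valid[tr], lf$fwd, lf$dout)
    upd <- adam_step(par, g, state, head_cfg$learning_rate)
    par <- upd$params
    state <- upd$state
    vl <- loss_fn(par, val_idx)$loss
    hist_tr <- c(hist_tr, lf$loss)
    hist_val <- c(hist_val, vl)
    if (vl < best$loss - 1e-6) {
      best <- list(loss = vl, par = par, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= head_cfg$patience) break
    }
    if (!quiet && epoch %% 25L == 0L) {
      message(sprintf("epoch %d train %.4f val %.4f", epoch, lf$loss, vl))
    }
  }
  par <- best$par
  fwd_val <- head_forward(par, feats[val_idx], valid[val_idx])
  metrics <- if (task == "classification") {
    pred <- max.col(fwd_val$out)
    tibble::tibble(accuracy = mean(pred == y[val_idx]),
                   n_validation = n_val)
  } else {
    r <- suppressWarnings(stats::cor(fwd_val$out[, 1L], y[val_idx]))
    tibble::tibble(pearson = r, n_validation = n_val)
  }
  structure(
    list(par = par, task = task,
         levels = if (task == "classification") levels(yfac) else NULL,
         head_cfg = head_cfg, best_epoch = best$epoch,
         history = tibble::tibble(
           epoch = seq_along(hist_tr),
           train_loss = hist_tr, val_loss = hist_val
         ),
         metrics = metrics),
    class = "downstream_fit"
  )
}

#' @export
print.downstream_fit <- function(x, ...) {
  cat(sprintf("<downstream_fit> %s head, best epoch %d\n",
              x$task, x$best_epoch))
  print(x$metrics)
  invisible(x)
}

#' @rdname train_downstream
#' @param x A `downstream_fit`.
#' @param ... Unused.
#' @method glance downstream_fit
#' @export
glance.downstream_fit <- function(x, ...) x$metrics

#' @rdname train_downstream
#' @method tidy downstream_fit
#' @export
tidy.downstream_fit <- function(x, ...) x$history

#' Predict with a fitted downstream head
#'
#' @param object A `downstream_fit`.
#' @param model The `masked_lm` encoder used for training.
#' @param sequences List of 0-based token vectors.
#' @param ... Unused.
#' @return Classification: tibble `class` (+ per-class probabilities);
#'   regression: tibble `prediction`.
#' @export
predict.downstream_fit <- function(object, model, sequences, ...) {
  feats <- encode_sequences(model, sequences)
  valid <- lapply(sequences, function(s) rep(TRUE, length(s)))
  fwd <- head_forward(object$par, feats, valid)
  if (object$task == "classification") {
    p <- row_softmax(fwd$out)
    colnames(p) <- object$levels
    dplyr::bind_cols(
      tibble::tibble(class = object$levels[max.col(fwd$out)]),
      tibble::as_tibble(p)
    )
  } else {
    tibble::tibble(prediction = fwd$out[, 1L])
  }
}
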