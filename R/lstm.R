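# Native implementation of the bidirectional-LSTM encoder used by the
# masked language model: initialization, forward pass, backpropagation
# through time, and Adam. Time-major layout: a batch of B sequences
# padded to T steps is a (T*B) x dim matrix whose rows (t-1)*B + b hold
# step t of sequence b, so all input projections and weight-gradient
# contractions run as single large matrix products and only the
# recurrence itself loops over t. Padded positions are excluded by
# zeroing the recurrent state through the validity mask, which is exact
# for right-padding in the forward direction and, because the state
# resets before real tokens begin, for the reversed direction as well.
# Gate layout in the 4H blocks: input, forget, cell, output; forget
# biases start at 1.

init_matrix <- function(nr, nc, scale) {
  matrix(stats::runif(nr * nc, -scale, scale), nr, nc)
}

init_lstm_cell <- function(input_dim, hidden_dim) {
  s <- 1 / sqrt(hidden_dim)
  b <- rep(0, 4L * hidden_dim)
  b[(hidden_dim + 1L):(2L * hidden_dim)] <- 1 # forget gate bias
  list(
    Wx = init_matrix(input_dim, 4L * hidden_dim, s),
    Wh = init_matrix(hidden_dim, 4L * hidden_dim, s),
    b = b
  )
}

# Initialize all parameters for the masked LM (encoder + output head).
init_lm_params <- function(cfg) {
  d <- cfg$embedding_dim
  h <- cfg$hidden_dim
  v <- cfg$vocab_size
  ndir <- if (cfg$bidirectional) 2L else 1L
  layers <- vector("list", cfg$num_layers)
  for (l in seq_len(cfg$num_layers)) {
    din <- if (l == 1L) d else ndir * h
    layers[[l]] <- list(fwd = init_lstm_cell(din, h))
    if (cfg$bidirectional) layers[[l]]$bwd <- init_lstm_cell(din, h)
  }
  list(
    E = init_matrix(v, d, 1 / sqrt(d)),
    layers = layers,
    Wo = init_matrix(ndir * h, v, 1 / sqrt(ndir * h)),
    bo = rep(0, v)
  )
}

add_bias <- function(z, b) z + rep(b, each = nrow(z))

# Forward pass of one direction. xall: (T*B) x Din time-major input;
# vall: length T*B validity (1 valid / 0 pad). The input projection is
# one BLAS call; the sequential recurrence runs in the compiled kernel.
lstm_cell_forward <- function(cell, xall, vall, B, T_, keep_cache = TRUE) {
  zx <- add_bias(xall %*% cell$Wx, cell$b)
  out <- lstm_forward_cpp(zx, cell$Wh, vall, B, T_, keep_cache)
  if (keep_cache) {
    list(hall = out$hall,
         cache = out[c("i", "f", "g", "o", "tc", "c_prev", "h_prev")])
  } else {
    list(hall = out$hall, cache = NULL)
  }
}

# BPTT for one direction. dhall: (T*B) x H gradients w.r.t. the (masked)
# hidden outputs. Returns parameter gradients and the input gradient;
# the weight contractions are single BLAS calls over the stacked gate
# gradients returned by the kernel.
lstm_cell_backward <- function(cell, xall, vall, fwd, dhall, B, T_) {
  ca <- fwd$cache
  dzall <- lstm_backward_cpp(cell$Wh, dhall, vall, ca$i, ca$f, ca$g,
                             ca$o, ca$tc, ca$c_prev, B, T_)
  list(
    Wx = crossprod(xall, dzall),
    Wh = crossprod(ca$h_prev, dzall),
    b = colSums(dzall),
    dx = dzall %*% t(cell$Wx)
  )
}

# Row permutation that reverses time order in a time-major matrix.
time_reverse_index <- function(B, T_) {
  as.vector(vapply(rev(seq_len(T_)), function(t) {
    ((t - 1L) * B + 1L):(t * B)
  }, integer(B)))
}

# Forward through the full encoder: tokens (B x T, 1-based; pad rows use
# token 1 but are masked out), vm numeric B x T. Returns the time-major
# top-layer outputs ((T*B) x ndir*H) plus caches for backprop.
encoder_forward <- function(params, cfg, tokens, vm, keep_cache = TRUE) {
  B <- nrow(tokens)
  T_ <- ncol(tokens)
  vall <- as.vector(vm) # column-major == time-major blocks of B
  xall <- params$E[as.vector(tokens), , drop = FALSE]
  rev_idx <- if (cfg$bidirectional) time_reverse_index(B, T_) else NULL
  layer_inputs <- vector("list", cfg$num_layers)
  layer_fwd <- vector("list", cfg$num_layers)
  for (l in seq_len(cfg$num_layers)) {
    layer_inputs[[l]] <- xall
    f <- lstm_cell_forward(params$layers[[l]]$fwd, xall, vall, B, T_,
                           keep_cache)
    if (cfg$bidirectional) {
      b <- lstm_cell_forward(params$layers[[l]]$bwd,
                             xall[rev_idx, , drop = FALSE],
                             vall[rev_idx], B, T_, keep_cache)
      xall <- cbind(f$hall, b$hall[rev_idx, , drop = FALSE])
    } else {
      xall <- f$hall
    }
    layer_fwd[[l]] <- list(fwd = f, bwd = if (cfg$bidirectional) b)
  }
  list(outputs = xall, layer_inputs = layer_inputs, layer_fwd = layer_fwd,
       rev_idx = rev_idx, B = B, T_ = T_)
}

# Backward through the full encoder given time-major output gradients.
encoder_backward <- function(params, cfg, tokens, vm, fwd, dout) {
  B <- fwd$B
  T_ <- fwd$T_
  vall <- as.vector(vm)
  rev_idx <- fwd$rev_idx
  grads <- list(layers = vector("list", cfg$num_layers))
  H1 <- nrow(params$layers[[1L]]$fwd$Wh)
  for (l in rev(seq_len(cfg$num_layers))) {
    xall <- fwd$layer_inputs[[l]]
    if (cfg$bidirectional) {
      gf <- lstm_cell_backward(params$layers[[l]]$fwd, xall, vall,
                               fwd$layer_fwd[[l]]$fwd,
                               dout[, seq_len(H1), drop = FALSE], B, T_)
      gb <- lstm_cell_backward(params$layers[[l]]$bwd,
                               xall[rev_idx, , drop = FALSE],
                               vall[rev_idx], fwd$layer_fwd[[l]]$bwd,
                               dout[rev_idx, H1 + seq_len(H1),
                                    drop = FALSE], B, T_)
      dout <- gf$dx
      dout[rev_idx, ] <- dout[rev_idx, , drop = FALSE] + gb$dx
      grads$layers[[l]] <- list(fwd = gf[c("Wx", "Wh", "b")],
                                bwd = gb[c("Wx", "Wh", "b")])
    } else {
      gf <- lstm_cell_backward(params$layers[[l]]$fwd, xall, vall,
                               fwd$layer_fwd[[l]]$fwd, dout, B, T_)
      dout <- gf$dx
      grads$layers[[l]] <- list(fwd = gf[c("Wx", "Wh", "b")])
    }
  }
  # embedding gradient: scatter-add per token id (pads have zero grads)
  agg <- rowsum(dout, group = as.vector(tokens))
  dE <- params$E * 0
  dE[as.integer(rownames(agg)), ] <- agg
  grads$E <- dE
  grads
}

# --- Adam over a nested parameter tree ------------------------------------

tree_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    by_name <- !is.null(names(a)) && all(nzchar(names(a)))
    for (i in seq_along(a)) {
      bi <- if (by_name) b[[names(a)[i]]] else b[[i]]
      out[[i]] <- tree_map2(a[[i]], bi, f)
    }
    out
  } else {
    f(a, b)
  }
}

tree_map <- function(a, f) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map(a[[i]], f)
    out
  } else {
    f(a)
  }
}

adam_init <- function(params) {
  list(m = tree_map(params, function(p) p * 0),
       v = tree_map(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      weight_decay = 0) {
  state$t <- state$t + 1L
  state$m <- tree_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- tree_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- tree_map2(state$m, state$v, function(m, v) {
    (m / bc1) / (sqrt(v / bc2) + eps)
  })
  params <- tree_map2(params, upd, function(p, u) p - lr * u)
  if (weight_decay > 0) {
    params <- tree_map(params, function(p) p - lr * weight_decay * p)
  }
  list(params = params, state = state)
}

count_params_tree <- function(params) {
  n <- 0
  rapply(params, function(p) {
    n <<- n + length(p)
    NULL
  }, how = "list")
  n
}
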