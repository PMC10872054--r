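# Correctness of the native encoder: analytic gradients against central
# finite differences, and exactness of the padding scheme.

test_that("encoder gradients match finite differences", {
  withr::local_seed(42)
  cfg <- lm_config(5L, embedding_dim = 4L, hidden_dim = 3L, num_layers = 2L)
  params <- redalph:::init_lm_params(cfg)
  batch <- list(c(0L, 1L, 2L, 3L), c(4L, 0L, 1L))
  pd <- redalph:::pad_batch(batch)
  B <- 2L
  T_ <- 4L
  Mmat <- matrix(FALSE, B, T_)
  Mmat[1, c(1, 3)] <- TRUE
  Mmat[2, 2] <- TRUE
  Tmat <- matrix(NA_integer_, B, T_)
  Tmat[1, 1] <- 2L
  Tmat[1, 3] <- 0L
  Tmat[2, 2] <- 3L
  sel <- which(Mmat, arr.ind = TRUE)
  rows <- (sel[, 2] - 1L) * B + sel[, 1]

  loss_of <- function(p) {
    fw <- redalph:::encoder_forward(p, cfg, pd$tokens, pd$vm)
    Hm <- fw$outputs[rows, , drop = FALSE]
    probs <- redalph:::row_softmax(redalph:::add_bias(Hm %*% p$Wo, p$bo))
    -mean(log(probs[cbind(seq_len(nrow(sel)), Tmat[sel] + 1L)]))
  }
  fw <- redalph:::encoder_forward(params, cfg, pd$tokens, pd$vm)
  Hm <- fw$outputs[rows, , drop = FALSE]
  probs <- redalph:::row_softmax(
    redalph:::add_bias(Hm %*% params$Wo, params$bo)
  )
  n_m <- nrow(sel)
  dlogits <- probs
  idx <- cbind(seq_len(n_m), Tmat[sel] + 1L)
  dlogits[idx] <- dlogits[idx] - 1
  dlogits <- dlogits / n_m
  dout <- matrix(0, T_ * B, ncol(Hm))
  dout[rows, ] <- dlogits %*% t(params$Wo)
  grads <- redalph:::encoder_backward(params, cfg, pd$tokens, pd$vm, fw, dout)
  grads$Wo <- crossprod(Hm, dlogits)
  grads$bo <- colSums(dlogits)

  eps <- 1e-6
  check_tensor <- function(get, set, g) {
    p0 <- get(params)
    for (i in sample(length(p0), min(5L, length(p0)))) {
      pp <- params
      v <- get(pp)
      v[i] <- v[i] + eps
      lp <- loss_of(set(pp, v))
      v[i] <- v[i] - 2 * eps
      lm_ <- loss_of(set(pp, v))
      expect_equal(g[i], (lp - lm_) / (2 * eps), tolerance = 1e-4)
    }
  }
  check_tensor(function(p) p$E, function(p, v) { p$E[] <- v; p }, grads$E)
  check_tensor(function(p) p$Wo, function(p, v) { p$Wo[] <- v; p }, grads$Wo)
  for (l in 1:2) {
    for (d in c("fwd", "bwd")) {
      for (w in c("Wx", "Wh", "b")) {
        check_tensor(
          function(p) p$layers[[l]][[d]][[w]],
          function(p, v) { p$layers[[l]][[d]][[w]][] <- v; p },
          grads$layers[[l]][[d]][[w]]
        )
      }
    }
  }
})

test_that("padding does not change a sequence's predictions", {
  m <- tiny_trained_model()
  s1 <- sample(0L:20L, 12, replace = TRUE)
  s2 <- sample(0L:20L, 25, replace = TRUE)
  alone <- token_probs(m, list(s1))[[1]]
  padded <- token_probs(m, list(s1, s2))[[1]]
  expect_equal(alone, padded, tolerance = 1e-12)
})

test_that("the learning-rate schedule is linear down to a tenth", {
  cfg <- train_config(learning_rate = 2e-4, max_steps = 1000L)
  expect_equal(scheduled_lr(cfg, 0L), 2e-4)
  expect_equal(scheduled_lr(cfg, 1000L), 2e-5)
  expect_equal(scheduled_lr(cfg, 500L), (2e-4 + 2e-5) / 2)
  steps <- 0:1000
  expect_equal(diff(scheduled_lr(cfg, steps)),
               rep(-0.9 * 2e-4 / 1000, 1000))
})
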