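# Finite-difference checks of the hand-written backward passes, plus
# hand-computed oracles for the LSTM step and the attention scores.

test_that("conv1d gradients match finite differences", {
  set.seed(41)
  B <- 2; L <- 8; Cin <- 3; Cout <- 2; k <- 5
  X <- array(rnorm(B * L * Cin), c(B, L, Cin))
  W <- matrix(rnorm(k * Cin * Cout), k * Cin, Cout)
  b <- rnorm(Cout)
  Wt <- matrix(rnorm(L * Cout), L, Cout)  # random linear readout
  loss <- function(Xv, Wv, bv) {
    f <- ecgan:::conv1d_fwd(array(Xv, c(B, L, Cin)),
                            matrix(Wv, k * Cin, Cout), bv, k)
    sum(matrix(f$out, B * L, Cout)^2) / 2
  }
  f <- ecgan:::conv1d_fwd(X, W, b, k)
  bk <- ecgan:::conv1d_bwd(f$out, W, f$cache)
  expect_equal(as.numeric(bk$dX),
               num_grad(function(v) loss(v, W, b), as.numeric(X)),
               tolerance = 1e-5)
  expect_equal(as.numeric(bk$dW),
               num_grad(function(v) loss(X, v, b), as.numeric(W)),
               tolerance = 1e-5)
  expect_equal(bk$db, num_grad(function(v) loss(X, W, v), b),
               tolerance = 1e-5)
})

test_that("batch-norm gradients match finite differences in train mode", {
  set.seed(42)
  B <- 3; L <- 4; C <- 2
  X <- array(rnorm(B * L * C, 1, 2), c(B, L, C))
  p <- ecgan:::bn_init(C)
  p$gamma <- rnorm(C, 1, 0.2); p$beta <- rnorm(C, 0, 0.2)
  R <- array(rnorm(B * L * C), c(B, L, C))  # fixed readout
  loss <- function(Xv) {
    f <- ecgan:::bn_fwd(array(Xv, c(B, L, C)), p, train = TRUE)
    sum(f$out * R)
  }
  f <- ecgan:::bn_fwd(X, p, train = TRUE)
  bk <- ecgan:::bn_bwd(R, p, f$cache)
  expect_equal(as.numeric(bk$dX), num_grad(loss, as.numeric(X)),
               tolerance = 1e-4)
})

test_that("pooling and upsampling backward passes match finite differences", {
  set.seed(43)
  B <- 2; L <- 6; C <- 2
  X <- array(rnorm(B * L * C), c(B, L, C))
  R <- array(rnorm(B * (L / 2) * C), c(B, L / 2, C))
  f <- ecgan:::maxpool2_fwd(X)
  bk <- ecgan:::maxpool2_bwd(R, f$cache)
  expect_equal(as.numeric(bk),
               num_grad(function(v) sum(ecgan:::maxpool2_fwd(
                 array(v, c(B, L, C)))$out * R), as.numeric(X)),
               tolerance = 1e-5)
  R2 <- array(rnorm(B * L * 3 * C), c(B, L * 3, C))
  up <- ecgan:::upsample_fwd(X, 3)
  expect_equal(as.numeric(ecgan:::upsample_bwd(R2, 3)),
               num_grad(function(v) sum(ecgan:::upsample_fwd(
                 array(v, c(B, L, C)), 3)$out * R2), as.numeric(X)),
               tolerance = 1e-5)
})

test_that("a scalar LSTM step matches the gate equations by hand", {
  p <- list(u_f = matrix(0.5), w_f = matrix(-0.3), b_f = 0.1,
            u_i = matrix(-0.2), w_i = matrix(0.4), b_i = -0.1,
            u_c = matrix(0.7), w_c = matrix(0.2), b_c = 0.05,
            u_o = matrix(0.3), w_o = matrix(-0.6), b_o = 0.2)
  x <- 0.8; h0 <- -0.5; c0 <- 0.3
  s <- lstm_step(x, h0, c0, p)
  phi <- function(z) 1 / (1 + exp(-z))
  f <- phi(0.1 + 0.5 * x + (-0.3) * h0)
  i <- phi(-0.1 + (-0.2) * x + 0.4 * h0)
  g <- tanh(0.05 + 0.7 * x + 0.2 * h0)
  o <- phi(0.2 + 0.3 * x + (-0.6) * h0)
  cn <- f * c0 + i * g
  expect_equal(s$c, cn, tolerance = 1e-10)
  expect_equal(s$h, o * tanh(cn), tolerance = 1e-10)
})

test_that("zero LSTM parameters give half-open gates and zero states", {
  p <- lapply(lstm_params(2, 3), function(m) m * 0)
  s <- lstm_step(c(1, -1), rep(0, 3), rep(0, 3), p)
  expect_equal(s$gates$f, matrix(0.5, 1, 3))
  expect_equal(s$c, rep(0, 3))
  expect_equal(s$h, rep(0, 3))
})

test_that("LSTM hidden states stay inside (-1, 1)", {
  set.seed(44)
  p <- lstm_params(4, 6)
  h <- rep(0, 6); cc <- rep(0, 6)
  for (t in 1:20) {
    s <- lstm_step(rnorm(4, 0, 5), h, cc, p)
    h <- s$h; cc <- s$c
    expect_true(all(abs(h) < 1))
  }
})

test_that("LSTM sequence backward matches finite differences", {
  set.seed(45)
  B <- 2; T_ <- 3; D <- 3; H <- 2
  p <- lstm_params(D, H)
  X <- array(rnorm(B * T_ * D), c(B, T_, D))
  R <- array(rnorm(B * T_ * H), c(B, T_, H))
  loss <- function(Xv) {
    f <- ecgan:::lstm_seq_fwd(array(Xv, c(B, T_, D)), p)
    sum(f$out * R)
  }
  f <- ecgan:::lstm_seq_fwd(X, p)
  bk <- ecgan:::lstm_seq_bwd(R, f, p)
  expect_equal(as.numeric(bk$dX), num_grad(loss, as.numeric(X)),
               tolerance = 1e-4)
  # parameter gradient spot check
  gnum <- num_grad(function(v) {
    p2 <- p; p2$u_c[] <- v
    sum(ecgan:::lstm_seq_fwd(X, p2)$out * R)
  }, as.numeric(p$u_c))
  expect_equal(as.numeric(bk$grads$u_c), gnum, tolerance = 1e-4)
})

test_that("bilstm output reverses with halves swapped on palindromes", {
  set.seed(46)
  p <- lstm_params(2, 3)
  seqx <- matrix(rnorm(3 * 2), 3, 2)
  pal <- rbind(seqx, seqx[(nrow(seqx) - 1):1, , drop = FALSE])  # length 5
  H <- bilstm(pal, p, p)  # shared forward/backward weights
  T_ <- nrow(pal); hh <- ncol(H) / 2
  swapped <- cbind(H[T_:1, (hh + 1):(2 * hh), drop = FALSE],
                   H[T_:1, 1:hh, drop = FALSE])
  expect_equal(H, swapped, tolerance = 1e-10)
})

test_that("attention oracle: two keys, dot score, hand-set values", {
  Q <- c(1, -0.5)
  K <- rbind(c(0.3, 0.4), c(-0.2, 0.8))
  r <- attention(Q, K, list(), score = "dot")
  s <- c(sum(Q * K[1, ]), sum(Q * K[2, ]))
  w <- exp(s) / sum(exp(s))
  expect_equal(r$weights, w, tolerance = 1e-10)
  expect_equal(r$context, w[1] * K[1, ] + w[2] * K[2, ], tolerance = 1e-10)
})

test_that("attention weights normalise for every score kind", {
  set.seed(47)
  for (score in c("dot", "general", "concat", "perceptron")) {
    Q <- rnorm(4)
    K <- matrix(rnorm(3 * 4), 3, 4)
    p <- attention_params(4, 4, da = 5, score = score)
    r <- attention(Q, K, p, score = score)
    expect_equal(sum(r$weights), 1, tolerance = 1e-10)
    expect_length(r$weights, 3)
  }
  # identical keys -> uniform weights
  K1 <- matrix(rep(c(1, 2, 3, 4), each = 5), 5, 4)
  r <- attention(rnorm(4), K1, list(), score = "dot")
  expect_equal(r$weights, rep(0.2, 5), tolerance = 1e-10)
  expect_error(attention(rnorm(4), matrix(0, 0, 4), list(), score = "dot"),
               "at least one key")
})

test_that("attention backward matches finite differences (all kinds)", {
  set.seed(48)
  B <- 2; T_ <- 3; dk <- 4
  for (score in c("dot", "general", "concat", "perceptron")) {
    Q <- matrix(rnorm(B * dk), B)
    K <- array(rnorm(B * T_ * dk), c(B, T_, dk))
    p <- attention_params(dk, dk, da = 3, score = score)
    R <- matrix(rnorm(B * dk), B)
    loss <- function(Qv, Kv) {
      r <- ecgan:::.attention_fwd(matrix(Qv, B), array(Kv, c(B, T_, dk)),
                                  p, score)
      sum(r$context * R)
    }
    r <- ecgan:::.attention_fwd(Q, K, p, score)
    bk <- ecgan:::.attention_bwd(R, Q, K, r$weights, p, score, r$cache)
    expect_equal(as.numeric(bk$dQ),
                 num_grad(function(v) loss(v, K), as.numeric(Q)),
                 tolerance = 1e-4, info = score)
    expect_equal(as.numeric(bk$dK),
                 num_grad(function(v) loss(Q, v), as.numeric(K)),
                 tolerance = 1e-4, info = score)
  }
})

test_that("residual block with zero conv weights returns the pooled input", {
  set.seed(49)
  p <- residual_block_params(3, 3, k = 3)
  p$conv1_W[] <- 0; p$conv2_W[] <- 0
  x <- matrix(rnorm(8 * 3), 8, 3)
  out <- residual_block(x, p, k = 3, train = FALSE)
  pooled <- apply(x, 2, function(col) pmax(col[c(1, 3, 5, 7)],
                                           col[c(2, 4, 6, 8)]))
  expect_equal(out, pooled, tolerance = 1e-6)
  expect_equal(nrow(out), 4L)
  expect_error(residual_block(matrix(rnorm(3), 1, 3), p, k = 3),
               "pool size")
})

test_that("residual block input gradient matches finite differences", {
  set.seed(50)
  p <- residual_block_params(2, 3, k = 3)
  p$bn2$gamma <- rnorm(3, 1, 0.2)  # move off the zero-init so both paths count
  B <- 2; L <- 6
  X <- array(rnorm(B * L * 2), c(B, L, 2))
  R <- array(rnorm(B * 3 * 3), c(B, 3, 3))
  loss <- function(Xv) {
    f <- ecgan:::.resblock_fwd(array(Xv, c(B, L, 2)), p, 3, 0, train = TRUE)
    sum(f$out * R)
  }
  f <- ecgan:::.resblock_fwd(X, p, 3, 0, train = TRUE)
  bk <- ecgan:::.resblock_bwd(R, p, f$cache, 3, train = TRUE)
  expect_equal(as.numeric(bk$dX), num_grad(loss, as.numeric(X)),
               tolerance = 1e-4)
  gnum <- num_grad(function(v) {
    p2 <- p; p2$conv1_W[] <- v
    f2 <- ecgan:::.resblock_fwd(X, p2, 3, 0, train = TRUE)
    sum(f2$out * R)
  }, as.numeric(p$conv1_W))
  expect_equal(as.numeric(bk$grads$conv1_W), gnum, tolerance = 1e-4)
})

test_that("full classifier gradient agrees with finite differences", {
  set.seed(51)
  cfg <- classifier_config(input_length = 128, n_residual_blocks = 7,
                           channels = c(2, 2, 3, 3, 4, 4, 4),
                           kernel_width = 3, lstm_hidden = 3,
                           attention_dim = 4, dropout = 0, seed = 52)
  mod <- ecgan:::.classifier_init(cfg, TRUE)
  # move BN scales off zero so every branch carries gradient
  for (i in seq_along(mod$params$blocks)) {
    mod$params$blocks[[i]]$bn2$gamma <- rnorm(length(
      mod$params$blocks[[i]]$bn2$gamma), 0.5, 0.1)
  }
  X <- matrix(rnorm(3 * 128, 0, 0.5), 3)
  y <- c(1, 3, 5)
  lossfun <- function(params) {
    r <- ecgan:::.clf_fwd(params, X, cfg, TRUE, train = TRUE)
    ecgan:::xent_fwd_bwd(r$logits, y)$loss
  }
  r <- ecgan:::.clf_fwd(mod$params, X, cfg, TRUE, train = TRUE)
  ce <- ecgan:::xent_fwd_bwd(r$logits, y)
  gr <- ecgan:::.clf_bwd(mod$params, ce$dZ, r$cache, cfg, TRUE, train = TRUE)
  paths <- list(c("fuse_W"), c("att", "v_a"), c("att", "W_a"),
                c("lstm_fw", "u_i"), c("lstm_bw", "w_o"),
                c("blocks", 1, "conv1_W"), c("blocks", 4, "conv2_W"),
                c("blocks", 7, "bn1", "gamma"), c("blocks", 3, "short_W"))
  for (path in paths) {
    pcur <- mod$params; gcur <- gr
    for (kk in path) { pcur <- pcur[[kk]]; gcur <- gcur[[kk]] }
    idx <- sample(length(pcur), min(3, length(pcur)))
    for (i in idx) {
      eps <- 1e-5
      setval <- function(lst, path, v) {
        if (length(path) == 1) { lst[[path[[1]]]][i] <- v; lst }
        else {
          lst[[path[[1]]]] <- setval(lst[[path[[1]]]], path[-1], v); lst
        }
      }
      f1 <- lossfun(setval(mod$params, as.list(path), pcur[i] + eps))
      f0 <- lossfun(setval(mod$params, as.list(path), pcur[i] - eps))
      expect_equal(gcur[i], (f1 - f0) / (2 * eps), tolerance = 1e-3,
                   info = paste(c(path, i), collapse = "/"))
    }
  }
})
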