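# Five-class heartbeat classifier: seven residual convolution blocks (each
# two conv + batch-norm layers with a shortcut, followed by max pooling)
# extract local morphology; a BiLSTM over the resulting short feature
# sequence extracts global context; an attention mechanism (or mean pooling
# in the ablation variant) condenses the BiLSTM outputs; the attention
# context is fused with globally average-pooled convolutional features and
# classified by a softmax layer.

#' Classifier configuration
#'
#' @param input_length Network input length (default 256; 150-sample beats
#'   are right-padded with zeros so that seven pooling halvings are exact).
#' @param n_residual_blocks Number of residual blocks (default 7, giving 14
#'   convolution layers and 7 pooling layers).
#' @param channels Output channels of each block (default
#'   `c(32, 32, 64, 64, 128, 128, 256)`).
#' @param kernel_width Convolution kernel width (default 5).
#' @param dropout Dropout rate inside residual blocks (default 0.2).
#' @param lstm_hidden Hidden units per LSTM direction (default 128).
#' @param attention_score Score function: `"perceptron"` (default)
#'   `v'tanh(W q + U k)`, `"dot"` `q'k`, `"general"` `q'W k`, or `"concat"`
#'   `w'[q; k]`.
#' @param attention_dim Hidden width of the perceptron score (default 64).
#' @param epochs Training epochs (default 100).
#' @param batch_size Mini-batch size (default 128).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param val_fraction,test_fraction Held-out fractions of the stratified
#'   beat-level split (defaults 0.1 and 0.1).
#' @param split `"beat"` (default) for a stratified beat-level split or
#'   `"record"` to split by record id.
#' @param seed Integer seed.
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(input_length = 256, n_residual_blocks = 7,
                              channels = c(32, 32, 64, 64, 128, 128, 256),
                              kernel_width = 5, dropout = 0.2,
                              lstm_hidden = 128,
                              attention_score = c("perceptron", "dot",
                                                  "general", "concat"),
                              attention_dim = 64, epochs = 100,
                              batch_size = 128, learning_rate = 1e-3,
                              val_fraction = 0.1, test_fraction = 0.1,
                              split = c("beat", "record"), seed = 1) {
  attention_score <- match.arg(attention_score)
  split <- match.arg(split)
  if (length(channels) != n_residual_blocks) {
    abort("channels must list one width per residual block")
  }
  if (input_length %% 2^n_residual_blocks != 0) {
    abort(paste0("input_length must be divisible by 2^", n_residual_blocks))
  }
  structure(list(input_length = as.integer(input_length),
                 n_residual_blocks = as.integer(n_residual_blocks),
                 channels = as.integer(channels),
                 kernel_width = as.integer(kernel_width), dropout = dropout,
                 lstm_hidden = as.integer(lstm_hidden),
                 attention_score = attention_score,
                 attention_dim = as.integer(attention_dim),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 val_fraction = val_fraction, test_fraction = test_fraction,
                 split = split, seed = as.integer(seed)),
            class = "classifier_config")
}

# ---- residual block ---------------------------------------------------------

#' Initialise residual block parameters
#'
#' @param cin,cout Input/output channel counts.
#' @param k Kernel width.
#' @return Named parameter list; includes a 1x1 projection for the shortcut
#'   when `cin != cout`.
#' @export
residual_block_params <- function(cin, cout, k = 5) {
  p <- list(conv1_W = .he_conv(k, cin, cout), conv1_b = rep(0, cout),
            bn1 = bn_init(cout),
            conv2_W = .he_conv(k, cout, cout), conv2_b = rep(0, cout),
            bn2 = bn_init(cout))
  # zero-init the residual branch's output scale so each block starts as
  # its shortcut; keeps activation variance flat across the stack
  p$bn2$gamma[] <- 0
  if (cin != cout) {
    # variance-preserving 1x1 projection
    p$short_W <- matrix(stats::rnorm(cin * cout, 0, sqrt(1 / cin)),
                        cin, cout)
    p$short_b <- rep(0, cout)
  }
  p
}

.resblock_fwd <- function(X, p, k, dropout, train) {
  c1 <- conv1d_fwd(X, p$conv1_W, p$conv1_b, k)
  b1 <- bn_fwd(c1$out, p$bn1, train)
  p$bn1 <- b1$state
  r1 <- relu_fwd(b1$out)
  d1 <- dropout_fwd(r1$out, dropout, train)
  c2 <- conv1d_fwd(d1$out, p$conv2_W, p$conv2_b, k)
  b2 <- bn_fwd(c2$out, p$bn2, train)
  p$bn2 <- b2$state
  if (is.null(p$short_W)) {
    sh <- X
    shc <- NULL
  } else {
    s <- conv1d_fwd(X, p$short_W, p$short_b, 1L)
    sh <- s$out
    shc <- s$cache
  }
  added <- b2$out + sh
  mp <- maxpool2_fwd(added)
  list(out = mp$out, state = p,
       cache = list(c1 = c1$cache, b1 = b1$cache, r1 = r1$cache,
                    d1 = d1$cache, c2 = c2$cache, b2 = b2$cache,
                    short = shc, pool = mp$cache))
}

.resblock_bwd <- function(dY, p, cache, k, train) {
  bnb <- if (train) bn_bwd else bn_bwd_infer
  dAdd <- maxpool2_bwd(dY, cache$pool)
  # shortcut branch
  if (is.null(p$short_W)) {
    dX_short <- dAdd
    g_short <- NULL
  } else {
    bk <- conv1d_bwd(dAdd, p$short_W, cache$short)
    dX_short <- bk$dX
    g_short <- list(short_W = bk$dW, short_b = bk$db)
  }
  # main branch
  b2 <- bnb(dAdd, p$bn2, cache$b2)
  bk2 <- conv1d_bwd(b2$dX, p$conv2_W, cache$c2)
  dd <- dropout_bwd(bk2$dX, cache$d1)
  dr <- relu_bwd(dd, cache$r1)
  b1 <- bnb(dr, p$bn1, cache$b1)
  bk1 <- conv1d_bwd(b1$dX, p$conv1_W, cache$c1)
  grads <- list(conv1_W = bk1$dW, conv1_b = bk1$db,
                bn1 = list(gamma = b1$dgamma, beta = b1$dbeta),
                conv2_W = bk2$dW, conv2_b = bk2$db,
                bn2 = list(gamma = b2$dgamma, beta = b2$dbeta))
  if (!is.null(g_short)) grads <- c(grads, g_short)
  list(dX = bk1$dX + dX_short, grads = grads)
}

#' Apply one residual block
#'
#' Two convolution + batch-norm layers (ReLU and dropout between them), a
#' shortcut (identity, or 1x1-projected when channel counts differ) added to
#' the second convolution's output, then max pooling of size 2, halving the
#' temporal length.
#'
#' @param x Input features: matrix (length x channels) or array
#'   (batch x length x channels), length >= 2.
#' @param params Parameters from [residual_block_params()].
#' @param k Kernel width (must match the parameters).
#' @param dropout Dropout rate (active only when `train = TRUE`).
#' @param train Training mode flag (batch statistics + dropout).
#' @return Feature array of halved length (same shape convention as input).
#' @export
residual_block <- function(x, params, k = 5, dropout = 0, train = FALSE) {
  vec_in <- length(dim(x)) == 2
  if (vec_in) x <- array(x, c(1, nrow(x), ncol(x)))
  if (dim(x)[2] < 2) abort("input length must be at least the pool size 2")
  out <- .resblock_fwd(x, params, k, dropout, train)$out
  if (vec_in) matrix(out[1, , ], dim(out)[2]) else out
}

# ---- local feature extractor ------------------------------------------------

.local_init <- function(config) {
  ch <- c(1L, config$channels)
  lapply(seq_len(config$n_residual_blocks), function(i) {
    residual_block_params(ch[i], ch[i + 1], config$kernel_width)
  })
}

.local_fwd <- function(X, blocks, config, train) {
  caches <- vector("list", length(blocks))
  for (i in seq_along(blocks)) {
    r <- .resblock_fwd(X, blocks[[i]], config$kernel_width, config$dropout,
                       train)
    X <- r$out
    blocks[[i]] <- r$state
    caches[[i]] <- r$cache
  }
  list(out = X, state = blocks, caches = caches)
}

.local_bwd <- function(dY, blocks, caches, config, train) {
  grads <- vector("list", length(blocks))
  for (i in rev(seq_along(blocks))) {
    r <- .resblock_bwd(dY, blocks[[i]], caches[[i]], config$kernel_width,
                       train)
    dY <- r$dX
    grads[[i]] <- r$grads
  }
  list(dX = dY, grads = grads)
}

#' Extract local features with the stacked residual blocks
#'
#' Applies the configured residual blocks in sequence; each halves the
#' temporal length, so the output length is
#' `input_length / 2^n_residual_blocks`.
#'
#' @param x Padded beat(s): numeric vector of length `config$input_length`,
#'   or a matrix with one padded beat per row.
#' @param blocks Block parameter list (from the internal initialiser or a
#'   trained model's `$params$blocks`).
#' @param config A [classifier_config()].
#' @param train Training mode flag.
#' @return Feature array (batch x reduced length x channels).
#' @export
local_features <- function(x, blocks, config = classifier_config(),
                           train = FALSE) {
  if (is.null(dim(x))) x <- matrix(x, 1)
  if (ncol(x) != config$input_length) {
    abort(paste0("input length ", ncol(x), " != config input_length ",
                 config$input_length,
                 "; pad beats to the configured length first (see pad_beats)"))
  }
  X <- array(x, c(nrow(x), ncol(x), 1))
  .local_fwd(X, blocks, config, train)$out
}

#' Right-pad beats with zeros to the network input length
#'
#' @param m Beat matrix (n x 150) or a single beat vector.
#' @param input_length Target length (default 256).
#' @return Matrix n x `input_length`.
#' @export
pad_beats <- function(m, input_length = 256) {
  if (is.null(dim(m))) m <- matrix(m, 1)
  if (ncol(m) > input_length) abort("beats longer than input_length")
  cbind(m, matrix(0, nrow(m), input_length - ncol(m)))
}

# ---- BiLSTM -----------------------------------------------------------------

#' Bidirectional LSTM over a feature sequence
#'
#' Runs one LSTM pass left-to-right and one right-to-left and concatenates
#' their hidden states at each step.
#'
#' @param features Array (batch x T x d) or matrix (T x d) for a single
#'   instance; T >= 1.
#' @param params_fw,params_bw Forward/backward [lstm_params()].
#' @return Hidden sequence (batch x T x 2*hidden), or (T x 2*hidden) for
#'   single-instance input.
#' @export
bilstm <- function(features, params_fw, params_bw) {
  vec_in <- length(dim(features)) == 2
  if (vec_in) features <- array(features, c(1, dim(features)))
  if (dim(features)[2] < 1) abort("empty sequence")
  fw <- lstm_seq_fwd(features, params_fw, reverse = FALSE)
  bw <- lstm_seq_fwd(features, params_bw, reverse = TRUE)
  d <- dim(fw$out)
  out <- array(0, c(d[1], d[2], 2 * d[3]))
  out[, , 1:d[3]] <- fw$out
  out[, , (d[3] + 1):(2 * d[3])] <- bw$out
  if (vec_in) matrix(out[1, , ], d[2]) else out
}

# ---- attention --------------------------------------------------------------

#' Initialise attention parameters
#'
#' @param dq Query width.
#' @param dk Key width.
#' @param da Hidden width of the perceptron score.
#' @param score Score kind (see [classifier_config()]).
#' @return Named list of weight arrays (empty for `"dot"`).
#' @export
attention_params <- function(dq, dk, da = 64, score = "perceptron") {
  switch(score,
         dot = list(),
         general = list(W_a = .he_dense(dq, dk) * 0.1),
         concat = list(w_cat = stats::rnorm(dq + dk, 0, 0.1)),
         perceptron = list(W_a = .he_dense(dq, da) * 0.1,
                           U_a = .he_dense(dk, da) * 0.1,
                           v_a = stats::rnorm(da, 0, 0.1)),
         abort(paste0("unknown attention score: ", score)))
}

# Batched attention forward. Q (B, dq), K (B, T, dk).
.attention_fwd <- function(Q, K, params, score) {
  B <- nrow(Q); T_ <- dim(K)[2]; dk <- dim(K)[3]
  S <- matrix(0, B, T_)
  cache <- list()
  if (score == "perceptron") {
    QW <- Q %*% params$W_a
    A <- vector("list", T_)
    for (t in seq_len(T_)) {
      A[[t]] <- tanh(QW + matrix(K[, t, ], B) %*% params$U_a)
      S[, t] <- A[[t]] %*% params$v_a
    }
    cache$A <- A; cache$QW <- QW
  } else if (score == "general") {
    QW <- Q %*% params$W_a
    for (t in seq_len(T_)) S[, t] <- rowSums(QW * matrix(K[, t, ], B))
    cache$QW <- QW
  } else if (score == "dot") {
    for (t in seq_len(T_)) S[, t] <- rowSums(Q * matrix(K[, t, ], B))
  } else if (score == "concat") {
    for (t in seq_len(T_)) {
      S[, t] <- cbind(Q, matrix(K[, t, ], B)) %*% params$w_cat
    }
  }
  W <- softmax_rows(S)
  ctx <- matrix(0, B, dk)
  for (t in seq_len(T_)) ctx <- ctx + W[, t] * matrix(K[, t, ], B)
  list(weights = W, context = ctx, cache = cache, S = S)
}

.attention_bwd <- function(dCtx, Q, K, W, params, score, cache) {
  B <- nrow(Q); T_ <- dim(K)[2]; dk <- dim(K)[3]
  dW_t <- matrix(0, B, T_)
  dK <- array(0, dim(K))
  for (t in seq_len(T_)) {
    Kt <- matrix(K[, t, ], B)
    dW_t[, t] <- rowSums(dCtx * Kt)
    dK[, t, ] <- W[, t] * dCtx
  }
  dS <- W * (dW_t - rowSums(dW_t * W))
  dQ <- matrix(0, B, ncol(Q))
  grads <- list()
  if (score == "perceptron") {
    dQW <- matrix(0, B, ncol(cache$QW))
    dUa <- matrix(0, nrow(params$U_a), ncol(params$U_a))
    dva <- numeric(length(params$v_a))
    for (t in seq_len(T_)) {
      At <- cache$A[[t]]
      dAt <- (dS[, t] %o% params$v_a) * (1 - At^2)
      dva <- dva + colSums(At * dS[, t])
      dQW <- dQW + dAt
      Kt <- matrix(K[, t, ], B)
      dUa <- dUa + crossprod(Kt, dAt)
      dK[, t, ] <- dK[, t, ] + dAt %*% t(params$U_a)
    }
    grads$W_a <- crossprod(Q, dQW)
    grads$U_a <- dUa
    grads$v_a <- dva
    dQ <- dQW %*% t(params$W_a)
  } else if (score == "general") {
    dQW <- matrix(0, B, dk)
    for (t in seq_len(T_)) {
      Kt <- matrix(K[, t, ], B)
      dQW <- dQW + dS[, t] * Kt
      dK[, t, ] <- dK[, t, ] + dS[, t] * cache$QW
    }
    grads$W_a <- crossprod(Q, dQW)
    dQ <- dQW %*% t(params$W_a)
  } else if (score == "dot") {
    for (t in seq_len(T_)) {
      Kt <- matrix(K[, t, ], B)
      dQ <- dQ + dS[, t] * Kt
      dK[, t, ] <- dK[, t, ] + dS[, t] * Q
    }
  } else if (score == "concat") {
    dq <- ncol(Q)
    dwc <- numeric(length(params$w_cat))
    for (t in seq_len(T_)) {
      Kt <- matrix(K[, t, ], B)
      dQ <- dQ + dS[, t] %o% params$w_cat[1:dq]
      dK[, t, ] <- dK[, t, ] + dS[, t] %o% params$w_cat[(dq + 1):(dq + dk)]
      dwc <- dwc + colSums(dS[, t] * cbind(Q, Kt))
    }
    grads$w_cat <- dwc
  }
  list(dQ = dQ, dK = dK, grads = grads)
}

#' Attention pooling over a key sequence
#'
#' Computes query-key compatibility scores (four selectable score
#' functions), normalises them with softmax and returns the weights together
#' with the weighted sum of the keys (the context vector).
#'
#' @param Q Query vector (length dq), or matrix (batch x dq).
#' @param K Key matrix (T x dk) for a single instance, or array
#'   (batch x T x dk); at least one key.
#' @param params Parameters from [attention_params()].
#' @param score Score kind.
#' @return List with `weights` (summing to 1 over keys) and `context`.
#' @export
attention <- function(Q, K, params = list(),
                      score = c("perceptron", "dot", "general", "concat")) {
  score <- match.arg(score)
  vec_in <- is.null(dim(Q))
  if (vec_in) {
    Q <- matrix(Q, 1)
    K <- array(K, c(1, dim(K)))
  }
  if (dim(K)[2] < 1) abort("attention needs at least one key")
  r <- .attention_fwd(Q, K, params, score)
  if (vec_in) list(weights = drop(r$weights), context = drop(r$context))
  else list(weights = r$weights, context = r$context)
}

# ---- full model -------------------------------------------------------------

.classifier_init <- function(config, with_attention) {
  set.seed(config$seed)
  blocks <- .local_init(config)
  C7 <- config$channels[config$n_residual_blocks]
  H <- config$lstm_hidden
  params <- list(blocks = blocks,
                 lstm_fw = lstm_params(C7, H),
                 lstm_bw = lstm_params(C7, H),
                 att = attention_params(2 * H, 2 * H, config$attention_dim,
                                        config$attention_score),
                 fuse_W = .he_dense(2 * H + C7, 5),
                 fuse_b = rep(0, 5))
  structure(list(params = params, config = config,
                 with_attention = isTRUE(with_attention),
                 classes = aami_classes(),
                 history = tibble(epoch = integer(0), train_loss = numeric(0),
                                  train_acc = numeric(0),
                                  val_loss = numeric(0),
                                  val_acc = numeric(0))),
            class = "ecg_classifier")
}

#' @export
print.ecg_classifier <- function(x, ...) {
  cat(sprintf(
    "<ecg_classifier: %d residual blocks, lstm %d, %s, %d epochs trained>\n",
    x$config$n_residual_blocks, x$config$lstm_hidden,
    if (x$with_attention) paste0("attention (", x$config$attention_score, ")")
    else "mean-pooling ablation",
    nrow(x$history)))
  invisible(x)
}

# Full forward pass. X is (B, input_length). Returns logits and caches.
.clf_fwd <- function(params, X, config, with_attention, train) {
  B <- nrow(X)
  A <- array(X, c(B, config$input_length, 1))
  lf <- .local_fwd(A, params$blocks, config, train)
  Fmap <- lf$out                      # (B, T, C)
  T_ <- dim(Fmap)[2]; C <- dim(Fmap)[3]
  fw <- lstm_seq_fwd(Fmap, params$lstm_fw, reverse = FALSE)
  bw <- lstm_seq_fwd(Fmap, params$lstm_bw, reverse = TRUE)
  H <- config$lstm_hidden
  Hseq <- array(0, c(B, T_, 2 * H))
  Hseq[, , 1:H] <- fw$out
  Hseq[, , (H + 1):(2 * H)] <- bw$out
  if (with_attention) {
    # query: final forward state joined with the initial backward state
    Q <- cbind(matrix(fw$out[, T_, ], B), matrix(bw$out[, 1, ], B))
    at <- .attention_fwd(Q, Hseq, params$att, config$attention_score)
    ctx <- at$context
  } else {
    Q <- NULL; at <- NULL
    ctx <- matrix(0, B, 2 * H)
    for (t in seq_len(T_)) ctx <- ctx + matrix(Hseq[, t, ], B) / T_
  }
  gap <- matrix(0, B, C)
  for (t in seq_len(T_)) gap <- gap + matrix(Fmap[, t, ], B) / T_
  feat <- cbind(ctx, gap)
  dn <- dense_fwd(feat, params$fuse_W, params$fuse_b)
  list(logits = dn$out,
       cache = list(local = lf, fw = fw, bw = bw, Hseq = Hseq, Q = Q,
                    at = at, gap_T = T_, Fmap = Fmap, feat = feat,
                    dense = dn$cache),
       blocks_state = lf$state)
}

.clf_bwd <- function(params, dLogits, cache, config, with_attention, train) {
  B <- nrow(dLogits)
  H <- config$lstm_hidden
  T_ <- cache$gap_T
  C <- dim(cache$Fmap)[3]
  dn <- dense_bwd(dLogits, params$fuse_W, cache$dense)
  grads <- list(fuse_W = dn$dW, fuse_b = dn$db)
  dCtx <- dn$dX[, 1:(2 * H), drop = FALSE]
  dGap <- dn$dX[, (2 * H + 1):(2 * H + C), drop = FALSE]
  dHseq <- array(0, c(B, T_, 2 * H))
  dQ <- matrix(0, B, 2 * H)
  if (with_attention) {
    ab <- .attention_bwd(dCtx, cache$Q, cache$Hseq, cache$at$weights,
                         params$att, config$attention_score, cache$at$cache)
    grads$att <- ab$grads
    dHseq <- dHseq + ab$dK
    dQ <- ab$dQ
  } else {
    for (t in seq_len(T_)) dHseq[, t, ] <- dHseq[, t, ] + dCtx / T_
  }
  dFw <- dHseq[, , 1:H, drop = FALSE]
  dBw <- dHseq[, , (H + 1):(2 * H), drop = FALSE]
  # query gradient feeds the last forward / first backward step
  dFw[, T_, ] <- dFw[, T_, ] + dQ[, 1:H]
  dBw[, 1, ] <- dBw[, 1, ] + dQ[, (H + 1):(2 * H)]
  bfw <- lstm_seq_bwd(dFw, cache$fw, params$lstm_fw)
  bbw <- lstm_seq_bwd(dBw, cache$bw, params$lstm_bw)
  grads$lstm_fw <- bfw$grads
  grads$lstm_bw <- bbw$grads
  dFmap <- bfw$dX + bbw$dX
  for (t in seq_len(T_)) dFmap[, t, ] <- dFmap[, t, ] + dGap / T_
  lb <- .local_bwd(dFmap, params$blocks, cache$local$caches, config, train)
  grads$blocks <- lb$grads
  grads
}

#' Classify beats
#'
#' Pads each beat to the network input length, runs the full model in
#' inference mode and returns per-class probabilities (summing to 1) and the
#' argmax class.
#'
#' @param model A trained (or initialised) `ecg_classifier`.
#' @param beats A beat tibble, a numeric beat matrix (n x 150), or a single
#'   length-150 beat.
#' @param normalize Z-score beats first (default `TRUE`; matches training).
#' @return Tibble with `.pred_class` and probability columns
#'   `.prob_N ... .prob_Q`.
#' @export
classify_beats <- function(model, beats, normalize = TRUE) {
  stopifnot(inherits(model, "ecg_classifier"))
  m <- if (is.data.frame(beats)) beat_matrix(beats) else
    if (is.null(dim(beats))) matrix(beats, 1) else beats
  if (ncol(m) != BEAT_LEN) {
    abort(paste0("beats must have length ", BEAT_LEN))
  }
  if (normalize) m <- t(apply(m, 1, zscore))
  X <- pad_beats(m, model$config$input_length)
  P <- matrix(0, nrow(X), 5)
  bs <- 512L
  for (s in seq(1, nrow(X), bs)) {
    e <- min(s + bs - 1, nrow(X))
    r <- .clf_fwd(model$params, X[s:e, , drop = FALSE], model$config,
                  model$with_attention, train = FALSE)
    P[s:e, ] <- softmax_rows(r$logits)
  }
  colnames(P) <- paste0(".prob_", model$classes)
  out <- as_tibble(as.data.frame(P))
  out$.pred_class <- factor(model$classes[max.col(P)],
                            levels = model$classes)
  out[, c(".pred_class", paste0(".prob_", model$classes))]
}

#' @export
predict.ecg_classifier <- function(object, newdata, ...) {
  classify_beats(object, newdata, ...)
}

# Stratified train/val/test assignment. Generated beats always train.
.split_beats <- function(beats, config) {
  set.seed(config$seed + 7L)
  n <- nrow(beats)
  assign <- rep("train", n)
  if (identical(config$split, "record")) {
    ids <- unique(beats$record_id)
    ids <- sample(ids)
    n_test <- max(1, round(length(ids) * config$test_fraction))
    n_val <- max(1, round(length(ids) * config$val_fraction))
    test_ids <- ids[seq_len(n_test)]
    val_ids <- ids[n_test + seq_len(n_val)]
    assign[beats$record_id %in% test_ids] <- "test"
    assign[beats$record_id %in% val_ids] <- "val"
  } else {
    for (cls in unique(beats$label)) {
      idx <- which(beats$label == cls & beats$source != "generated")
      idx <- sample(idx)
      n_test <- round(length(idx) * config$test_fraction)
      n_val <- round(length(idx) * config$val_fraction)
      if (n_test) assign[idx[seq_len(n_test)]] <- "test"
      if (n_val) assign[idx[n_test + seq_len(n_val)]] <- "val"
    }
  }
  assign[beats$source == "generated"] <- "train"
  assign
}

#' Train the beat classifier
#'
#' Cross-entropy training with Adam on z-scored, zero-padded beats. The
#' dataset is split into train/validation/test partitions (generated beats
#' are confined to training); accuracy and loss on train and validation are
#' recorded each epoch. With `with_attention = FALSE` the attention context
#' is replaced by mean pooling over the BiLSTM outputs — the ablation
#' variant — leaving everything else identical.
#'
#' @param beats A labeled beat tibble with at least two classes.
#' @param config A [classifier_config()].
#' @param with_attention Use the attention mechanism (default `TRUE`).
#' @return A trained `ecg_classifier`; the split assignment is attached as
#'   `$split` and per-epoch history as `$history`.
#' @export
train_classifier <- function(beats, config = classifier_config(),
                             with_attention = TRUE) {
  beats <- beats[!is.na(beats$label), ]
  if (length(unique(beats$label)) < 2) {
    abort("training needs at least two classes")
  }
  model <- .classifier_init(config, with_attention)
  split <- .split_beats(beats, config)
  model$split <- split
  if (config$epochs == 0) return(model)

  m <- beat_matrix(normalize_beats(beats))
  X <- pad_beats(m, config$input_length)
  y <- match(beats$label, model$classes)
  tr <- which(split == "train")
  va <- which(split == "val")
  if (!length(va)) va <- tr
  opt <- adam_init(model$params)
  hist <- matrix(0, config$epochs, 4)
  set.seed(config$seed + 13L)
  for (ep in seq_len(config$epochs)) {
    ord <- sample(tr)
    tl <- 0; tn <- 0; tc <- 0
    for (s in seq(1, length(ord), config$batch_size)) {
      bi <- ord[s:min(s + config$batch_size - 1, length(ord))]
      r <- .clf_fwd(model$params, X[bi, , drop = FALSE], config,
                    with_attention, train = TRUE)
      model$params$blocks <- r$blocks_state   # BN running stats
      ce <- xent_fwd_bwd(r$logits, y[bi])
      grads <- .clf_bwd(model$params, ce$dZ, r$cache, config,
                        with_attention, train = TRUE)
      st <- adam_step(model$params, grads, opt, config$learning_rate)
      model$params <- st$params
      opt <- st$state
      tl <- tl + ce$loss * length(bi); tn <- tn + length(bi)
      tc <- tc + sum(max.col(ce$P) == y[bi])
    }
    ev <- .clf_eval(model, X[va, , drop = FALSE], y[va])
    hist[ep, ] <- c(tl / tn, tc / tn, ev$loss, ev$acc)
  }
  model$history <- tibble(epoch = seq_len(config$epochs),
                          train_loss = hist[, 1], train_acc = hist[, 2],
                          val_loss = hist[, 3], val_acc = hist[, 4])
  model
}

.clf_eval <- function(model, X, y) {
  loss <- 0; acc <- 0; n <- nrow(X)
  bs <- 512L
  for (s in seq(1, n, bs)) {
    e <- min(s + bs - 1, n)
    r <- .clf_fwd(model$params, X[s:e, , drop = FALSE], model$config,
                  model$with_attention, train = FALSE)
    ce <- xent_fwd_bwd(r$logits, y[s:e])
    loss <- loss + ce$loss * (e - s + 1)
    acc <- acc + sum(max.col(ce$P) == y[s:e])
  }
  list(loss = loss / n, acc = acc / n)
}

#' Evaluate a trained classifier on its held-out test partition
#'
#' @param model A trained `ecg_classifier` (with `$split`).
#' @param beats The beat tibble the model was trained on.
#' @param partition `"test"` (default) or `"val"`.
#' @return Tibble with `truth`, `estimate` and probability columns.
#' @export
holdout_predictions <- function(model, beats, partition = "test") {
  beats <- beats[!is.na(beats$label), ]
  idx <- which(model$split == partition)
  if (!length(idx)) abort(paste0("empty partition: ", partition))
  preds <- classify_beats(model, beats[idx, ])
  dplyr::bind_cols(tibble(truth = factor(beats$label[idx],
                                         levels = model$classes)), preds)
}

#' @export
tidy.ecg_classifier <- function(x, ...) x$history

#' @export
glance.ecg_classifier <- function(x, ...) {
  h <- x$history
  count_params <- function(p) {
    if (is.list(p)) sum(vapply(p, count_params, numeric(1)))
    else length(p)
  }
  tibble(epochs = nrow(h),
         final_train_acc = if (nrow(h)) h$train_acc[nrow(h)] else NA_real_,
         final_val_acc = if (nrow(h)) h$val_acc[nrow(h)] else NA_real_,
         with_attention = x$with_attention,
         n_params = count_params(x$params))
}

#' @export
autoplot.ecg_classifier <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, -"epoch",
                           names_to = c("partition", "metric"),
                           names_sep = "_", values_to = "value")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value,
                                  colour = .data$partition)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
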