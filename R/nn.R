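# Minimal neural-network core used by the GAN and the classifier: 1D
# convolution (im2col + BLAS), batch normalisation, max pooling, nearest
# upsampling, dense layers, LSTM cells and Adam, each with a hand-written
# backward pass. Batched signals are stored as arrays of dim (batch, length,
# channels); parameters as plain matrices/vectors in named lists.

# ---- initialisers -----------------------------------------------------------

.he_conv <- function(k, cin, cout) {
  matrix(stats::rnorm(k * cin * cout, 0, sqrt(2 / (k * cin))), k * cin, cout)
}
.he_dense <- function(din, dout) {
  matrix(stats::rnorm(din * dout, 0, sqrt(2 / din)), din, dout)
}
.lstm_mat <- function(din, h) {
  matrix(stats::runif(din * h, -1, 1) / sqrt(h), din, h)
}

# ---- conv1d ("same" padding, stride 1) --------------------------------------

conv1d_fwd <- function(X, W, b, k) {
  d <- dim(X); B <- d[1]; L <- d[2]; Cin <- d[3]
  Cout <- length(b)
  pl <- (k - 1) %/% 2
  Xp <- array(0, c(B, L + k - 1, Cin))
  Xp[, (pl + 1):(pl + L), ] <- X
  M <- matrix(0, B * L, Cin * k)
  for (j in seq_len(k)) {
    M[, ((j - 1) * Cin + 1):(j * Cin)] <- Xp[, j:(j + L - 1), ]
  }
  Y <- M %*% W
  Y <- Y + rep(b, each = B * L)
  list(out = array(Y, c(B, L, Cout)),
       cache = list(M = M, dims = d, k = k, pl = pl))
}

conv1d_bwd <- function(dY, W, cache) {
  d <- cache$dims; B <- d[1]; L <- d[2]; Cin <- d[3]
  k <- cache$k; pl <- cache$pl
  dYm <- matrix(dY, B * L)
  dW <- crossprod(cache$M, dYm)
  db <- colSums(dYm)
  dM <- dYm %*% t(W)
  dXp <- array(0, c(B, L + k - 1, Cin))
  for (j in seq_len(k)) {
    dXp[, j:(j + L - 1), ] <- dXp[, j:(j + L - 1), , drop = FALSE] +
      array(dM[, ((j - 1) * Cin + 1):(j * Cin)], c(B, L, Cin))
  }
  list(dX = dXp[, (pl + 1):(pl + L), , drop = FALSE], dW = dW, db = db)
}

# ---- batch normalisation (per channel over batch x length) ------------------

bn_init <- function(C) {
  list(gamma = rep(1, C), beta = rep(0, C),
       run_mean = rep(0, C), run_var = rep(1, C))
}

bn_fwd <- function(X, p, train, momentum = 0.1, eps = 1e-5) {
  d <- dim(X); C <- d[3]; m <- d[1] * d[2]
  Xm <- matrix(X, m, C)
  if (train) {
    mu <- colMeans(Xm)
    v <- colMeans(Xm^2) - mu^2
    p$run_mean <- (1 - momentum) * p$run_mean + momentum * mu
    p$run_var <- (1 - momentum) * p$run_var + momentum * v * m / max(m - 1, 1)
  } else {
    mu <- p$run_mean; v <- p$run_var
  }
  ivar <- 1 / sqrt(v + eps)
  xhat <- (Xm - rep(mu, each = m)) * rep(ivar, each = m)
  Y <- xhat * rep(p$gamma, each = m) + rep(p$beta, each = m)
  list(out = array(Y, d), state = p,
       cache = list(xhat = xhat, ivar = ivar, dims = d))
}

bn_bwd <- function(dY, p, cache) {
  d <- cache$dims; C <- d[3]; m <- d[1] * d[2]
  dYm <- matrix(dY, m, C)
  xhat <- cache$xhat
  dgamma <- colSums(dYm * xhat)
  dbeta <- colSums(dYm)
  dxhat <- dYm * rep(p$gamma, each = m)
  dX <- (dxhat - rep(colMeans(dxhat), each = m) -
           xhat * rep(colMeans(dxhat * xhat), each = m)) *
    rep(cache$ivar, each = m)
  list(dX = array(dX, d), dgamma = dgamma, dbeta = dbeta)
}

# inference-path normalisation gradient (running stats are constants)
bn_bwd_infer <- function(dY, p, cache) {
  d <- cache$dims; C <- d[3]; m <- d[1] * d[2]
  dYm <- matrix(dY, m, C)
  dgamma <- colSums(dYm * cache$xhat)
  dbeta <- colSums(dYm)
  dX <- dYm * rep(p$gamma * cache$ivar, each = m)
  list(dX = array(dX, d), dgamma = dgamma, dbeta = dbeta)
}

# ---- activations / dropout --------------------------------------------------

relu_fwd <- function(X) {
  mask <- X > 0
  list(out = X * mask, cache = mask)
}
relu_bwd <- function(dY, mask) dY * mask

lrelu_fwd <- function(X, alpha = 0.2) {
  mask <- X > 0
  list(out = ifelse(mask, X, alpha * X), cache = mask, alpha = alpha)
}
lrelu_bwd <- function(dY, mask, alpha = 0.2) ifelse(mask, dY, alpha * dY)

dropout_fwd <- function(X, rate, train) {
  if (!train || rate <= 0) return(list(out = X, cache = NULL))
  mask <- (stats::runif(length(X)) > rate) / (1 - rate)
  dim(mask) <- dim(X)
  list(out = X * mask, cache = mask)
}
dropout_bwd <- function(dY, mask) if (is.null(mask)) dY else dY * mask

sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- max pooling (size 2) ---------------------------------------------------

maxpool2_fwd <- function(X) {
  d <- dim(X); L <- d[2]
  if (L < 2) abort("sequence too short for pool size 2")
  Lh <- L %/% 2
  Xo <- X[, seq(1, 2 * Lh, 2), , drop = FALSE]
  Xe <- X[, seq(2, 2 * Lh, 2), , drop = FALSE]
  mask <- Xo >= Xe  # ties break to the left sample
  list(out = Xo * mask + Xe * !mask, cache = list(mask = mask, L = L))
}

maxpool2_bwd <- function(dY, cache) {
  mask <- cache$mask
  d <- dim(mask); Lh <- d[2]
  dX <- array(0, c(d[1], cache$L, d[3]))
  dX[, seq(1, 2 * Lh, 2), ] <- dY * mask
  dX[, seq(2, 2 * Lh, 2), ] <- dY * !mask
  dX
}

# ---- nearest-neighbour upsampling ------------------------------------------

upsample_fwd <- function(X, f) {
  d <- dim(X)
  list(out = X[, rep(seq_len(d[2]), each = f), , drop = FALSE], f = f)
}

upsample_bwd <- function(dY, f) {
  d <- dim(dY); B <- d[1]; Lf <- d[2]; C <- d[3]; L <- Lf %/% f
  dYr <- array(dY, c(B, f, L, C))
  dX <- array(0, c(B, L, C))
  for (j in seq_len(f)) {
    dX <- dX + array(dYr[, j, , , drop = FALSE], c(B, L, C))
  }
  dX
}

# ---- dense ------------------------------------------------------------------

dense_fwd <- function(X, W, b) {
  list(out = X %*% W + rep(b, each = nrow(X)), cache = X)
}
dense_bwd <- function(dY, W, cache) {
  list(dX = dY %*% t(W), dW = crossprod(cache, dY), db = colSums(dY))
}

# ---- softmax / cross-entropy ------------------------------------------------

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# returns loss and gradient at the logits
xent_fwd_bwd <- function(Z, y_idx) {
  P <- softmax_rows(Z)
  B <- nrow(Z)
  eps <- 1e-12
  loss <- -mean(log(pmax(P[cbind(seq_len(B), y_idx)], eps)))
  dZ <- P
  dZ[cbind(seq_len(B), y_idx)] <- dZ[cbind(seq_len(B), y_idx)] - 1
  list(loss = loss, dZ = dZ / B, P = P)
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  zero <- function(p) {
    if (is.list(p)) lapply(p, zero) else array(0, dim(p) %||% length(p))
  }
  list(m = lapply(params, zero), v = lapply(params, zero), t = 0)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  t <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- list(p = p, m = m, v = v)
      for (nm in names(p)) {
        if (is.null(g[[nm]])) next
        r <- upd(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out$p[[nm]] <- r$p; out$m[[nm]] <- r$m; out$v[[nm]] <- r$v
      }
      out
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      mh <- m / (1 - beta1^t)
      vh <- v / (1 - beta2^t)
      list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
    }
  }
  r <- upd(params, grads, state$m, state$v)
  state$m <- r$m; state$v <- r$v
  list(params = r$p, state = state)
}

# ---- LSTM -------------------------------------------------------------------

#' Initialise LSTM cell parameters
#'
#' Per-gate input weights `u_*` (`d_in` x `hidden`), recurrent weights `w_*`
#' (`hidden` x `hidden`) and biases `b_*` for the forget (f), input (i),
#' candidate (c) and output (o) gates.
#'
#' @param d_in Input feature width.
#' @param hidden Hidden state width.
#' @return Named list of parameter arrays.
#' @export
lstm_params <- function(d_in, hidden) {
  p <- list()
  for (g in c("f", "i", "c", "o")) {
    p[[paste0("u_", g)]] <- .lstm_mat(d_in, hidden)
    p[[paste0("w_", g)]] <- .lstm_mat(hidden, hidden)
    p[[paste0("b_", g)]] <- rep(0, hidden)
  }
  p$b_f <- rep(1, hidden)  # standard forget-gate bias
  p
}

#' One LSTM time step
#'
#' Gated recurrent update: forget, input and output gates are sigmoids of
#' affine maps of the input and previous hidden state; the cell candidate
#' uses tanh; the new cell state is `f * c_prev + i * candidate` and the
#' hidden state `o * tanh(c)`.
#'
#' @param x_n Input at this step: numeric vector (one instance) or matrix
#'   (batch x d_in).
#' @param h_prev,c_prev Previous hidden and cell state, same shape
#'   convention as `x_n` with width `hidden`.
#' @param params Parameters from [lstm_params()].
#' @return List with `h`, `c` (matrices batch x hidden; vectors in, vectors
#'   out) and `gates` (cached activations).
#' @export
lstm_step <- function(x_n, h_prev, c_prev, params) {
  vec_in <- is.null(dim(x_n))
  if (vec_in) {
    x_n <- matrix(x_n, 1); h_prev <- matrix(h_prev, 1)
    c_prev <- matrix(c_prev, 1)
  }
  if (ncol(x_n) != nrow(params$u_f) || ncol(h_prev) != nrow(params$w_f)) {
    abort("lstm_step: input/hidden widths do not match the parameters")
  }
  B <- nrow(x_n)
  aff <- function(u, w, b) x_n %*% u + h_prev %*% w + rep(b, each = B)
  f <- sigmoid(aff(params$u_f, params$w_f, params$b_f))
  i <- sigmoid(aff(params$u_i, params$w_i, params$b_i))
  g <- tanh(aff(params$u_c, params$w_c, params$b_c))
  o <- sigmoid(aff(params$u_o, params$w_o, params$b_o))
  c_n <- f * c_prev + i * g
  hc <- tanh(c_n)
  h_n <- o * hc
  out <- list(h = h_n, c = c_n,
              gates = list(f = f, i = i, g = g, o = o, hc = hc,
                           x = x_n, h_prev = h_prev, c_prev = c_prev))
  if (vec_in) { out$h <- drop(out$h); out$c <- drop(out$c) }
  out
}

# Backward through one step. dh, dc are gradients flowing into h_n, c_n.
lstm_step_bwd <- function(dh, dc, gates, params) {
  g <- gates
  do_ <- dh * g$hc
  dcn <- dc + dh * g$o * (1 - g$hc^2)
  df <- dcn * g$c_prev
  dc_prev <- dcn * g$f
  di <- dcn * g$g
  dg <- dcn * g$i
  daf <- df * g$f * (1 - g$f)
  dai <- di * g$i * (1 - g$i)
  dag <- dg * (1 - g$g^2)
  dao <- do_ * g$o * (1 - g$o)
  dx <- daf %*% t(params$u_f) + dai %*% t(params$u_i) +
    dag %*% t(params$u_c) + dao %*% t(params$u_o)
  dh_prev <- daf %*% t(params$w_f) + dai %*% t(params$w_i) +
    dag %*% t(params$w_c) + dao %*% t(params$w_o)
  grads <- list(
    u_f = crossprod(g$x, daf), w_f = crossprod(g$h_prev, daf),
    b_f = colSums(daf),
    u_i = crossprod(g$x, dai), w_i = crossprod(g$h_prev, dai),
    b_i = colSums(dai),
    u_c = crossprod(g$x, dag), w_c = crossprod(g$h_prev, dag),
    b_c = colSums(dag),
    u_o = crossprod(g$x, dao), w_o = crossprod(g$h_prev, dao),
    b_o = colSums(dao))
  list(dx = dx, dh_prev = dh_prev, dc_prev = dc_prev, grads = grads)
}

# Unidirectional pass over a (B, T, D) array; returns (B, T, H) plus caches.
lstm_seq_fwd <- function(X, params, reverse = FALSE) {
  d <- dim(X); B <- d[1]; T_ <- d[2]
  H <- ncol(params$w_f)
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  out <- array(0, c(B, T_, H))
  caches <- vector("list", T_)
  steps <- if (reverse) rev(seq_len(T_)) else seq_len(T_)
  for (t in steps) {
    st <- lstm_step(matrix(X[, t, ], B), h, cc, params)
    h <- st$h; cc <- st$c
    out[, t, ] <- h
    caches[[t]] <- st$gates
  }
  list(out = out, caches = caches, steps = steps)
}

lstm_seq_bwd <- function(dOut, fwd, params) {
  d <- dim(dOut); B <- d[1]; T_ <- d[2]
  H <- ncol(params$w_f)
  dX <- NULL
  dh <- matrix(0, B, H); dc <- matrix(0, B, H)
  grads <- NULL
  for (t in rev(fwd$steps)) {
    dh <- dh + matrix(dOut[, t, ], B)
    bk <- lstm_step_bwd(dh, dc, fwd$caches[[t]], params)
    dh <- bk$dh_prev; dc <- bk$dc_prev
    if (is.null(dX)) dX <- array(0, c(B, T_, ncol(bk$dx)))
    dX[, t, ] <- bk$dx
    grads <- if (is.null(grads)) bk$grads else
      purrr::map2(grads, bk$grads, `+`)
  }
  list(dX = dX, grads = grads)
}

# gradient-descent-free accumulation helper for nested grad lists
acc_grads <- function(a, b) {
  if (is.null(a)) return(b)
  purrr::map2(a, b, function(x, y) if (is.list(x)) acc_grads(x, y) else x + y)
}
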