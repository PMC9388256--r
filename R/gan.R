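# 1D convolutional GAN for heartbeat synthesis. The generator projects a
# 100-dim latent vector to a length-1 x 128-channel feature, then four
# upsample+convolution blocks (factors 5,5,3,2 -> length 150, channels
# halving 128 -> 8) and a final width-6 convolution to one channel. The
# discriminator mirrors it: four width-6 convolution + LeakyReLU + pool
# blocks (channels 8 -> 64) and a sigmoid output unit.

#' GAN configuration
#'
#' @param latent_dim Latent vector width (default 100).
#' @param projected_width Channels after projecting the latent vector to a
#'   length-1 feature map (default 128).
#' @param kernel_width Convolution kernel width (default 6).
#' @param upsample_factors Four upsampling factors whose product is the beat
#'   length 150 (default `c(5, 5, 3, 2)`).
#' @param generator_channels Channel plan after each of the four
#'   deconvolution blocks (default `c(64, 32, 16, 8)`, halving from the
#'   projected 128).
#' @param dropout Generator dropout rate (default 0.4).
#' @param final_activation `"linear"` (default, suits z-scored beats) or
#'   `"tanh"`.
#' @param loss `"non_saturating"` (default) or `"minimax"` generator loss.
#' @param learning_rate Adam learning rate (default 2e-4; the much larger
#'   0.1 is selectable but diverges on this architecture).
#' @param adam_beta1 Adam first-moment decay (default 0.5, the standard
#'   setting for adversarial training).
#' @param iterations Training iterations (default 1000).
#' @param batch_size Mini-batch size (default 32).
#' @param seed Integer seed.
#' @return A `gan_config` list.
#' @export
gan_config <- function(latent_dim = 100, projected_width = 128,
                       kernel_width = 6, upsample_factors = c(5, 5, 3, 2),
                       generator_channels = c(64, 32, 16, 8), dropout = 0.4,
                       final_activation = c("linear", "tanh"),
                       loss = c("non_saturating", "minimax"),
                       learning_rate = 2e-4, adam_beta1 = 0.5,
                       iterations = 1000, batch_size = 32, seed = 1) {
  final_activation <- match.arg(final_activation)
  loss <- match.arg(loss)
  if (prod(upsample_factors) != BEAT_LEN) {
    abort("product of upsample_factors must equal the beat length 150")
  }
  if (dropout < 0 || dropout >= 1) abort("dropout must be in [0, 1)")
  structure(list(latent_dim = latent_dim, projected_width = projected_width,
                 kernel_width = kernel_width,
                 upsample_factors = upsample_factors,
                 generator_channels = generator_channels, dropout = dropout,
                 final_activation = final_activation, loss = loss,
                 learning_rate = learning_rate, adam_beta1 = adam_beta1,
                 iterations = as.integer(iterations),
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "gan_config")
}

# discriminator channel plan mirrors the generator, doubling 8 -> 64
.disc_channels <- function(config) rev(config$generator_channels)

gan_init <- function(config = gan_config()) {
  set.seed(config$seed)
  k <- config$kernel_width
  chans <- c(config$projected_width, config$generator_channels)
  G <- list(proj_W = .he_dense(config$latent_dim, config$projected_width),
            proj_b = rep(0, config$projected_width))
  for (i in seq_along(config$upsample_factors)) {
    G[[paste0("conv", i, "_W")]] <- .he_conv(k, chans[i], chans[i + 1])
    G[[paste0("conv", i, "_b")]] <- rep(0, chans[i + 1])
  }
  G$out_W <- .he_conv(k, chans[length(chans)], 1)
  G$out_b <- 0
  dch <- c(1, .disc_channels(config))
  D <- list()
  for (i in seq_along(.disc_channels(config))) {
    D[[paste0("conv", i, "_W")]] <- .he_conv(k, dch[i], dch[i + 1])
    D[[paste0("conv", i, "_b")]] <- rep(0, dch[i + 1])
  }
  d_len <- BEAT_LEN
  for (i in seq_along(.disc_channels(config))) d_len <- d_len %/% 2
  D$out_W <- .he_dense(d_len * dch[length(dch)], 1)
  D$out_b <- 0
  structure(list(G = G, D = D, config = config,
                 history = tibble(iteration = integer(0),
                                  d_loss = numeric(0), g_loss = numeric(0))),
            class = "ecg_gan")
}

#' @export
print.ecg_gan <- function(x, ...) {
  cat(sprintf("<ecg_gan: latent %d, %d iterations trained>\n",
              x$config$latent_dim, nrow(x$history)))
  invisible(x)
}

# Generator forward; returns (B, 150) plus caches for backprop.
.gen_fwd <- function(G, Z, config, train) {
  B <- nrow(Z)
  caches <- list()
  dn <- dense_fwd(Z, G$proj_W, G$proj_b)
  caches$proj <- dn$cache
  X <- array(dn$out, c(B, 1, config$projected_width))
  for (i in seq_along(config$upsample_factors)) {
    f <- config$upsample_factors[i]
    up <- upsample_fwd(X, f)
    cv <- conv1d_fwd(up$out, G[[paste0("conv", i, "_W")]],
                     G[[paste0("conv", i, "_b")]], config$kernel_width)
    rl <- relu_fwd(cv$out)
    dp <- dropout_fwd(rl$out, config$dropout, train)
    caches[[paste0("blk", i)]] <- list(f = f, conv = cv$cache,
                                       relu = rl$cache, drop = dp$cache)
    X <- dp$out
  }
  cv <- conv1d_fwd(X, G$out_W, matrix(G$out_b), config$kernel_width)
  caches$out <- cv$cache
  Y <- cv$out
  if (config$final_activation == "tanh") {
    Y <- tanh(Y)
    caches$tanh <- Y
  }
  list(out = matrix(Y, B, BEAT_LEN), caches = caches)
}

.gen_bwd <- function(G, dOut, caches, config) {
  B <- nrow(dOut)
  dY <- array(dOut, c(B, BEAT_LEN, 1))
  if (config$final_activation == "tanh") {
    dY <- dY * (1 - caches$tanh^2)
  }
  grads <- list()
  bk <- conv1d_bwd(dY, G$out_W, caches$out)
  grads$out_W <- bk$dW; grads$out_b <- bk$db
  dX <- bk$dX
  for (i in rev(seq_along(config$upsample_factors))) {
    cc <- caches[[paste0("blk", i)]]
    dX <- dropout_bwd(dX, cc$drop)
    dX <- relu_bwd(dX, cc$relu)
    bk <- conv1d_bwd(dX, G[[paste0("conv", i, "_W")]], cc$conv)
    grads[[paste0("conv", i, "_W")]] <- bk$dW
    grads[[paste0("conv", i, "_b")]] <- bk$db
    dX <- upsample_bwd(bk$dX, cc$f)
  }
  dn <- dense_bwd(matrix(dX, B), G$proj_W, caches$proj)
  grads$proj_W <- dn$dW; grads$proj_b <- dn$db
  grads
}

# Discriminator forward; X is (B, 150). Returns probabilities in (0, 1).
.disc_fwd <- function(D, X, config) {
  B <- nrow(X)
  A <- array(X, c(B, BEAT_LEN, 1))
  caches <- list()
  nblk <- length(.disc_channels(config))
  for (i in seq_len(nblk)) {
    cv <- conv1d_fwd(A, D[[paste0("conv", i, "_W")]],
                     D[[paste0("conv", i, "_b")]], config$kernel_width)
    lr <- lrelu_fwd(cv$out)
    mp <- maxpool2_fwd(lr$out)
    caches[[paste0("blk", i)]] <- list(conv = cv$cache, lrelu = lr$cache,
                                       pool = mp$cache)
    A <- mp$out
  }
  flat <- matrix(A, B)
  caches$flat_dim <- dim(A)
  dn <- dense_fwd(flat, D$out_W, matrix(D$out_b))
  caches$out <- dn$cache
  z <- dn$out
  p <- sigmoid(z)
  # keep probabilities strictly inside (0, 1)
  eps <- 1e-7
  list(p = pmin(pmax(as.numeric(p), eps), 1 - eps), z = as.numeric(z),
       caches = caches)
}

# Backward from gradient at the pre-sigmoid logit.
.disc_bwd <- function(D, dz, caches, config) {
  B <- length(dz)
  dn <- dense_bwd(matrix(dz, B, 1), D$out_W, caches$out)
  grads <- list(out_W = dn$dW, out_b = dn$db)
  dA <- array(dn$dX, caches$flat_dim)
  nblk <- length(.disc_channels(config))
  for (i in rev(seq_len(nblk))) {
    cc <- caches[[paste0("blk", i)]]
    dA <- maxpool2_bwd(dA, cc$pool)
    dA <- lrelu_bwd(dA, cc$lrelu)
    bk <- conv1d_bwd(dA, D[[paste0("conv", i, "_W")]], cc$conv)
    grads[[paste0("conv", i, "_W")]] <- bk$dW
    grads[[paste0("conv", i, "_b")]] <- bk$db
    dA <- bk$dX
  }
  list(grads = grads, dX = dA)
}

#' Generate beats from latent vectors
#'
#' Runs the generator in inference mode (dropout disabled), so the output is
#' a deterministic function of the latent input and the parameters.
#'
#' @param model An `ecg_gan` (trained or freshly initialised).
#' @param z Latent matrix (n x latent_dim) or a single latent vector; or
#'   `NULL` to draw `n` standard-normal latents.
#' @param n Number of beats when `z` is `NULL`.
#' @param seed Seed for latent draws when `z` is `NULL`.
#' @return Numeric matrix, one length-150 beat per row.
#' @export
gan_generate <- function(model, z = NULL, n = 1, seed = 1) {
  stopifnot(inherits(model, "ecg_gan"))
  cfg <- model$config
  if (is.null(z)) {
    set.seed(seed)
    z <- matrix(stats::rnorm(n * cfg$latent_dim), n)
  }
  if (is.null(dim(z))) z <- matrix(z, 1)
  if (ncol(z) != cfg$latent_dim) {
    abort(paste0("latent vectors must have dimension ", cfg$latent_dim))
  }
  .gen_fwd(model$G, z, cfg, train = FALSE)$out
}

#' Score beats with the discriminator
#'
#' @param model An `ecg_gan`.
#' @param x Numeric matrix (n x 150) or a single length-150 vector.
#' @return Numeric vector of probabilities strictly inside (0, 1).
#' @export
gan_discriminate <- function(model, x) {
  stopifnot(inherits(model, "ecg_gan"))
  if (is.null(dim(x))) x <- matrix(x, 1)
  if (ncol(x) != BEAT_LEN) {
    abort(paste0("discriminator input must have length ", BEAT_LEN))
  }
  .disc_fwd(model$D, x, model$config)$p
}

#' Adversarial losses from discriminator outputs
#'
#' The discriminator loss is the negative log-likelihood of the two-player
#' game value, `-mean(log d_real) - mean(log(1 - d_fake))`; the generator
#' loss is the non-saturating form `-mean(log d_fake)` by default, or the
#' minimax form `mean(log(1 - d_fake))`. Probabilities at exactly 0 or 1
#' are clamped by `eps` so both losses stay finite.
#'
#' @param d_real Discriminator outputs on real beats, in (0, 1).
#' @param d_fake Discriminator outputs on generated beats, in (0, 1).
#' @param loss Generator loss form.
#' @param eps Clamp width (default 1e-7).
#' @return Named list `g_loss`, `d_loss`.
#' @export
gan_losses <- function(d_real, d_fake,
                       loss = c("non_saturating", "minimax"), eps = 1e-7) {
  loss <- match.arg(loss)
  d_real <- pmin(pmax(d_real, eps), 1 - eps)
  d_fake <- pmin(pmax(d_fake, eps), 1 - eps)
  d_loss <- -mean(log(d_real)) - mean(log(1 - d_fake))
  g_loss <- if (loss == "non_saturating") -mean(log(d_fake)) else
    mean(log(1 - d_fake))
  list(g_loss = g_loss, d_loss = d_loss)
}

#' Train a GAN on beats of one class
#'
#' Alternating updates: one Adam step on the discriminator (binary
#' cross-entropy on a real and a generated mini-batch), then one on the
#' generator. Beats are z-scored per beat before training. Fully seeded:
#' identical config and data give identical histories.
#'
#' @param beats A beat tibble restricted to the class being modelled (at
#'   least 32 beats).
#' @param config A [gan_config()].
#' @return An `ecg_gan` with per-iteration loss history.
#' @export
train_gan <- function(beats, config = gan_config()) {
  m <- beat_matrix(normalize_beats(beats))
  if (nrow(m) < 32) abort("GAN training needs at least 32 beats")
  if (nrow(m) < config$batch_size) {
    abort("fewer beats than the configured batch size")
  }
  model <- gan_init(config)
  if (config$iterations == 0) return(model)
  G_opt <- adam_init(model$G)
  D_opt <- adam_init(model$D)
  lr <- config$learning_rate
  B <- config$batch_size
  hist_d <- numeric(config$iterations)
  hist_g <- numeric(config$iterations)
  set.seed(config$seed + 1L)
  for (it in seq_len(config$iterations)) {
    idx <- sample.int(nrow(m), B)
    real <- m[idx, , drop = FALSE]
    Z <- matrix(stats::rnorm(B * config$latent_dim), B)
    gen <- .gen_fwd(model$G, Z, config, train = TRUE)
    fake <- gen$out

    # --- discriminator step ---
    fr <- .disc_fwd(model$D, real, config)
    ff <- .disc_fwd(model$D, fake, config)
    losses <- gan_losses(fr$p, ff$p, loss = config$loss)
    # d(BCE)/dz with sigmoid: (p - target) / batch
    bk_r <- .disc_bwd(model$D, (fr$p - 1) / B, fr$caches, config)
    bk_f <- .disc_bwd(model$D, ff$p / B, ff$caches, config)
    d_grads <- acc_grads(bk_r$grads, bk_f$grads)
    st <- adam_step(model$D, d_grads, D_opt, lr, beta1 = config$adam_beta1)
    model$D <- st$params; D_opt <- st$state

    # --- generator step (through the updated discriminator) ---
    gen <- .gen_fwd(model$G, Z, config, train = TRUE)
    ff <- .disc_fwd(model$D, gen$out, config)
    # d/dz of -log(sigmoid(z)) is (p - 1); of log(1 - sigmoid(z)) is -p
    dz <- if (config$loss == "non_saturating") (ff$p - 1) / B else -ff$p / B
    bk <- .disc_bwd(model$D, dz, ff$caches, config)
    dFake <- matrix(bk$dX, B, BEAT_LEN)
    g_grads <- .gen_bwd(model$G, dFake, gen$caches, config)
    st <- adam_step(model$G, g_grads, G_opt, lr, beta1 = config$adam_beta1)
    model$G <- st$params; G_opt <- st$state

    hist_d[it] <- losses$d_loss
    hist_g[it] <- gan_losses(fr$p, ff$p, loss = config$loss)$g_loss
  }
  model$history <- tibble(iteration = seq_len(config$iterations),
                          d_loss = hist_d, g_loss = hist_g)
  model
}

#' Augment minority classes with generated beats
#'
#' Appends generated beats (tagged `source = "generated"`) to each class
#' until its count reaches the target; real beats are never modified or
#' removed. Generated beats are produced on the z-score scale.
#'
#' @param beats A labeled beat tibble.
#' @param targets Named per-class target counts (>= current counts);
#'   defaults to [aami_augment_targets()].
#' @param models Named list of trained `ecg_gan` models, one per class that
#'   needs expansion.
#' @param seed Seed for the latent draws.
#' @return The augmented beat tibble.
#' @export
augment_beats <- function(beats, targets = aami_augment_targets(), models,
                          seed = 1) {
  counts <- stats::setNames(beat_counts(beats)$n, aami_classes())
  plan <- augment_plan(counts, targets)
  out <- beats
  for (r in seq_len(nrow(plan))) {
    ng <- plan$n_generated[r]
    if (ng == 0) next
    cls <- as.character(plan$class[r])
    if (is.null(models[[cls]])) {
      abort(paste0("no GAN model supplied for class ", cls,
                   " (needs ", ng, " generated beats)"))
    }
    gm <- gan_generate(models[[cls]], n = ng,
                       seed = stage_seed(seed, paste0("augment_", cls)))
    out <- bind_rows(out, beat_tbl(gm, record_id = "gan",
                                   r_sample = NA_integer_, label = cls,
                                   source = "generated"))
  }
  class(out) <- unique(c("beat_tbl", class(out)))
  out
}

#' @export
tidy.ecg_gan <- function(x, ...) x$history

#' @export
glance.ecg_gan <- function(x, ...) {
  h <- x$history
  tibble(iterations = nrow(h),
         final_d_loss = if (nrow(h)) h$d_loss[nrow(h)] else NA_real_,
         final_g_loss = if (nrow(h)) h$g_loss[nrow(h)] else NA_real_,
         n_params = sum(vapply(c(x$G, x$D), length, numeric(1))))
}

#' @export
autoplot.ecg_gan <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, c("d_loss", "g_loss"),
                           names_to = "network", values_to = "loss")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$iteration, y = .data$loss,
                                  colour = .data$network)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "iteration", y = "adversarial loss", colour = NULL) +
    ggplot2::theme_minimal()
}
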