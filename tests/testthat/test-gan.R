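test_that("generator obeys its shape and determinism contracts", {
  g <- ecgan:::gan_init(gan_config(seed = 61))
  z <- matrix(rnorm(4 * 100), 4)
  out <- gan_generate(g, z)
  expect_equal(dim(out), c(4L, 150L))
  expect_true(all(is.finite(out)))
  expect_identical(out, gan_generate(g, z))
  # batch output equals per-latent output
  expect_equal(out[3, ], as.numeric(gan_generate(g, z[3, ])),
               tolerance = 1e-12)
  expect_error(gan_generate(g, matrix(rnorm(10), 1)), "dimension 100")
})

test_that("discriminator returns probabilities strictly inside (0, 1)", {
  g <- ecgan:::gan_init(gan_config(seed = 62))
  x <- matrix(rnorm(6 * 150), 6)
  p <- gan_discriminate(g, x)
  expect_true(all(p > 0 & p < 1))
  expect_equal(p[2], gan_discriminate(g, x[2, ]), tolerance = 1e-12)
  expect_error(gan_discriminate(g, rnorm(100)), "length 150")
})

test_that("adversarial losses match the two-player objective", {
  l <- gan_losses(0.5, 0.5)
  expect_equal(l$d_loss, 2 * log(2), tolerance = 1e-12)
  l2 <- gan_losses(1 - 1e-9, 1e-9)
  expect_lt(l2$d_loss, 1e-6)
  # brute-force scalar oracle on random vectors
  set.seed(63)
  dr <- runif(5, 0.05, 0.95)
  df <- runif(5, 0.05, 0.95)
  l3 <- gan_losses(dr, df)
  d_ref <- 0; g_ref <- 0
  for (i in 1:5) {
    d_ref <- d_ref - log(dr[i]) / 5 - log(1 - df[i]) / 5
    g_ref <- g_ref - log(df[i]) / 5
  }
  expect_equal(l3$d_loss, d_ref, tolerance = 1e-10)
  expect_equal(l3$g_loss, g_ref, tolerance = 1e-10)
  mm <- gan_losses(dr, df, loss = "minimax")
  expect_equal(mm$g_loss, mean(log(1 - df)), tolerance = 1e-10)
  # exact 0/1 probabilities are clamped, never NaN
  expect_true(is.finite(gan_losses(c(0, 1), c(0, 1))$d_loss))
})

test_that("zero-iteration training returns the initialised model", {
  beats <- synth_beats(c(V = 40), seed = 64)
  cfg <- gan_config(iterations = 0, seed = 65)
  m <- train_gan(beats, cfg)
  expect_identical(m$G, ecgan:::gan_init(cfg)$G)
  expect_equal(nrow(m$history), 0L)
  expect_error(train_gan(beats[1:10, ], cfg), "at least 32")
})

test_that("short GAN training is reproducible and scores real above noise", {
  beats <- synth_beats(c(N = 128), seed = 66, snr_db = 25)
  cfg <- gan_config(iterations = 60, seed = 67)
  m1 <- train_gan(beats, cfg)
  m2 <- train_gan(beats, cfg)
  expect_identical(m1$history, m2$history)
  expect_equal(nrow(m1$history), 60L)
  # after training on normal beats, held-out real beats outscore noise
  held <- beat_matrix(normalize_beats(synth_beats(c(N = 100), seed = 68,
                                                  snr_db = 25)))
  set.seed(69)
  noise <- matrix(rnorm(100 * 150), 100)
  expect_gt(mean(gan_discriminate(m1, held)),
            mean(gan_discriminate(m1, noise)))
})

test_that("augmentation reaches targets exactly and keeps real beats", {
  beats <- synth_beats(c(N = 30, V = 40, S = 35, F = 32, Q = 33), seed = 70)
  cfg <- gan_config(iterations = 0, seed = 71)
  models <- list(V = ecgan:::gan_init(cfg), S = ecgan:::gan_init(cfg),
                 F = ecgan:::gan_init(cfg), Q = ecgan:::gan_init(cfg))
  targets <- c(N = 30, S = 60, V = 60, F = 60, Q = 60)
  out <- augment_beats(beats, targets, models, seed = 72)
  cnt <- stats::setNames(beat_counts(out)$n, aami_classes())
  expect_equal(cnt, targets[aami_classes()])
  expect_equal(sum(out$source == "generated"), 25L + 20L + 28L + 27L)
  # real rows unchanged, in place
  expect_equal(as.data.frame(out[seq_len(nrow(beats)), ]),
               as.data.frame(beats))
  # identity when targets equal current counts
  same <- augment_beats(beats, stats::setNames(beat_counts(beats)$n,
                                               aami_classes()), list())
  expect_equal(as.data.frame(same), as.data.frame(beats))
  expect_error(augment_beats(beats, c(N = 1, S = 60, V = 60, F = 60, Q = 60),
                             models), "below the raw count")
})
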