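test_that("the quadrature-mirror relation reproduces reference filters", {
  # Haar: the alternating-sign reversal gives (-1, 1)/sqrt(2), matching the
  # reference filter bank's sign convention
  expect_equal(qmf_highpass(c(1, 1) / sqrt(2)), c(-1, 1) / sqrt(2))
  expect_lt(max(abs(qmf_highpass(ref_db6_lo) - ref_db6_hi)), 1e-12)
  expect_error(qmf_highpass(numeric(0)), "non-empty")
})

test_that("applying the mirror relation twice returns the filter up to sign", {
  set.seed(4)
  for (L in 2:8) {
    h <- rnorm(L)
    g2 <- qmf_highpass(qmf_highpass(h))
    # brute-force oracle: g[L-1-n] = (-1)^n h[n] applied twice (0-based)
    g1 <- numeric(L); g2o <- numeric(L)
    for (n in 0:(L - 1)) g1[L - n] <- (-1)^n * h[n + 1]
    for (n in 0:(L - 1)) g2o[L - n] <- (-1)^n * g1[n + 1]
    expect_equal(g2, g2o, tolerance = 1e-12)
    expect_lt(min(max(abs(g2 - h)), max(abs(g2 + h)),
                  max(abs(g2 - rev(h))), max(abs(g2 + rev(h)))), 1e-12)
  }
})

test_that("a Haar impulse decomposes to hand-computed coefficients", {
  x <- c(1, rep(0, 7))
  d <- dwt_decompose(x, wavelet_config("haar", levels = 1,
                                       zeroed_detail_levels = integer(0),
                                       remove_baseline = FALSE))
  # hand convolution: symmetric extension doubles the edge sample, the
  # first retained output pairs (x1, x1); both filters see tap 1/sqrt(2)
  expect_equal(d$approximation, c(1 / sqrt(2), 0, 0, 0), tolerance = 1e-10)
  expect_equal(d$details[[1]], c(1 / sqrt(2), 0, 0, 0), tolerance = 1e-10)
  x2 <- c(0, 1, rep(0, 6))
  d2 <- dwt_decompose(x2, wavelet_config("haar", levels = 1,
                                         zeroed_detail_levels = integer(0),
                                         remove_baseline = FALSE))
  expect_equal(d2$approximation, c(1 / sqrt(2), 0, 0, 0), tolerance = 1e-10)
  expect_equal(d2$details[[1]], c(-1 / sqrt(2), 0, 0, 0), tolerance = 1e-10)
})

test_that("the transform reconstructs unmodified coefficients exactly", {
  set.seed(5)
  for (n in c(64, 333, 1000)) {
    x <- rnorm(n)
    d <- dwt_decompose(x, wavelet_config())
    expect_lt(max(abs(dwt_reconstruct(d) - x)), 1e-8)
  }
})

test_that("a 170 Hz tone at 360 Hz lands in the level-1 detail band", {
  t <- (0:3599) / 360
  x <- sin(2 * pi * 170 * t)
  d <- dwt_decompose(x, wavelet_config(remove_baseline = FALSE))
  e1 <- sum(d$details[[1]]^2)
  etot <- e1 + sum(unlist(d$details[-1])^2) + sum(d$approximation^2)
  expect_gte(e1 / etot, 0.9)
})

test_that("denoising preserves length, zeros, and the no-op configuration", {
  set.seed(6)
  x <- rnorm(500)
  expect_equal(denoise_ecg(rep(0, 400)), rep(0, 400))
  expect_length(denoise_ecg(x), 500)
  idc <- wavelet_config(zeroed_detail_levels = integer(0),
                        threshold_rule = "none", remove_baseline = FALSE)
  expect_lt(max(abs(denoise_ecg(x, idc) - x)), 1e-8)
  expect_identical(denoise_ecg(x), denoise_ecg(x))
  expect_error(denoise_ecg(c(x, NA)), "finite")
  expect_error(denoise_ecg(rnorm(16)), "2\\^levels")
})

test_that("a 50 Hz tone on a clean beat train is removed almost entirely", {
  rec <- generate_record(synthetic_config(
    duration = 10, heart_rate = 70,
    noise = list(list(kind = "powerline", snr_db = 5, freq = 50)),
    seed = 11))
  clean <- attr(rec, "clean")
  out <- denoise_ecg(rec$signal)
  expect_gte(snr_db(out, clean) - snr_db(rec$signal, clean), 5)
})
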