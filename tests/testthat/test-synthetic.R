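test_that("beat generation is deterministic per seed and 150 samples long", {
  b1 <- generate_beat("N", seed = 7)
  b2 <- generate_beat("N", seed = 7)
  expect_identical(b1, b2)
  expect_length(b1, 150)
  expect_false(identical(b1, generate_beat("N", seed = 8)))
})

test_that("ventricular templates are much wider than normal ones", {
  fwhm <- function(x) {
    half <- max(x) / 2
    sum(x > half)
  }
  n <- generate_beat("N", jitter = 0)
  v <- generate_beat("V", jitter = 0)
  expect_gte(fwhm(v), 1.5 * fwhm(n))
})

test_that("the class templates are mutually separable", {
  # nearest-template classification of 1000 jittered beats, 200 per class
  templates <- sapply(aami_classes(), function(cl)
    generate_beat(cl, jitter = 0))
  beats <- synth_beats(stats::setNames(rep(200, 5), aami_classes()),
                       seed = 31)
  m <- beat_matrix(beats)
  pred <- aami_classes()[apply(m, 1, function(b)
    which.min(colSums((templates - b)^2)))]
  expect_gte(mean(pred == beats$label), 0.99)
})

test_that("ground-truth R peaks sit on the template maxima", {
  rec <- generate_record(synthetic_config(duration = 20, heart_rate = 80,
                                          seed = 32,
                                          class_mix = c(N = 0.6, V = 0.2,
                                                        S = 0.2)))
  for (r in rec$ground_truth_r) {
    win <- rec$signal[(r - 20):(r + 20) + 1]
    expect_equal(which.max(win), 21L)
  }
})

test_that("record generation matches the configured rate and mix", {
  rec <- generate_record(synthetic_config(duration = 60, heart_rate = 60,
                                          hr_jitter = 0, seed = 33))
  expect_gte(nrow(rec$annotations), 59)
  expect_lte(nrow(rec$annotations), 61)
  expect_true(all(map_symbol_to_aami(rec$annotations$symbol) == "N"))
  expect_identical(rec$ground_truth_r, rec$annotations$sample)
  # determinism
  rec2 <- generate_record(synthetic_config(duration = 60, heart_rate = 60,
                                           hr_jitter = 0, seed = 33))
  expect_identical(rec$signal, rec2$signal)
})

test_that("powerline noise creates a spectral peak absent from clean data", {
  cfg_clean <- synthetic_config(duration = 10, heart_rate = 70, seed = 34)
  cfg_noisy <- synthetic_config(duration = 10, heart_rate = 70, seed = 34,
                                noise = list(list(kind = "powerline",
                                                  snr_db = 5, freq = 50)))
  clean <- generate_record(cfg_clean)$signal
  noisy <- generate_record(cfg_noisy)$signal
  spec_at <- function(x, f, fs = 360) {
    n <- length(x)
    bin <- round(f * n / fs) + 1
    abs(fft(x))[bin]
  }
  expect_gt(spec_at(noisy, 50), 20 * spec_at(clean, 50))
})

test_that("noise layers hit the requested SNR and respect seeds", {
  set.seed(35)
  x <- generate_record(synthetic_config(duration = 5, seed = 36))$signal
  for (kind in c("baseline_wander", "powerline", "emg_white")) {
    y <- add_noise(x, kind, snr_db = 10, seed = 37)
    expect_equal(snr_db(y, x), 10, tolerance = 0.5)
  }
  expect_identical(add_noise(x, "emg_white", snr_db = 10, seed = 1),
                   add_noise(x, "emg_white", snr_db = 10, seed = 1))
  expect_identical(add_noise(x, "emg_white", amplitude = 0), x)
  expect_error(add_noise(x, "cosmic_rays", snr_db = 1), "unknown noise")
})
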