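# Shared helpers for the test suite. All fixtures are generated in code.

# Greedy one-to-one matching of detected peaks against ground truth within
# a sample tolerance; returns sensitivity and positive predictive value.
match_peaks <- function(detected, truth, tol) {
  used <- rep(FALSE, length(detected))
  tp <- 0
  for (g in truth) {
    d <- which(!used & abs(detected - g) <= tol)
    if (length(d)) {
      used[d[which.min(abs(detected[d] - g))]] <- TRUE
      tp <- tp + 1
    }
  }
  list(se = if (length(truth)) tp / length(truth) else NA_real_,
       ppv = if (length(detected)) tp / length(detected) else NA_real_)
}

# Scaled-down classifier configuration used for training experiments: the
# full-width default architecture is unnecessary to separate the synthetic
# templates, and this width keeps a 20-epoch run around a minute.
scaled_classifier_config <- function(epochs = 20, seed = 1,
                                     batch_size = 128, ...) {
  classifier_config(channels = c(4, 4, 8, 8, 16, 16, 32), kernel_width = 3,
                    lstm_hidden = 16, attention_dim = 16, epochs = epochs,
                    batch_size = batch_size, seed = seed, ...)
}

# Central finite-difference gradient of f at x (numeric vector).
num_grad <- function(f, x, eps = 1e-5) {
  vapply(seq_along(x), function(i) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + eps
    xm[i] <- xm[i] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, numeric(1))
}

# Frozen reference db6 analysis filters (independent published filter bank).
ref_db6_lo <- c(-1.0773010853084796e-03,  4.7772575109455108e-03,
                 5.5384220116149613e-04, -3.1582039317486030e-02,
                 2.7522865530305727e-02,  9.7501605587323043e-02,
                -1.2976686756726194e-01, -2.2626469396543983e-01,
                 3.1525035170919763e-01,  7.5113390802109536e-01,
                 4.9462389039845306e-01,  1.1154074335010947e-01)
ref_db6_hi <- c(-1.1154074335010947e-01,  4.9462389039845306e-01,
                -7.5113390802109536e-01,  3.1525035170919763e-01,
                 2.2626469396543983e-01, -1.2976686756726194e-01,
                -9.7501605587323043e-02,  2.7522865530305727e-02,
                 3.1582039317486030e-02,  5.5384220116149613e-04,
                -4.7772575109455108e-03, -1.0773010853084796e-03)
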