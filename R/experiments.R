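# Scaled-down benchmark experiments on synthetic ECG. These functions fix
# the study conditions (noise levels, record lengths, training sizes); the
# seed arguments only move the random draws.

#' Denoising SNR-gain experiment
#'
#' Generates 10 s records at 75 bpm with the canonical three-component
#' noise mix at a given input SNR, denoises with the default configuration
#' and measures the SNR improvement against the known clean signal.
#'
#' @param n_seeds Number of independent records (default 20).
#' @param input_snr_db Input SNR in dB (default 5).
#' @param seed Base seed; record `i` uses `seed + i`.
#' @return Tibble with `seed`, `snr_in`, `snr_out`, `gain_db`.
#' @export
experiment_denoise_snr <- function(n_seeds = 20, input_snr_db = 5, seed = 0) {
  purrr::map_dfr(seq_len(n_seeds), function(i) {
    rec <- generate_record(synthetic_config(
      duration = 10, heart_rate = 75, noise = mixed_noise(input_snr_db),
      seed = seed + i))
    clean <- attr(rec, "clean")
    s_in <- snr_db(rec$signal, clean)
    s_out <- snr_db(denoise_ecg(rec$signal), clean)
    tibble(seed = seed + i, snr_in = s_in, snr_out = s_out,
           gain_db = s_out - s_in)
  })
}

#' R-peak detector benchmark on clean synthetic records
#'
#' 60 s records at 75 bpm with a mixed beat population; detections are
#' matched to ground truth within a +/-50 ms tolerance by greedy
#' nearest-neighbour pairing.
#'
#' @param n_records Number of records (default 3).
#' @param seed Base seed.
#' @param noise Optional noise list for the generator (default none).
#' @param denoise Denoise before detection (default `FALSE`).
#' @return Tibble with per-record `sensitivity`, `ppv`, counts.
#' @export
experiment_detector <- function(n_records = 3, seed = 0, noise = list(),
                                denoise = FALSE) {
  purrr::map_dfr(seq_len(n_records), function(i) {
    rec <- generate_record(synthetic_config(
      duration = 60, heart_rate = 75,
      class_mix = c(N = 0.7, S = 0.1, V = 0.1, F = 0.05, Q = 0.05),
      noise = noise, seed = seed + i))
    x <- if (denoise) denoise_ecg(rec$signal) else rec$signal
    det <- detect_r_peaks(x, rec$fs)
    tol <- round(0.05 * rec$fs)
    truth <- rec$ground_truth_r
    used <- rep(FALSE, length(det))
    tp <- 0
    for (g in truth) {
      d <- which(!used & abs(det - g) <= tol)
      if (length(d)) {
        used[d[which.min(abs(det[d] - g))]] <- TRUE
        tp <- tp + 1
      }
    }
    tibble(seed = seed + i, n_true = length(truth), n_detected = length(det),
           sensitivity = tp / length(truth), ppv = tp / length(det))
  })
}

#' GAN loss-decrease experiment
#'
#' Trains the beat GAN for 200 iterations on 500 synthetic normal beats and
#' compares the mean generator loss over the first and last 20 iterations.
#'
#' @param seeds Training seeds (default `1:3`).
#' @param iterations Training iterations (default 200).
#' @param n_beats Beats in the training set (default 500).
#' @return Tibble with per-seed `g_first20`, `g_last20`, `decreased`.
#' @export
experiment_gan_loss <- function(seeds = 1:3, iterations = 200,
                                n_beats = 500) {
  beats <- synth_beats(c(N = n_beats), seed = 1000)
  purrr::map_dfr(seeds, function(s) {
    m <- train_gan(beats, gan_config(iterations = iterations, seed = s))
    h <- m$history$g_loss
    tibble(seed = s, g_first20 = mean(head(h, 20)),
           g_last20 = mean(tail(h, 20)),
           decreased = mean(tail(h, 20)) < mean(head(h, 20)))
  })
}

#' Classifier benchmark: attention model vs mean-pooling ablation
#'
#' Trains the scaled-width classifier for 20 epochs on 500 synthetic beats
#' per class (light template jitter plus 20 dB white noise) under several
#' seeds, for both the attention and the ablation variant, and scores the
#' held-out test partition.
#'
#' @param seeds Training seeds (default `1:3`).
#' @param n_per_class Beats per class (default 500).
#' @param epochs Training epochs (default 20).
#' @return Tibble with `seed`, `variant`, `test_accuracy`,
#'   `min_class_sensitivity`, `macro_auc`.
#' @export
experiment_classifier <- function(seeds = 1:3, n_per_class = 500,
                                  epochs = 20) {
  beats <- synth_beats(stats::setNames(rep(n_per_class, 5), aami_classes()),
                       seed = 2000, snr_db = 20)
  cfg0 <- classifier_config(channels = c(4, 4, 8, 8, 16, 16, 32),
                            kernel_width = 3, lstm_hidden = 16,
                            attention_dim = 16, epochs = epochs,
                            batch_size = 128)
  purrr::map_dfr(seeds, function(s) {
    purrr::map_dfr(c(TRUE, FALSE), function(att) {
      cfg <- cfg0
      cfg$seed <- as.integer(s)
      m <- train_classifier(beats, cfg, with_attention = att)
      preds <- holdout_predictions(m, beats)
      rep_ <- metrics_report(preds)
      tibble(seed = s, variant = if (att) "attention" else "ablation",
             test_accuracy = mean(preds$truth == preds$.pred_class),
             min_class_sensitivity = min(rep_$by_class$sensitivity,
                                         na.rm = TRUE),
             macro_auc = mean(rep_$roc$auc$auc, na.rm = TRUE))
    })
  })
}
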