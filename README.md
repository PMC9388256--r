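# ecgan

Heartbeat-level arrhythmia classification on single-lead ECG, end to end:
wavelet denoising, Pan–Tompkins QRS detection, beat segmentation, GAN-based
augmentation of minority beat classes, and a residual-convolution +
BiLSTM + attention classifier over the five AAMI beat classes, with
per-class metrics and one-vs-rest ROC evaluation. A synthetic ECG generator
with known R-peak ground truth makes the whole pipeline testable without
external data; a reader/writer for WFDB-format records connects it to the
PhysioNet arrhythmia databases.

The package is for researchers and engineers who want a transparent,
dependency-light reference implementation of this common pipeline shape —
every layer, including the neural networks, is plain R with hand-written
backward passes, verified against finite differences and scalar oracles in
the test suite.

## The methods in brief

* **Denoising** — 5-level db6 discrete wavelet transform; detail bands
  D1–D2 (45–180 Hz at 360 Hz sampling) zeroed, D3–D5 soft-thresholded
  (hybrid SURE rule by default, universal threshold selectable), plus
  subtraction of the sub-0.7 Hz approximation trend to remove baseline
  wander. The high-pass filter comes from the quadrature-mirror relation
  `g[L−1−n] = (−1)^n h[n]`.
* **QRS detection** — Pan–Tompkins: 5–15 Hz zero-phase band-pass,
  derivative, squaring, 150 ms moving-window integration, dual adaptive
  thresholds with search-back, 200 ms refractory period; detections settle
  on the raw-signal R apex. Beats are the half-open 150-sample windows
  `[r−50, r+100)`.
* **Augmentation** — per minority class, a 1D convolutional GAN: generator
  100-dim latent → 1×128 features → four upsample(5,5,3,2)+conv(width 6)
  blocks, channels halving 128→8 → one channel, length 150; mirrored
  discriminator with sigmoid output; non-saturating adversarial loss,
  Adam (2e-4, β₁ = 0.5).
* **Classification** — beats z-scored and zero-padded to 256; seven
  residual blocks (two conv+batch-norm layers, shortcut, max-pool) halve
  the length to 2; a BiLSTM (128 units/direction) with an attention head
  (perceptron score `v'tanh(WQ + UK)` by default) produces a context vector
  fused with average-pooled convolutional features into a 5-way softmax.
  A mean-pooling ablation isolates the attention mechanism.
* **Evaluation** — per-class one-vs-rest accuracy, sensitivity, both the
  printed PPV-style "specificity" and standard specificity, and trapezoid
  ROC/AUC, in fixed class order N, S, V, F, Q.

## A worked example

```r
library(ecgan)

# a 60 s synthetic record: 75 bpm, mixed beat classes, 10 dB mixed noise
rec <- generate_record(synthetic_config(
  duration = 60, heart_rate = 75,
  class_mix = c(N = 0.7, S = 0.1, V = 0.1, F = 0.05, Q = 0.05),
  noise = mixed_noise(10), seed = 42))
rec
#> <ecg_record synth: 21600 samples @ 360 Hz (60.0 s), 74 annotations>

clean <- attr(rec, "clean")
den <- denoise_ecg(rec$signal)
round(c(snr_in = snr_db(rec$signal, clean), snr_out = snr_db(den, clean)), 2)
#>  snr_in snr_out
#>   10.01   13.70

peaks <- detect_r_peaks(den, rec$fs)
length(peaks)
#> [1] 74
all(abs(peaks - rec$ground_truth_r) <= 18)   # every apex within 50 ms
#> [1] TRUE

beats <- segment_beats(rec)                  # labels from the annotations
beat_counts(beats)
#> # A tibble: 5 x 2
#>   class     n
#>   <fct> <int>
#> 1 N        48
#> 2 S         5
#> 3 V        12
#> 4 F         2
#> 5 Q         7
```

The record sits at the requested 10 dB SNR; denoising buys 3.7 dB on this
relatively clean input (the gain grows as the input gets noisier), and every
one of the 74 annotated beats is recovered within the ±50 ms matching
tolerance. (Numbers printed by the code above, seed 42.)

Training runs chain the same way — `train_gan()`, `augment_beats()`,
`train_classifier()`, `holdout_predictions()`, `metrics_report()` — or in
one call:

```r
res <- run_pipeline(run_config(seed = 1))
res$report$overall_accuracy
tidy(res$model)        # per-epoch history
autoplot(res$report$roc)
```

A thin command-line front end over the same functions ships in
`inst/cli/ecgan.R` (`Rscript inst/cli/ecgan.R help`).

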