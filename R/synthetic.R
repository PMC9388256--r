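# Synthetic single-lead ECG with known ground truth. Beats are sums of
# parameterised wave components (Gaussian, or flat-topped super-Gaussian for
# paced beats) on a 150-sample window; records concatenate beats at a
# configurable heart rate and layer baseline-wander, powerline and EMG noise
# on top. Everything is driven by explicit seeds.

# Per-class wave component tables: amplitude a (mV), width b (s), centre
# theta (s relative to the R peak), shape exponent (2 = Gaussian, 4 =
# flat-topped). Morphologies mimic the clinical distinctions at fixture
# fidelity: S-class beats lose the P wave and shrink slightly; V-class beats
# have a wide, high-amplitude QRS with an inverted T and no P; F averages
# N and V; Q is a flat-topped paced pulse.
.template_components <- function(cls) {
  comp <- function(wave, a, b, theta, shape = 2) {
    tibble(wave = wave, a = a, b = b, theta = theta, shape = shape)
  }
  switch(cls,
    N = bind_rows(comp("P", 0.12, 0.022, -0.105),
                  comp("Q", -0.10, 0.009, -0.028),
                  comp("R", 1.10, 0.012, 0),
                  comp("S", -0.22, 0.010, 0.030),
                  comp("T", 0.30, 0.045, 0.220)),
    S = bind_rows(comp("Q", -0.08, 0.009, -0.026),
                  comp("R", 0.95, 0.011, 0),
                  comp("S", -0.18, 0.010, 0.028),
                  comp("T", 0.22, 0.040, 0.200)),
    V = bind_rows(comp("R", 1.30, 0.034, 0),
                  comp("S", -0.50, 0.030, 0.080),
                  comp("T", -0.35, 0.050, 0.240)),
    F = NULL,  # rendered as the mean of N and V
    Q = bind_rows(comp("R", 0.95, 0.010, 0),
                  comp("pulse", 0.75, 0.050, 0.012, shape = 4)),
    abort(paste0("unknown AAMI class: ", cls)))
}

#' Beat template parameters
#'
#' Wave-component tables for the five AAMI classes, editable before passing
#' to [generate_beat()].
#'
#' @return Named list of tibbles (one per class; `F` is `NULL` because it is
#'   rendered as the average of the N and V templates) with columns `wave`,
#'   `a` (mV), `b` (s), `theta` (s relative to the R peak), `shape`.
#' @export
beat_template_params <- function() {
  stats::setNames(lapply(aami_classes(), .template_components), aami_classes())
}

.render_components <- function(comp, t) {
  y <- numeric(length(t))
  for (k in seq_len(nrow(comp))) {
    y <- y + comp$a[k] *
      exp(-abs((t - comp$theta[k]) / comp$b[k])^comp$shape[k] / 2)
  }
  y
}

.render_template <- function(cls, params, t, jitter_rng = NULL) {
  comp <- if (cls == "F") NULL else params[[cls]]
  render1 <- function(comp) {
    if (!is.null(jitter_rng)) {
      m <- nrow(comp)
      comp$a <- comp$a * exp(jitter_rng(1, 0.04)) * (1 + jitter_rng(m, 0.03))
      comp$b <- comp$b * (1 + jitter_rng(m, 0.03))
      sh <- jitter_rng(m, 0.0015)
      sh[comp$wave == "R"] <- 0  # keep the R apex on the window centre
      comp$theta <- comp$theta + sh
    }
    .render_components(comp, t)
  }
  if (cls == "F") {
    (render1(params[["N"]]) + render1(params[["V"]])) / 2
  } else {
    render1(comp)
  }
}

#' Generate one synthetic heartbeat
#'
#' Renders a 150-sample beat (50 samples before the R peak, 100 after) as a
#' sum of wave components with small multiplicative amplitude/width jitter
#' and additive timing jitter. Deterministic for a fixed seed; `jitter = 0`
#' gives the noiseless class template.
#'
#' @param cls AAMI class, one of `"N","S","V","F","Q"`.
#' @param params Template table from [beat_template_params()].
#' @param seed Integer seed (ignored when `jitter = 0`).
#' @param fs Sampling rate in Hz (default 360).
#' @param jitter Jitter scale multiplier (default 1; 0 disables).
#' @return Numeric vector of 150 samples (mV).
#' @export
generate_beat <- function(cls, params = beat_template_params(), seed = 1,
                          fs = 360, jitter = 1) {
  stopifnot(cls %in% aami_classes())
  t <- ((0:(BEAT_LEN - 1)) - BEAT_PRE) / fs
  jr <- NULL
  if (jitter > 0) {
    rs <- local({ set.seed(seed); function(m, s) rnorm(m, 0, s * jitter) })
    jr <- rs
  }
  .render_template(cls, params, t, jitter_rng = jr)
}

#' Generate a labeled table of synthetic beats
#'
#' @param counts Named vector of beats per class, e.g. `c(N = 500, V = 500)`.
#' @param seed Integer seed.
#' @param snr_db Optional additive white-noise SNR in dB per beat (default
#'   `NULL`, noiseless).
#' @param jitter Template jitter scale (see [generate_beat()]).
#' @param fs Sampling rate in Hz.
#' @return A beat tibble with labels, `source = "real"`.
#' @export
synth_beats <- function(counts, seed = 1, snr_db = NULL, jitter = 1,
                        fs = 360) {
  stopifnot(all(names(counts) %in% aami_classes()))
  params <- beat_template_params()
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, sum(counts))
  labels <- rep(names(counts), times = counts)
  m <- matrix(0, length(labels), BEAT_LEN)
  for (i in seq_along(labels)) {
    b <- generate_beat(labels[i], params, seed = seeds[i], fs = fs,
                       jitter = jitter)
    if (!is.null(snr_db)) {
      b <- add_noise(b, "emg_white", snr_db = snr_db,
                     seed = seeds[i] %% 1000001L, fs = fs)
    }
    m[i, ] <- b
  }
  beat_tbl(m, record_id = "synth", r_sample = NA_integer_, label = labels,
           source = "real")
}

#' Synthetic record configuration
#'
#' @param fs Sampling rate in Hz (default 360).
#' @param heart_rate Mean heart rate in bpm.
#' @param hr_jitter Fractional RR-interval jitter (uniform, default 0.05).
#' @param duration Record length in seconds (at least 2).
#' @param class_mix Named class proportions summing to 1.
#' @param noise List of noise layers, each
#'   `list(kind =, snr_db =)` or `list(kind =, amplitude =)`; kinds are
#'   `"baseline_wander"`, `"powerline"`, `"emg_white"`. `powerline` accepts
#'   an optional `freq` (default 50 Hz).
#' @param seed Integer seed.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(fs = 360, heart_rate = 80, hr_jitter = 0.05,
                             duration = 60,
                             class_mix = c(N = 1),
                             noise = list(), seed = 1) {
  stopifnot(fs > 0, duration >= 2)
  if (!all(names(class_mix) %in% aami_classes()) ||
      abs(sum(class_mix) - 1) > 1e-8 || any(class_mix < 0)) {
    abort("class_mix must be nonnegative proportions over AAMI classes summing to 1")
  }
  structure(list(fs = fs, heart_rate = heart_rate, hr_jitter = hr_jitter,
                 duration = duration, class_mix = class_mix, noise = noise,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# Representative MIT-BIH annotation symbol written for each generated class.
.class_symbol <- c(N = "N", S = "A", V = "V", F = "F", Q = "/")

#' Generate a synthetic ECG record
#'
#' Places jittered beat templates at the configured heart rate on a zero
#' baseline, records the true R-peak locations and per-beat annotations,
#' then layers the configured noise (each layer scaled against the clean
#' signal). The clean signal is attached as attribute `"clean"` for SNR
#' evaluation.
#'
#' @param config A [synthetic_config()].
#' @param record_id Identifier for the resulting record.
#' @return An [ecg_record] with `ground_truth_r` and annotations populated.
#' @export
generate_record <- function(config = synthetic_config(), record_id = "synth") {
  stopifnot(inherits(config, "synthetic_config"))
  fs <- config$fs
  n <- round(config$duration * fs)
  set.seed(config$seed)
  rr0 <- 60 / config$heart_rate * fs
  r <- round(0.45 * fs)
  r_pos <- integer(0)
  while (r + BEAT_POST <= n - 1) {
    r_pos <- c(r_pos, r)
    r <- r + round(rr0 * (1 + stats::runif(1, -config$hr_jitter,
                                           config$hr_jitter)))
  }
  nb <- length(r_pos)
  classes <- sample(names(config$class_mix), nb, replace = TRUE,
                    prob = config$class_mix)
  beat_seeds <- sample.int(.Machine$integer.max, nb)
  params <- beat_template_params()
  x <- numeric(n)
  for (i in seq_len(nb)) {
    b <- generate_beat(classes[i], params, seed = beat_seeds[i], fs = fs)
    idx <- (r_pos[i] - BEAT_PRE):(r_pos[i] + BEAT_POST - 1) + 1L
    x[idx] <- x[idx] + b
    # overlapping wave components can shift the composite apex by a sample;
    # the stored ground truth is the rendered beat's true maximum
    r_pos[i] <- r_pos[i] + which.max(b) - (BEAT_PRE + 1L)
  }
  clean <- x
  noise_seeds <- sample.int(1000000L, max(1, length(config$noise)))
  for (j in seq_along(config$noise)) {
    spec <- config$noise[[j]]
    x <- add_noise(x, spec$kind, amplitude = spec$amplitude,
                   snr_db = spec$snr_db, freq = spec$freq %||% 50,
                   seed = noise_seeds[j], fs = fs, reference = clean)
  }
  rec <- ecg_record(record_id, fs, x,
                    annotations = tibble(sample = r_pos,
                                         symbol = unname(.class_symbol[classes])),
                    ground_truth_r = r_pos)
  attr(rec, "clean") <- clean
  rec
}

#' Equal-power mixed noise specification
#'
#' Convenience constructor for the canonical three-component ECG noise mix
#' (baseline wander + powerline + EMG). Each layer carries a third of the
#' total noise power, so the combined SNR against the clean signal equals
#' `total_snr_db`.
#'
#' @param total_snr_db Target overall SNR in dB.
#' @param powerline_freq Powerline frequency in Hz (default 50).
#' @return A list suitable for the `noise` field of [synthetic_config()].
#' @export
mixed_noise <- function(total_snr_db, powerline_freq = 50) {
  per_layer <- total_snr_db + 10 * log10(3)
  list(list(kind = "baseline_wander", snr_db = per_layer),
       list(kind = "powerline", snr_db = per_layer, freq = powerline_freq),
       list(kind = "emg_white", snr_db = per_layer))
}

#' Add a canonical ECG noise layer to a signal
#'
#' Three noise kinds: `"baseline_wander"` (a mixture of sub-0.5 Hz
#' sinusoids), `"powerline"` (a fixed-frequency 50/60 Hz sinusoid with
#' random phase) and `"emg_white"` (Gaussian white noise). Exactly one of
#' `amplitude` (RMS, mV) or `snr_db` (target SNR against `reference`) must
#' be given; the achieved SNR matches the request to within numerical
#' precision because the layer is scaled analytically.
#'
#' @param x Numeric signal.
#' @param kind Noise kind.
#' @param amplitude RMS amplitude in mV (`0` returns `x` unchanged).
#' @param snr_db Target SNR in dB of `reference` against this layer.
#' @param seed Integer seed.
#' @param fs Sampling rate in Hz.
#' @param freq Powerline frequency in Hz (default 50).
#' @param reference Clean signal used for SNR scaling (defaults to `x`).
#' @return `x` plus the noise layer.
#' @export
add_noise <- function(x, kind, amplitude = NULL, snr_db = NULL, seed = 1,
                      fs = 360, freq = 50, reference = x) {
  n <- length(x)
  if (!is.null(amplitude) && amplitude == 0) return(x)
  set.seed(seed)
  noise <- switch(kind,
    baseline_wander = {
      fr <- stats::runif(3, 0.05, 0.45)
      ph <- stats::runif(3, 0, 2 * pi)
      am <- stats::runif(3, 0.5, 1)
      tt <- (0:(n - 1)) / fs
      am[1] * sin(2 * pi * fr[1] * tt + ph[1]) +
        am[2] * sin(2 * pi * fr[2] * tt + ph[2]) +
        am[3] * sin(2 * pi * fr[3] * tt + ph[3])
    },
    powerline = sin(2 * pi * freq * (0:(n - 1)) / fs +
                      stats::runif(1, 0, 2 * pi)),
    emg_white = stats::rnorm(n),
    abort(paste0("unknown noise kind: ", kind)))
  rms <- sqrt(mean(noise^2))
  if (!is.null(amplitude)) {
    x + noise * amplitude / rms
  } else if (!is.null(snr_db)) {
    p_sig <- mean(reference^2)
    target_p <- p_sig / 10^(snr_db / 10)
    x + noise * sqrt(target_p) / rms
  } else {
    abort("give either amplitude or snr_db")
  }
}
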