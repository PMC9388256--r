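# Pan-Tompkins QRS detection and 150-sample beat segmentation.

#' Detect R peaks with the Pan-Tompkins algorithm
#'
#' Classic real-time QRS detection pipeline: 5-15 Hz band-pass (second-order
#' Butterworth sections applied forwards and backwards), five-point
#' derivative, squaring, 150 ms moving-window integration, then dual
#' adaptive thresholds with search-back. A 200 ms refractory period is
#' enforced and each detection is refined to the local maximum of the
#' band-passed signal within +/-50 ms.
#'
#' @param x Numeric ECG signal (raw or denoised).
#' @param fs Sampling rate in Hz.
#' @return Integer vector of strictly increasing 0-based R-peak sample
#'   indices. Records shorter than 2 s yield an empty result with a warning.
#' @export
detect_r_peaks <- function(x, fs) {
  assert_finite(x, "signal")
  stopifnot(fs > 0)
  n <- length(x)
  if (n < 2 * fs) {
    warn("record shorter than 2 s; no peaks detected")
    return(integer(0))
  }
  if (stats::sd(x) < 1e-8) return(integer(0))  # no QRS energy

  bp <- .bandpass_5_15(x, fs)
  deriv <- .five_point_derivative(bp)
  sq <- deriv^2
  w <- max(1L, round(0.150 * fs))
  mwi <- as.numeric(stats::filter(sq, rep(1 / w, w), sides = 2))
  mwi[is.na(mwi)] <- 0

  refractory <- round(0.2 * fs)
  cand <- .local_maxima(mwi)
  if (!length(cand)) return(integer(0))

  init <- seq_len(min(2 * fs, n))
  spki <- max(mwi[init]) * 0.5
  npki <- mean(mwi[init]) * 0.5
  thr1 <- npki + 0.25 * (spki - npki)

  qrs <- integer(0)
  noise_cand <- integer(0)
  rr <- numeric(0)
  for (p in cand) {
    if (length(qrs) && (p - qrs[length(qrs)]) < refractory) {
      # within refractory: keep the taller of the two integration peaks
      if (mwi[p] > mwi[qrs[length(qrs)]]) qrs[length(qrs)] <- p
      next
    }
    if (mwi[p] > thr1) {
      qrs <- c(qrs, p)
      spki <- 0.125 * mwi[p] + 0.875 * spki
      if (length(qrs) >= 2) {
        rr <- c(rr, diff(tail(qrs, 2)))
        if (length(rr) > 8) rr <- tail(rr, 8)
      }
    } else {
      noise_cand <- c(noise_cand, p)
      npki <- 0.125 * mwi[p] + 0.875 * npki
    }
    thr1 <- npki + 0.25 * (spki - npki)

    # search-back: a long gap suggests a missed beat below the main
    # threshold; recover the tallest skipped candidate above thr1/2
    if (length(qrs) >= 2 && length(rr)) {
      gap <- qrs[length(qrs)] - qrs[length(qrs) - 1]
      if (gap > 1.66 * mean(rr)) {
        inwin <- noise_cand[noise_cand > qrs[length(qrs) - 1] + refractory &
                            noise_cand < qrs[length(qrs)] - refractory]
        inwin <- inwin[mwi[inwin] > thr1 / 2]
        if (length(inwin)) {
          pk <- inwin[which.max(mwi[inwin])]
          qrs <- sort(c(qrs, pk))
          spki <- 0.25 * mwi[pk] + 0.75 * spki
        }
      }
    }
  }
  if (!length(qrs)) return(integer(0))

  # the integration window delays the peak by about w/2 relative to the
  # band-passed QRS; anchor each detection on the band-passed signal, then
  # settle on the local maximum of the raw signal (the R apex) within 50 ms
  half <- round(0.05 * fs)
  delay <- round(w / 2)
  refined <- vapply(qrs, function(p) {
    c0 <- max(1L, p - delay - half)
    c1 <- min(n, p - delay + half)
    anchor <- c0 + which.max(abs(bp[c0:c1])) - 1L
    r0 <- max(1L, anchor - half)
    r1 <- min(n, anchor + half)
    as.integer(r0 + which.max(x[r0:r1]) - 1L)
  }, integer(1))
  refined <- sort(unique(refined))
  keep <- c(TRUE, diff(refined) >= refractory)
  while (!all(keep)) {
    refined <- refined[keep]
    keep <- c(TRUE, diff(refined) >= refractory)
  }
  as.integer(refined - 1L)  # 0-based
}

.bandpass_5_15 <- function(x, fs) {
  ny <- fs / 2
  bf <- signal::butter(2, c(5, 15) / ny, type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

.five_point_derivative <- function(x) {
  n <- length(x)
  xp <- c(x[1], x[1], x, x[n], x[n])
  (2 * xp[5:(n + 4)] + xp[4:(n + 3)] - xp[2:(n + 1)] - 2 * xp[1:n]) / 8
}

.local_maxima <- function(v) {
  n <- length(v)
  if (n < 3) return(integer(0))
  which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
}

#' Cut fixed-length beats around R peaks
#'
#' Extracts one 150-sample window per R peak: 50 samples before the peak and
#' 100 from the peak onwards (half-open, so the R peak sits at within-beat
#' position 50, 0-based). Windows that would cross a record boundary are
#' dropped; the number dropped is attached as attribute `n_dropped`.
#'
#' @param record An [ecg_record], or a numeric signal (then `record_id`
#'   defaults to `"signal"`).
#' @param r_indices 0-based R-peak sample indices. Defaults to the record's
#'   annotation samples (so labels align exactly with annotated positions);
#'   pass the output of [detect_r_peaks()] for unannotated input.
#' @param labels Optional per-peak labels (AAMI classes), attached
#'   positionally. Defaults to the record's mapped annotation symbols when
#'   `r_indices` is taken from the annotations.
#' @param lenient Passed to [map_symbol_to_aami()] when labels are derived
#'   from annotations.
#' @return A beat tibble ([beat_tbl()]), one row per retained beat.
#' @export
segment_beats <- function(record, r_indices = NULL, labels = NULL,
                          lenient = FALSE) {
  if (inherits(record, "ecg_record")) {
    x <- record$signal
    rid <- record$record_id
    if (is.null(r_indices)) {
      r_indices <- record$annotations$sample
      if (is.null(labels) && nrow(record$annotations)) {
        labels <- map_symbol_to_aami(record$annotations$symbol,
                                     lenient = lenient)
      }
    }
  } else {
    x <- as.numeric(record)
    rid <- "signal"
  }
  r_indices <- as.integer(r_indices)
  if (!is.null(labels)) stopifnot(length(labels) == length(r_indices))
  n <- length(x)
  ok <- r_indices - BEAT_PRE >= 0 & r_indices + BEAT_POST <= n
  n_dropped <- sum(!ok)
  r_keep <- r_indices[ok]
  lab <- if (is.null(labels)) rep(NA_character_, length(r_keep)) else labels[ok]
  m <- if (length(r_keep)) {
    t(vapply(r_keep, function(r) x[(r - BEAT_PRE + 1):(r + BEAT_POST)],
             numeric(BEAT_LEN)))
  } else {
    matrix(numeric(0), ncol = BEAT_LEN)
  }
  out <- beat_tbl(m, record_id = rid, r_sample = r_keep,
                  label = if (length(r_keep)) lab else character(0),
                  source = "real")
  attr(out, "n_dropped") <- n_dropped
  out
}
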