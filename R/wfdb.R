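# Reader/writer for the WFDB format family (.hea header, .dat signal,
# .atr annotations) as used by the PhysioNet arrhythmia databases.
# Supports signal formats 16 (16-bit LE) and 212 (packed 12-bit pairs) for
# reading and format 16 for writing; annotations use the MIT format.

# Standard MIT annotation code <-> symbol table (beat and non-beat codes).
.ann_codes <- c(
  "1" = "N", "2" = "L", "3" = "R", "4" = "a", "5" = "V", "6" = "F",
  "7" = "J", "8" = "A", "9" = "S", "10" = "E", "11" = "j", "12" = "/",
  "13" = "Q", "14" = "~", "16" = "|", "18" = "s", "19" = "T", "20" = "*",
  "21" = "D", "22" = "\"", "23" = "=", "24" = "p", "25" = "B", "26" = "^",
  "27" = "t", "28" = "+", "29" = "u", "30" = "?", "31" = "!", "32" = "[",
  "33" = "]", "34" = "e", "35" = "n", "36" = "@", "37" = "x", "38" = "f",
  "39" = "(", "40" = ")", "41" = "r"
)
.symbol_to_code <- stats::setNames(as.integer(names(.ann_codes)),
                                   unname(.ann_codes))

#' Construct an ECG record object
#'
#' One continuous single-channel ECG trace in millivolts, with its sampling
#' rate and (optionally) beat annotations and ground-truth R-peak locations.
#' Sample indices are 0-based throughout, matching the WFDB convention.
#'
#' @param record_id Record identifier string.
#' @param fs Sampling rate in Hz (positive).
#' @param signal Numeric vector, the ECG in mV; must be finite.
#' @param annotations Tibble with integer column `sample` (0-based, strictly
#'   increasing, `< length(signal)`) and character column `symbol`.
#' @param ground_truth_r Optional integer vector of true R-peak sample
#'   indices (populated by the synthetic generator).
#' @return An object of class `ecg_record`.
#' @export
ecg_record <- function(record_id, fs, signal,
                       annotations = tibble(sample = integer(0),
                                            symbol = character(0)),
                       ground_truth_r = NULL) {
  stopifnot(is.character(record_id), length(record_id) == 1)
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    abort("fs must be a single positive number")
  }
  assert_finite(signal, "signal")
  annotations <- as_tibble(annotations)
  stopifnot(all(c("sample", "symbol") %in% names(annotations)))
  annotations$sample <- as.integer(annotations$sample)
  if (nrow(annotations)) {
    s <- annotations$sample
    if (any(diff(s) <= 0) || any(s < 0) || any(s >= length(signal))) {
      abort("annotation samples must be strictly increasing and within the signal")
    }
  }
  structure(list(record_id = record_id, fs = fs, signal = as.numeric(signal),
                 annotations = annotations,
                 ground_truth_r = if (!is.null(ground_truth_r))
                   as.integer(ground_truth_r)),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record %s: %d samples @ %g Hz (%.1f s), %d annotations>\n",
              x$record_id, length(x$signal), x$fs,
              length(x$signal) / x$fs, nrow(x$annotations)))
  invisible(x)
}

.parse_header <- function(hea_path) {
  lines <- readLines(hea_path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rec <- list(record_id = sub("/.*", "", top[1]),
              n_sig = as.integer(top[2]),
              fs = if (length(top) >= 3) as.numeric(sub("/.*", "", top[3])) else 250,
              n_samples = if (length(top) >= 4) as.numeric(top[4]) else NA_real_)
  sig <- lapply(seq_len(rec$n_sig), function(i) {
    tok <- strsplit(trimws(lines[1 + i]), "\\s+")[[1]]
    gain_spec <- tok[3]
    baseline <- NA_real_
    if (grepl("\\(", gain_spec)) {
      baseline <- as.numeric(sub(".*\\(([-0-9]+)\\).*", "\\1", gain_spec))
    }
    gain <- as.numeric(sub("[(/].*", "", gain_spec))
    if (!is.finite(gain) || gain == 0) gain <- 200
    adc_zero <- if (length(tok) >= 5) as.numeric(tok[5]) else 0
    list(file = tok[1], format = sub("x.*|:.*|\\+.*", "", tok[2]),
         gain = gain,
         baseline = if (is.finite(baseline)) baseline else adc_zero)
  })
  rec$signals <- sig
  rec
}

.read_dat <- function(dat_path, format, n_sig, n_samples) {
  sz <- file.info(dat_path)$size
  if (format == "16") {
    need <- 2 * n_sig * n_samples
    if (is.na(sz) || sz < need) {
      abort(paste0("signal file ", dat_path, " is truncated: ", sz,
                   " bytes, expected ", need))
    }
    raw <- readBin(dat_path, "integer", n = n_sig * n_samples, size = 2,
                   signed = TRUE, endian = "little")
    matrix(raw, ncol = n_sig, byrow = TRUE)
  } else if (format == "212") {
    total <- n_sig * n_samples
    need <- ceiling(total * 1.5)
    if (is.na(sz) || sz < need) {
      abort(paste0("signal file ", dat_path, " is truncated: ", sz,
                   " bytes, expected ", need))
    }
    b <- as.integer(readBin(dat_path, "raw", n = need))
    n_pairs <- floor(length(b) / 3)
    b1 <- b[seq(1, by = 3, length.out = n_pairs)]
    b2 <- b[seq(2, by = 3, length.out = n_pairs)]
    b3 <- b[seq(3, by = 3, length.out = n_pairs)]
    s1 <- bitwOr(bitwShiftL(bitwAnd(b2, 15L), 8), b1)
    s2 <- bitwOr(bitwShiftL(bitwAnd(b2, 240L), 4), b3)
    s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
    s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
    flat <- as.vector(rbind(s1, s2))[seq_len(total)]
    matrix(flat, ncol = n_sig, byrow = TRUE)
  } else {
    abort(paste0("unsupported WFDB signal format ", format))
  }
}

.read_atr <- function(atr_path) {
  words <- readBin(atr_path, "integer",
                   n = file.info(atr_path)$size / 2, size = 2,
                   signed = FALSE, endian = "little")
  samples <- integer(0); symbols <- character(0)
  t_cur <- 0; i <- 1
  while (i <= length(words)) {
    w <- words[i]
    code <- bitwShiftR(w, 10)
    tm <- bitwAnd(w, 1023L)
    if (code == 0 && tm == 0) break           # end of annotations
    if (code == 59) {                          # SKIP: 4-byte interval follows
      hi <- words[i + 1]; lo <- words[i + 2]
      t_cur <- t_cur + hi * 65536 + lo
      i <- i + 3
      next
    }
    if (code %in% c(60, 61, 62)) { i <- i + 1; next }  # NUM/SUB/CHN
    if (code == 63) {                          # AUX: skip payload
      i <- i + 1 + ceiling(tm / 2)
      next
    }
    t_cur <- t_cur + tm
    sym <- .ann_codes[as.character(code)]
    if (!is.na(sym)) {
      samples <- c(samples, t_cur)
      symbols <- c(symbols, unname(sym))
    }
    i <- i + 1
  }
  tibble(sample = as.integer(samples), symbol = symbols)
}

#' Read a WFDB record
#'
#' Reads a `.hea`/`.dat` pair (and `.atr` annotations when present), selects
#' one channel, and converts it to physical units (mV) via the header's gain
#' and baseline. Non-beat annotation symbols (rhythm marks, noise flags, ...)
#' are dropped; only heartbeat annotations are kept.
#'
#' @param path Record path without extension (e.g. `"data/100"`), or the
#'   `.hea` file path.
#' @param channel Channel to read, 1-based (default 1, the first channel —
#'   lead MLII in most MIT-BIH records).
#' @param keep_all_symbols Keep non-beat annotation symbols too (default
#'   `FALSE`).
#' @return An [ecg_record].
#' @export
read_record <- function(path, channel = 1, keep_all_symbols = FALSE) {
  base <- sub("\\.hea$", "", path)
  hea <- paste0(base, ".hea")
  if (!file.exists(hea)) abort(paste0("header file not found: ", hea))
  hdr <- .parse_header(hea)
  if (channel < 1 || channel > hdr$n_sig) {
    abort(paste0("channel ", channel, " out of range; record has ",
                 hdr$n_sig, " channel(s)"))
  }
  sig_info <- hdr$signals[[channel]]
  dat <- file.path(dirname(hea), sig_info$file)
  if (!file.exists(dat)) abort(paste0("signal file not found: ", dat))
  adc <- .read_dat(dat, sig_info$format, hdr$n_sig, hdr$n_samples)[, channel]
  mv <- (adc - sig_info$baseline) / sig_info$gain
  atr <- paste0(base, ".atr")
  ann <- if (file.exists(atr)) .read_atr(atr) else
    tibble(sample = integer(0), symbol = character(0))
  if (!keep_all_symbols && nrow(ann)) {
    ann <- ann[ann$symbol %in% beat_symbols(), ]
  }
  ann <- ann[ann$sample < length(mv), ]
  ecg_record(hdr$record_id, hdr$fs, mv, ann)
}

#' Write a WFDB record
#'
#' Writes an [ecg_record] as a single-channel format-16 WFDB triple
#' (`.hea`, `.dat`, and `.atr` when annotations are present). The signal is
#' quantised with the given gain, so a read-back agrees with the original to
#' within half an ADC step (`1 / (2 * gain)` mV).
#'
#' @param record An [ecg_record].
#' @param dir Output directory (created if missing).
#' @param gain ADC gain in units per mV (default 200, the MIT-BIH value).
#' @return The record path (without extension), invisibly.
#' @export
write_record <- function(record, dir, gain = 200) {
  stopifnot(inherits(record, "ecg_record"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  base <- file.path(dir, record$record_id)
  n <- length(record$signal)
  adc <- as.integer(pmax(pmin(round(record$signal * gain), 32767), -32768))
  writeLines(c(sprintf("%s 1 %g %d", record$record_id, record$fs, n),
               sprintf("%s.dat 16 %g 16 0 %d 0 0 ECG", record$record_id,
                       gain, adc[1])),
             paste0(base, ".hea"))
  writeBin(adc, paste0(base, ".dat"), size = 2, endian = "little")
  if (nrow(record$annotations)) {
    .write_atr(record$annotations, paste0(base, ".atr"))
  }
  invisible(base)
}

.write_atr <- function(ann, path) {
  codes <- .symbol_to_code[ann$symbol]
  if (anyNA(codes)) {
    abort(paste0("cannot encode annotation symbol(s): ",
                 paste(unique(ann$symbol[is.na(codes)]), collapse = ", ")))
  }
  deltas <- diff(c(0L, ann$sample))
  words <- integer(0)
  for (k in seq_along(deltas)) {
    d <- deltas[k]
    if (d > 1023) {
      words <- c(words, bitwShiftL(59L, 10),
                 d %/% 65536, d %% 65536)
      d <- 0L
    }
    words <- c(words, bitwOr(bitwShiftL(codes[k], 10), as.integer(d)))
  }
  words <- c(words, 0L)                        # end marker
  con <- file(path, "wb")
  on.exit(close(con))
  # writeBin has no unsigned 16-bit mode; emit the two bytes explicitly.
  bytes <- as.raw(rbind(words %% 256, words %/% 256))
  writeBin(bytes, con)
  invisible(path)
}
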