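# Beat datasets: one row per 150-sample beat, in a tibble with columns
# record_id, r_sample (0-based absolute index of the R peak), label
# (AAMI class or NA), source ("real" or "generated"), s0..s149.

BEAT_LEN <- 150L
BEAT_PRE <- 50L    # samples taken before the R peak
BEAT_POST <- 100L  # samples taken from the R peak onwards (includes it)

.sample_cols <- function() paste0("s", 0:(BEAT_LEN - 1))

#' Assemble a beat tibble
#'
#' @param samples Numeric matrix, one beat per row, 150 columns.
#' @param record_id,r_sample,label,source Per-beat metadata (recycled if
#'   length 1). `label` may be `NA` for unlabeled beats.
#' @return A `beat_tbl` tibble.
#' @export
beat_tbl <- function(samples, record_id = "synth", r_sample = NA_integer_,
                     label = NA_character_, source = "real") {
  samples <- matrix(as.numeric(samples), ncol = BEAT_LEN)
  assert_finite(as.vector(samples), "beat samples")
  n <- nrow(samples)
  lab <- as.character(label)
  if (!all(is.na(lab) | lab %in% aami_classes())) {
    abort("labels must be AAMI classes (N, S, V, F, Q) or NA")
  }
  meta <- tibble(record_id = rep_len(as.character(record_id), n),
                 r_sample = rep_len(as.integer(r_sample), n),
                 label = rep_len(lab, n),
                 source = rep_len(as.character(source), n))
  sm <- as_tibble(as.data.frame(samples))
  names(sm) <- .sample_cols()
  out <- dplyr::bind_cols(meta, sm)
  class(out) <- c("beat_tbl", class(out))
  out
}

#' Extract the sample matrix from a beat tibble
#'
#' @param beats A beat tibble.
#' @return Numeric matrix, one beat per row, 150 columns.
#' @export
beat_matrix <- function(beats) {
  as.matrix(beats[, .sample_cols()])
}

#' Per-class beat counts of a dataset
#'
#' @param beats A beat tibble.
#' @return Tibble with `class`, `n` (five rows; `NA` labels excluded).
#' @export
beat_counts <- function(beats) {
  tab <- table(factor(beats$label, levels = aami_classes()))
  tibble(class = factor(aami_classes(), levels = aami_classes()),
         n = as.integer(tab))
}

#' Z-score each beat
#'
#' Per-beat amplitude normalisation (subtract the beat mean, divide by its
#' standard deviation); constant beats become all-zero. Applied before GAN
#' and classifier training.
#'
#' @param beats A beat tibble.
#' @return The beat tibble with normalised sample columns.
#' @export
normalize_beats <- function(beats) {
  m <- beat_matrix(beats)
  mu <- rowMeans(m)
  sdv <- sqrt(pmax(rowMeans(m^2) - mu^2, 0))
  sdv[sdv < 1e-12] <- 1
  m <- (m - mu) / sdv
  beats[, .sample_cols()] <- as.data.frame(m)
  beats
}

#' Write a beat dataset to CSV
#'
#' Plain columnar text with a header row: `record_id, r_sample, label,
#' source, s0...s149`. Lossless for labels and source tags; samples are
#' written in full double precision.
#'
#' @param beats A beat tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_beats <- function(beats, path) {
  readr::write_csv(as_tibble(beats)[, c("record_id", "r_sample", "label",
                                        "source", .sample_cols())], path)
  invisible(path)
}

#' Read a beat dataset from CSV
#'
#' Validates the header and the label column; a label outside
#' \{N, S, V, F, Q\} (or NA) raises an error naming the offending row.
#'
#' @param path CSV file written by [write_beats()].
#' @return A beat tibble.
#' @export
read_beats <- function(path) {
  if (!file.exists(path)) abort(paste0("beat file not found: ", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(
                          record_id = readr::col_character(),
                          r_sample = readr::col_integer(),
                          label = readr::col_character(),
                          source = readr::col_character(),
                          .default = readr::col_double()))
  need <- c("record_id", "r_sample", "label", "source", .sample_cols())
  if (!all(need %in% names(df))) {
    abort(paste0("malformed beat file ", path, ": missing column(s) ",
                 paste(setdiff(need, names(df)), collapse = ", ")))
  }
  bad <- which(!(is.na(df$label) | df$label %in% aami_classes()))
  if (length(bad)) {
    abort(paste0("invalid label ", sQuote(df$label[bad[1]]), " at row ",
                 bad[1], " of ", path))
  }
  out <- df[, need]
  class(out) <- c("beat_tbl", class(out))
  out
}
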